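# Stage orchestration: simulate -> preprocess -> features -> stats ->
# train -> evaluate, with manifests and one seed governing every stage.

fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

config_hash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 8,
                                      force = TRUE)))
}

write_manifest <- function(out_dir, stage, config, outputs, t0) {
  man <- list(stage = stage, seed = config$seed,
              config_hash = config_hash(config),
              outputs = outputs,
              duration_s = round(as.numeric(Sys.time()) - t0, 2))
  jsonlite::write_json(man, file.path(out_dir, paste0("manifest_", stage,
                                                      ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations under one run seed. The default
#' cohort here is a small demonstration cohort so a full `run_pipeline("all")`
#' completes quickly; pass an explicit `cohort` for full-scale simulations.
#'
#' @param seed Run seed applied to every stochastic stage.
#' @param cohort A [cohort_config()].
#' @param preprocess A [preprocess_config()].
#' @param events An [events_config()].
#' @param model A [model_config()].
#' @param fractions Train/validation/test split fractions.
#' @param max_windows_per_patient Optional training-window cap per patient.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            cohort = cohort_config(n_patients = 24,
                                                   duration = 0.5,
                                                   sample_rate = 10,
                                                   seed = seed),
                            preprocess = preprocess_config(),
                            events = events_config(),
                            model = model_config(seed = seed),
                            fractions = c(train = 0.70, val = 0.15,
                                          test = 0.15),
                            max_windows_per_patient = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 preprocess = preprocess, events = events, model = model,
                 fractions = fractions,
                 max_windows_per_patient = max_windows_per_patient),
            class = "pipeline_config")
}

#' Patient-level train/validation/test split
#'
#' Seeded assignment stratified by label combination where the combination
#' group is large enough to spread over the subsets; smaller groups are
#' assigned jointly. Every window of a patient inherits the patient's
#' subset.
#'
#' @param labels Data frame with `patient_id` and the three label columns.
#' @param fractions Named fractions (`train`, `val`, `test`).
#' @param seed Integer seed.
#' @return Data frame with `patient_id` and `subset`.
#' @export
split_plan <- function(labels, fractions = c(train = 0.70, val = 0.15,
                                             test = 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  set.seed(as.integer(seed))
  combo <- interaction(labels$hypertension, labels$diabetes,
                       labels$asthma_copd, drop = TRUE)
  groups <- split(labels$patient_id, combo)
  small <- unlist(groups[vapply(groups, length, 0L) < 3L], use.names = FALSE)
  groups <- groups[vapply(groups, length, 0L) >= 3L]
  if (length(small)) groups <- c(groups, list(pooled = small))
  assign_one <- function(ids) {
    ids <- sample(ids)
    n <- length(ids)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["val"]] * n)
    n_tr <- min(n_tr, n)
    n_va <- min(n_va, n - n_tr)
    rep(c("train", "val", "test"),
        c(n_tr, n_va, n - n_tr - n_va))[seq_len(n)] -> subs
    data.frame(patient_id = ids, subset = subs)
  }
  out <- do.call(rbind, lapply(groups, assign_one))
  rownames(out) <- NULL
  out
}

stage_require <- function(path, produced_by) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path, "; run stage '", produced_by,
         "' first")
  path
}

#' Run the pipeline
#'
#' Stages run in dependency order and write their artifacts plus a manifest
#' (seed, config hash, outputs, duration) under `out_dir`:
#' \describe{
#'   \item{simulate}{EDF per patient, `clinical.csv`, `ground_truth.jsonl`}
#'   \item{preprocess}{per-patient Feather caches of the processed traces}
#'   \item{features}{`features.csv`, per-event `events.jsonl`}
#'   \item{stats}{group-comparison CSVs and the severity-strata report}
#'   \item{train}{trained model (`model.rds`), `history.csv`, split plan}
#'   \item{evaluate}{test-set metrics JSON, MLCM CSV, stratified CSV}
#' }
#'
#' @param stage One of `simulate`, `preprocess`, `features`, `stats`,
#'   `train`, `evaluate`, `all`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list of stage outputs.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "preprocess",
                                   "features", "stats", "train", "evaluate"),
                         config = pipeline_config(), out_dir = tempfile()) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all")
    c("simulate", "preprocess", "features", "stats", "train", "evaluate")
  else stage
  res <- list()
  for (s in stages) res[[s]] <- run_stage(s, config, out_dir)
  invisible(res)
}

run_stage <- function(stage, config, out_dir) {
  t0 <- as.numeric(Sys.time())
  raw_dir <- file.path(out_dir, "raw")
  pp_dir <- file.path(out_dir, "preprocessed")
  switch(stage,
    simulate = {
      generate_cohort(config$cohort, dir = raw_dir)
      write_manifest(out_dir, "simulate", config,
                     list.files(raw_dir), t0)
      raw_dir
    },
    preprocess = {
      stage_require(file.path(raw_dir, "clinical.csv"), "simulate")
      clin <- read_clinical(file.path(raw_dir, "clinical.csv"),
                            require_labels = TRUE)
      dir.create(pp_dir, showWarnings = FALSE)
      for (pid in clin$patient_id) {
        tr <- read_edf(file.path(raw_dir, paste0(pid, ".edf")))
        pp <- preprocess_patient(tr$SpO2, tr$FP0, config$preprocess)
        cache_columnar(pp$spo2, file.path(pp_dir, paste0(pid, "_spo2.feather")))
        cache_columnar(pp$dspo2, file.path(pp_dir, paste0(pid, "_dspo2.feather")))
        cache_columnar(pp$fp0, file.path(pp_dir, paste0(pid, "_fp0.feather")))
      }
      write_manifest(out_dir, "preprocess", config, list.files(pp_dir), t0)
      pp_dir
    },
    features = {
      stage_require(pp_dir, "preprocess")
      clin <- read_clinical(file.path(raw_dir, "clinical.csv"),
                            require_labels = TRUE)
      feats <- list()
      ev_con <- file(file.path(out_dir, "events.jsonl"), "w")
      for (pid in clin$patient_id) {
        pp <- load_processed(pp_dir, pid)
        ev <- patient_events(pp, clin[clin$patient_id == pid, ],
                             config$events)
        feats[[pid]] <- ev$features
        if (nrow(ev$pairs)) for (i in seq_len(nrow(ev$pairs)))
          writeLines(jsonlite::toJSON(c(list(patient_id = pid),
                                        as.list(ev$pairs[i, ])),
                                      auto_unbox = TRUE, digits = NA), ev_con)
      }
      close(ev_con)
      fm <- do.call(rbind, feats)
      # missing-event rows are imputed later inside assemble_and_normalize
      write_feature_matrix(fm, file.path(out_dir, "features.csv"))
      write_manifest(out_dir, "features", config, "features.csv", t0)
      file.path(out_dir, "features.csv")
    },
    stats = {
      stage_require(file.path(out_dir, "features.csv"), "features")
      raw_fm <- read_feature_matrix(file.path(out_dir, "features.csv"))
      labels <- read_clinical(file.path(raw_dir, "clinical.csv"),
                              require_labels = TRUE)
      for (sp in c("any", "hypertension", "diabetes", "asthma_copd")) {
        cmp <- tryCatch(compare_groups(raw_fm, labels, sp),
                        error = function(e) NULL)
        if (!is.null(cmp))
          utils::write.csv(cmp, file.path(out_dir,
                                          paste0("comparison_", sp, ".csv")),
                           row.names = FALSE)
      }
      strata <- severity_strata(raw_fm, labels)
      jsonlite::write_json(strata, file.path(out_dir, "severity_strata.json"),
                           auto_unbox = TRUE, pretty = TRUE, dataframe = "rows")
      write_manifest(out_dir, "stats", config, "comparison_*.csv", t0)
      out_dir
    },
    train = {
      stage_require(file.path(out_dir, "features.csv"), "features")
      bundle <- assemble_training_data(config, out_dir)
      model <- build_model(config$model, ncol(bundle$data$spo2),
                           length(feature_columns()))
      fit <- train_cnn(model, bundle$data, bundle$split)
      saveRDS(list(model = fit$model, scaler = bundle$scaler,
                   split = bundle$split),
              file.path(out_dir, "model.rds"))
      utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      utils::write.csv(bundle$plan, file.path(out_dir, "split.csv"),
                       row.names = FALSE)
      write_manifest(out_dir, "train", config,
                     c("model.rds", "history.csv", "split.csv"), t0)
      file.path(out_dir, "model.rds")
    },
    evaluate = {
      stage_require(file.path(out_dir, "model.rds"), "train")
      saved <- readRDS(file.path(out_dir, "model.rds"))
      bundle <- assemble_training_data(config, out_dir, scaler = saved$scaler)
      labels <- read_clinical(file.path(raw_dir, "clinical.csv"),
                              require_labels = TRUE)
      test_ids <- intersect(saved$split$test, unique(bundle$data$patient_id))
      pred <- predict_patients(saved$model, bundle$data, ids = test_ids)
      truth <- as.matrix(labels[match(rownames(pred$prob),
                                      labels$patient_id), LABELS])
      rep <- metrics_report(truth, pred$labels, scores = pred$prob)
      out <- rep[c("subset_accuracy", "flat_accuracy", "partial_accuracy",
                   "hamming_loss", "f1_macro", "f1_micro", "f1_weighted")]
      out$auc_roc_macro <- rep$auc_roc_macro
      out$auc_pr_macro <- rep$auc_pr_macro
      jsonlite::write_json(out, file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      utils::write.csv(as.data.frame(rep$mlcm$raw),
                       file.path(out_dir, "mlcm_raw.csv"))
      clin_test <- labels[match(rownames(pred$prob), labels$patient_id), ]
      strat <- stratified_eval(truth, pred$labels, clin_test, by = "Age",
                               breaks = demographic_bins()$Age)
      utils::write.csv(strat, file.path(out_dir, "stratified_age.csv"),
                       row.names = FALSE)
      write_manifest(out_dir, "evaluate", config,
                     c("metrics.json", "mlcm_raw.csv"), t0)
      out
    },
    stop("unknown stage ", stage)
  )
}

load_processed <- function(pp_dir, pid) {
  list(
    spo2 = load_columnar(file.path(pp_dir, paste0(pid, "_spo2.feather"))),
    dspo2 = load_columnar(file.path(pp_dir, paste0(pid, "_dspo2.feather"))),
    fp0 = load_columnar(file.path(pp_dir, paste0(pid, "_fp0.feather")))
  )
}

assemble_training_data <- function(config, out_dir, scaler = NULL) {
  raw_dir <- file.path(out_dir, "raw")
  pp_dir <- file.path(out_dir, "preprocessed")
  labels <- read_clinical(file.path(raw_dir, "clinical.csv"),
                          require_labels = TRUE)
  fm <- read_feature_matrix(file.path(out_dir, "features.csv"))
  plan <- split_plan(labels, config$fractions, config$seed)
  split <- split(plan$patient_id, plan$subset)
  if (is.null(scaler)) {
    norm <- assemble_and_normalize(fm, fit_ids = split$train)
    scaler <- norm$scaler
    feats <- norm$matrix
  } else {
    feats <- apply_scaler(scaler, fm)
  }
  windows <- lapply(labels$patient_id, function(pid) {
    pp <- load_processed(pp_dir, pid)
    make_windows(pp$spo2, pp$dspo2, pp$fp0, config$preprocess)
  })
  data <- window_dataset(windows, feats, labels,
                         config$max_windows_per_patient)
  list(data = data, split = split, scaler = scaler, plan = plan)
}

#' Evaluate the bundled reference label fixture
#'
#' Runs the full metric report on the bundled truth/prediction fixture
#' whose MLCM reproduces the reference raw matrix (fractional entries
#' included), optionally writing the report to JSON.
#'
#' @param out_path Optional JSON output path.
#' @return The [metrics_report()] list.
#' @export
evaluate_reference_fixture <- function(out_path = NULL) {
  fx <- mlcm_example_labels()
  rep <- metrics_report(fx$truth, fx$pred)
  if (!is.null(out_path)) {
    out <- rep[c("subset_accuracy", "flat_accuracy", "partial_accuracy",
                 "hamming_loss", "f1_macro", "f1_micro", "f1_weighted")]
    out$mlcm_raw <- rep$mlcm$raw
    out$precision <- rep$mlcm$precision
    out$recall <- rep$mlcm$recall
    jsonlite::write_json(out, out_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, matrix = "rowmajor")
  }
  rep
}
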