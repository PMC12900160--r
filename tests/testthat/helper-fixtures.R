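# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A tiny noiseless patient with a moderate number of events: the workhorse
# for detector and preprocessing checks.
noiseless_patient <- function() memo("noiseless_patient", function() {
  cfg <- cohort_config(
    n_patients = 1, duration = 1.0, sample_rate = 25,
    ahi_distribution = list(meanlog = log(25), sdlog = 1e-6, lo = 0, hi = 60),
    noise_sd_spo2 = 0, noise_frac_fp0 = 0, seed = 11
  )
  p <- generate_patient(cfg, 1)
  list(patient = p, pp = preprocess_patient(p$spo2, p$fp0))
})

# Small noisy cohort with preprocessed windows and features: used by the
# model and pipeline tests. Short recordings keep this cheap.
small_cohort <- function() memo("small_cohort", function() {
  cfg <- cohort_config(
    n_patients = 40, duration = 0.25, sample_rate = 5,
    ahi_distribution = list(meanlog = log(18), sdlog = 0.5, lo = 0, hi = 25),
    seed = 21
  )
  coh <- generate_cohort(cfg)
  pps <- lapply(coh$patients, function(p) preprocess_patient(p$spo2, p$fp0))
  feats <- do.call(rbind, lapply(seq_along(pps), function(i)
    suppressWarnings(
      patient_events(pps[[i]], coh$patients[[i]]$clinical)$features
    )))
  ids <- coh$clinical$patient_id
  split <- list(train = ids[1:28], val = ids[29:34], test = ids[35:40])
  norm <- assemble_and_normalize(feats, fit_ids = split$train)
  data <- window_dataset(lapply(pps, function(p) p$windows), norm$matrix,
                         coh$clinical, max_windows_per_patient = 4)
  list(cohort = coh, pps = pps, features = feats, norm = norm, data = data,
       split = split)
})

# Large injected-signal cohort for the model-recovery properties.
# 400 patients, short recordings; the label model couples labels to both
# covariates and desaturation morphology.
signal_cohort <- function(label_model = NULL, key = "signal_cohort",
                          n = 400) memo(key, function() {
  args <- list(
    n_patients = n, duration = 0.25, sample_rate = 5,
    ahi_distribution = list(meanlog = log(20), sdlog = 0.5, lo = 0, hi = 25),
    seed = 101
  )
  if (!is.null(label_model)) args$label_model <- label_model
  cfg <- do.call(cohort_config, args)
  coh <- generate_cohort(cfg)
  pps <- lapply(coh$patients, function(p)
    suppressWarnings(preprocess_patient(p$spo2, p$fp0)))
  feats <- do.call(rbind, lapply(seq_along(pps), function(i)
    suppressWarnings(
      patient_events(pps[[i]], coh$patients[[i]]$clinical)$features
    )))
  labels <- coh$clinical
  plan <- split_plan(labels, seed = 101)
  split <- split(plan$patient_id, plan$subset)
  norm <- assemble_and_normalize(feats, fit_ids = split$train)
  data <- window_dataset(lapply(pps, function(p) p$windows), norm$matrix,
                         labels, max_windows_per_patient = 3)
  list(labels = labels, split = split, data = data)
})

# Train one model on a prepared cohort and return its test macro AUC-ROC.
train_and_auc <- function(fx, seed, clinical = TRUE, epochs = 80,
                          eval_on = "test") {
  mc <- model_config(pool = 4, batch_size = 128, epochs = epochs,
                     patience = 15, lr = 2e-3,
                     use_clinical_branch = clinical, seed = seed)
  mdl <- build_model(mc, ncol(fx$data$spo2), length(feature_columns()))
  fit <- suppressWarnings(train_cnn(mdl, fx$data, fx$split))
  ids <- unlist(fx$split[eval_on], use.names = FALSE)
  ids <- intersect(ids, unique(fx$data$patient_id))
  pv <- predict_patients(fit$model, fx$data, ids = ids)
  truth <- as.matrix(fx$labels[match(rownames(pv$prob),
                                     fx$labels$patient_id),
                               c("hypertension", "diabetes", "asthma_copd")])
  suppressWarnings(auc_metrics(pv$prob, truth)$auc_roc_macro)
}

# Random binary label matrices for the metric property suites.
random_label_matrix <- function(n, q = 3, p = 0.4) {
  matrix(stats::rbinom(n * q, 1, p), n, q)
}

# Independent brute-force multi-label metrics, written directly from the
# defining formulas with explicit loops (the oracle for the fast paths).
brute_force_metrics <- function(truth, pred) {
  N <- nrow(truth); q <- ncol(truth)
  subset_acc <- 0; flat <- 0; jacc <- 0; hamm <- 0
  for (i in seq_len(N)) {
    Y <- which(truth[i, ] == 1); Z <- which(pred[i, ] == 1)
    subset_acc <- subset_acc + as.numeric(setequal(Y, Z))
    for (j in seq_len(q)) {
      flat <- flat + as.numeric(truth[i, j] == pred[i, j])
      hamm <- hamm + as.numeric(truth[i, j] != pred[i, j])
    }
    u <- union(Y, Z)
    jacc <- jacc + if (length(u) == 0) 1 else length(intersect(Y, Z)) / length(u)
  }
  per_label <- lapply(seq_len(q), function(j) {
    TP <- sum(truth[, j] == 1 & pred[, j] == 1)
    FP <- sum(truth[, j] == 0 & pred[, j] == 1)
    TN <- sum(truth[, j] == 0 & pred[, j] == 0)
    FN <- sum(truth[, j] == 1 & pred[, j] == 0)
    prec <- if (TP + FP > 0) TP / (TP + FP) else if (TP + FN == 0) 1 else 0
    rec <- if (TP + FN > 0) TP / (TP + FN) else if (TP + FP == 0) 1 else 0
    f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN)
          else if (TP + FP + FN == 0) 1 else 0
    list(TP = TP, FP = FP, TN = TN, FN = FN, accuracy = (TP + TN) / N,
         precision = prec, recall = rec, F1 = f1, support = TP + FN)
  })
  f1s <- vapply(per_label, `[[`, 0, "F1")
  supp <- vapply(per_label, `[[`, 0, "support")
  TPs <- sum(vapply(per_label, `[[`, 0, "TP"))
  FPs <- sum(vapply(per_label, `[[`, 0, "FP"))
  FNs <- sum(vapply(per_label, `[[`, 0, "FN"))
  micro_f1 <- if (2 * TPs + FPs + FNs > 0) 2 * TPs / (2 * TPs + FPs + FNs)
              else 1
  list(
    subset_accuracy = subset_acc / N,
    flat_accuracy = flat / (N * q),
    partial_accuracy = jacc / N,
    hamming_loss = hamm / (N * q),
    f1_macro = mean(f1s),
    f1_micro = micro_f1,
    f1_weighted = if (sum(supp) > 0) sum(f1s * supp) / sum(supp) else mean(f1s),
    per_label = per_label
  )
}
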