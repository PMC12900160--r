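# Multi-branch 1D-CNN for multi-label comorbidity prediction.
#
# Three convolutional branches (SpO2, SpO2 derivative, FP0 airflow) and a
# dense clinical branch are fused into a 3-unit sigmoid head. Training uses
# class-weighted binary cross-entropy (or focal loss) under Adam with early
# stopping on validation macro AUC-PR.

LABELS <- c("hypertension", "diabetes", "asthma_copd")

#' Model configuration
#'
#' @param conv_filters Filters of the two convolution blocks in every signal
#'   branch.
#' @param kernel Convolution kernel length (samples, odd).
#' @param pool Average-pooling factor applied to the time axis between
#'   convolution blocks (1 = no intermediate pooling; larger values trade
#'   temporal resolution of the second block for compute).
#' @param dropout Dropout rate applied after every ReLU.
#' @param batchnorm Use batch normalization after each convolution?
#' @param clinical_dense Width of the clinical branch embedding.
#' @param fusion_dense Width of the post-fusion dense layer.
#' @param loss `"weighted_bce"` or `"focal"`.
#' @param gamma Focal-loss exponent (ignored for weighted BCE).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size (windows).
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param use_derivative_branch Include the SpO2-derivative branch?
#' @param use_clinical_branch Include the clinical branch? (`FALSE` gives
#'   the signals-only baseline.)
#' @param seed Seed controlling initialization, dropout and batch order.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(16, 32), kernel = 7, pool = 1L,
                         dropout = 0.3,
                         batchnorm = TRUE, clinical_dense = 32,
                         fusion_dense = 64, loss = c("weighted_bce", "focal"),
                         gamma = 2, lr = 1e-3, batch_size = 32, epochs = 30,
                         patience = 15, use_derivative_branch = TRUE,
                         use_clinical_branch = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(kernel %% 2 == 1, dropout >= 0, dropout < 1, gamma >= 0,
            length(conv_filters) >= 1, all(conv_filters >= 1),
            pool >= 1, pool == round(pool))
  structure(as.list(environment()), class = "model_config")
}

#' Inverse-frequency class weights
#'
#' `w_j = (N - n_j) / n_j` with `n_j` the number of positive training
#' patients for label j: rare labels weigh more, a balanced label weighs 1.
#'
#' @param labels N x 3 binary label matrix (training patients).
#' @return Positive weight vector of length 3.
#' @export
class_weights <- function(labels) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  pos <- colSums(labels)
  if (any(pos == 0))
    stop("label(s) without positives in training data: ",
         paste(colnames(labels)[pos == 0], collapse = ", "),
         "; regenerate or resample the split")
  stats::setNames((n - pos) / pos,
                  colnames(labels) %||% LABELS[seq_len(ncol(labels))])
}

#' Class-weighted multi-label loss
#'
#' `weighted_bce`: mean over samples and labels of
#' `-(w_j y log p + (1-y) log(1-p))`. `focal` adds the `(1-p_t)^gamma`
#' modulation to both terms. Probabilities are clipped to
#' `[1e-7, 1-1e-7]`.
#'
#' @param prob N x q probability matrix.
#' @param truth N x q binary matrix.
#' @param w Positive per-label weights (length q).
#' @param mode `"weighted_bce"` or `"focal"`.
#' @param gamma Focal exponent.
#' @return Scalar loss.
#' @export
weighted_loss <- function(prob, truth, w = rep(1, ncol(as.matrix(truth))),
                          mode = c("weighted_bce", "focal"), gamma = 2) {
  mode <- match.arg(mode)
  p <- pmin(pmax(as.matrix(prob), 1e-7), 1 - 1e-7)
  y <- as.matrix(truth)
  W <- matrix(w, nrow(p), ncol(p), byrow = TRUE)
  ll <- if (mode == "weighted_bce") {
    -(W * y * log(p) + (1 - y) * log(1 - p))
  } else {
    -(W * y * (1 - p)^gamma * log(p) + (1 - y) * p^gamma * log(1 - p))
  }
  mean(ll)
}

# Gradient of the mean loss w.r.t. the logits.
loss_grad_logits <- function(p, y, w, mode, gamma) {
  W <- matrix(w, nrow(p), ncol(p), byrow = TRUE)
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  g <- if (mode == "weighted_bce") {
    -W * y * (1 - p) + (1 - y) * p
  } else {
    y * W * (gamma * p * (1 - p)^gamma * log(p) - (1 - p)^(gamma + 1)) +
      (1 - y) * (p^(gamma + 1) - gamma * p^gamma * (1 - p) * log(1 - p))
  }
  g / length(p)
}

active_branches <- function(config) {
  br <- c("spo2", "fp0")
  if (config$use_derivative_branch) br <- c("spo2", "dspo2", "fp0")
  br
}

#' Build an untrained model
#'
#' Parameter initialization is fully determined by `config$seed`.
#'
#' @param config A [model_config()].
#' @param window_samples Samples per window (kernel must fit).
#' @param n_clinical Number of clinical features (11 canonical columns).
#' @return A `cnn_model` list (`params`, `bn`, `config`, `n_param`, ...).
#' @export
build_model <- function(config, window_samples, n_clinical) {
  stopifnot(inherits(config, "model_config"))
  if (config$kernel > window_samples)
    stop("kernel (", config$kernel, ") larger than window (",
         window_samples, " samples)")
  set.seed(config$seed)
  params <- list()
  bn <- list()
  gap_width <- config$conv_filters[length(config$conv_filters)]
  for (br in active_branches(config)) {
    C <- 1L
    bn[[br]] <- list()
    for (i in seq_along(config$conv_filters)) {
      Fo <- config$conv_filters[i]
      init <- nn_init_conv(config$kernel, C, Fo)
      params[[paste0(br, ".conv_W_", i)]] <- init$W
      params[[paste0(br, ".conv_b_", i)]] <- init$b
      if (config$batchnorm) {
        params[[paste0(br, ".bn_gamma_", i)]] <- rep(1, Fo)
        params[[paste0(br, ".bn_beta_", i)]] <- rep(0, Fo)
        bn[[br]][[i]] <- list(run_mean = rep(0, Fo), run_var = rep(1, Fo))
      }
      C <- Fo
    }
  }
  concat <- gap_width * length(active_branches(config))
  if (config$use_clinical_branch) {
    init <- nn_init_dense(n_clinical, config$clinical_dense)
    params[["clin.W"]] <- init$W
    params[["clin.b"]] <- init$b
    concat <- concat + config$clinical_dense
  }
  init <- nn_init_dense(concat, config$fusion_dense)
  params[["fuse.W"]] <- init$W
  params[["fuse.b"]] <- init$b
  init <- nn_init_dense(config$fusion_dense, 3L)
  params[["out.W"]] <- init$W
  params[["out.b"]] <- init$b
  structure(list(
    config = config, params = params, bn = bn,
    window_samples = window_samples, n_clinical = n_clinical,
    input_norm = NULL, class_weights = rep(1, 3),
    n_param = sum(vapply(params, length, 0L)),
    fused_width = concat
  ), class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %d branches (%s)%s, %d parameters, fused width %d\n",
    length(active_branches(x$config)),
    paste(active_branches(x$config), collapse = "+"),
    if (x$config$use_clinical_branch) " + clinical" else "",
    x$n_param, x$fused_width
  ))
  invisible(x)
}

branch_layers_from_params <- function(model, br) {
  cf <- model$config
  lapply(seq_along(cf$conv_filters), function(i) {
    l <- list(conv = list(W = model$params[[paste0(br, ".conv_W_", i)]],
                          b = model$params[[paste0(br, ".conv_b_", i)]]))
    if (cf$batchnorm) {
      l$bn_gamma <- model$params[[paste0(br, ".bn_gamma_", i)]]
      l$bn_beta <- model$params[[paste0(br, ".bn_beta_", i)]]
      l$bn_stats <- model$bn[[br]][[i]]
    }
    l
  })
}

normalize_inputs <- function(model, data, idx) {
  lapply(stats::setNames(nm = active_branches(model$config)), function(br) {
    x <- data[[br]][idx, , drop = FALSE]
    nrm <- model$input_norm[[br]]
    (x - nrm$mean) / nrm$sd
  })
}

# Fused forward(+backward) step through the compiled kernel. `y = NULL`
# gives a forward-only evaluation pass.
nn_step_cpp <- function(model, data, idx, training, y = NULL,
                        mask_seed = 0L) {
  cf <- model$config
  xs <- normalize_inputs(model, data, idx)
  clin <- if (cf$use_clinical_branch) data$clin[idx, , drop = FALSE] else NULL
  .cpp_nn_step(xs, clin, model$params, model$bn,
               as.integer(cf$conv_filters), as.integer(cf$kernel),
               as.integer(cf$pool %||% 1L), cf$batchnorm, cf$dropout,
               if (is.null(y)) matrix(0, 0, 3) else y,
               as.numeric(model$class_weights), cf$loss, cf$gamma,
               training, as.integer(mask_seed))
}

model_forward <- function(model, data, idx, training = FALSE) {
  cf <- model$config
  xs <- normalize_inputs(model, data, idx)
  fwd <- list()
  gaps <- list()
  for (br in active_branches(cf)) {
    layers <- branch_layers_from_params(model, br)
    f <- branch_forward(xs[[br]], layers, cf$kernel, cf$dropout,
                        training, cf$batchnorm, pool = cf$pool %||% 1L)
    if (training && cf$batchnorm) {
      for (i in seq_along(f$layers))
        model$bn[[br]][[i]] <- f$layers[[i]]$bn_stats
    }
    fwd[[br]] <- f
    gaps[[br]] <- f$gap
  }
  feat <- do.call(cbind, gaps)
  clin_cache <- NULL
  if (cf$use_clinical_branch) {
    zc <- add_cols(data$clin[idx, , drop = FALSE] %*% model$params[["clin.W"]],
                   model$params[["clin.b"]])
    mc <- zc > 0
    hc <- zc * mc
    clin_cache <- list(mask = mc, h = hc)
    feat <- cbind(feat, hc)
  }
  zf <- add_cols(feat %*% model$params[["fuse.W"]], model$params[["fuse.b"]])
  mf <- zf > 0
  hf <- zf * mf
  dmask <- if (training) dropout_mask(dim(hf), cf$dropout) else NULL
  hfd <- if (is.null(dmask)) hf else hf * dmask
  logits <- add_cols(hfd %*% model$params[["out.W"]], model$params[["out.b"]])
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob, model = model,
       cache = list(fwd = fwd, feat = feat, clin_cache = clin_cache,
                    mf = mf, hfd = hfd, dmask = dmask, idx = idx))
}

model_backward <- function(model, data, cache, dlogits) {
  cf <- model$config
  grads <- list()
  grads[["out.W"]] <- crossprod(cache$hfd, dlogits)
  grads[["out.b"]] <- colSums(dlogits)
  dhfd <- dlogits %*% t(model$params[["out.W"]])
  if (!is.null(cache$dmask)) dhfd <- dhfd * cache$dmask
  dzf <- dhfd * cache$mf
  grads[["fuse.W"]] <- crossprod(cache$feat, dzf)
  grads[["fuse.b"]] <- colSums(dzf)
  dfeat <- dzf %*% t(model$params[["fuse.W"]])
  gap_w <- cf$conv_filters[length(cf$conv_filters)]
  off <- 0L
  for (br in active_branches(cf)) {
    dgap <- dfeat[, (off + 1L):(off + gap_w), drop = FALSE]
    off <- off + gap_w
    layers <- branch_layers_from_params(model, br)
    bg <- branch_backward(dgap, cache$fwd[[br]], layers, cf$kernel,
                          cf$batchnorm)
    for (nm in names(bg)) grads[[paste0(br, ".", nm)]] <- bg[[nm]]
  }
  if (cf$use_clinical_branch) {
    dh <- dfeat[, (off + 1L):(off + cf$clinical_dense), drop = FALSE]
    dzc <- dh * cache$clin_cache$mask
    grads[["clin.W"]] <- crossprod(data$clin[cache$idx, , drop = FALSE], dzc)
    grads[["clin.b"]] <- colSums(dzc)
  }
  grads
}

#' Assemble a window-level training dataset
#'
#' Stacks the complete (mask-free) windows of every patient, repeating the
#' patient's normalized clinical feature row and label vector per window.
#'
#' @param windows_list List of `window_set`s (one per patient).
#' @param features Normalized feature data frame (`patient_id` + 11
#'   columns), e.g. `assemble_and_normalize(...)$matrix`.
#' @param labels Data frame with `patient_id` and the three label columns.
#' @param max_windows_per_patient Optional cap; windows are subsampled
#'   deterministically per patient when a patient has more.
#' @return List with matrices `spo2`, `dspo2`, `fp0`, `clin`, `y` and the
#'   `patient_id` of every window row.
#' @export
window_dataset <- function(windows_list, features, labels,
                           max_windows_per_patient = NULL) {
  rows <- list()
  for (ws in windows_list) {
    keep <- which(ws$complete)
    if (!length(keep)) next
    if (!is.null(max_windows_per_patient) &&
        length(keep) > max_windows_per_patient) {
      keep <- keep[round(seq(1, length(keep),
                             length.out = max_windows_per_patient))]
    }
    rows[[length(rows) + 1L]] <- list(id = ws$patient_id, keep = keep,
                                      ws = ws)
  }
  if (!length(rows)) stop("no complete windows in any patient")
  ids <- unlist(lapply(rows, function(r) rep(r$id, length(r$keep))))
  stack <- function(field) do.call(rbind, lapply(rows, function(r)
    r$ws[[field]][r$keep, , drop = FALSE]))
  fmat <- as.matrix(features[match(ids, features$patient_id),
                             feature_columns()])
  ymat <- as.matrix(labels[match(ids, labels$patient_id), LABELS])
  if (anyNA(fmat) || anyNA(ymat))
    stop("windows reference patients missing from features/labels")
  list(spo2 = stack("spo2"), dspo2 = stack("dspo2"), fp0 = stack("fp0"),
       clin = fmat, y = ymat, patient_id = ids)
}

patient_level_labels <- function(data, ids) {
  keep <- !duplicated(data$patient_id) & data$patient_id %in% ids
  m <- data$y[keep, , drop = FALSE]
  rownames(m) <- data$patient_id[keep]
  colnames(m) <- LABELS
  m
}

#' Train the model
#'
#' Minibatch Adam on the training windows with early stopping on validation
#' macro AUC-PR (patient-level, mean-aggregated window probabilities);
#' the best-epoch parameters are restored. Per-channel input normalization
#' and the inverse-frequency class weights are estimated on the training
#' split only. Fully deterministic given `config$seed`.
#'
#' @param model A [build_model()] result.
#' @param data A [window_dataset()].
#' @param split List with `train` and `val` patient-id vectors (patient
#'   level; a patient's windows never straddle subsets).
#' @param verbose Print per-epoch progress?
#' @param engine `"cpp"` (compiled fused step, default) or `"r"` (the pure-R
#'   reference path; identical up to dropout mask generation).
#' @return List with `model` (trained) and `history` (per-epoch data frame).
#' @export
train_cnn <- function(model, data, split, verbose = FALSE,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cf <- model$config
  stopifnot(length(intersect(split$train, split$val)) == 0)
  tr_idx <- which(data$patient_id %in% split$train)
  va_idx <- which(data$patient_id %in% split$val)
  if (!length(tr_idx)) stop("no training windows")
  model$input_norm <- lapply(stats::setNames(nm = active_branches(cf)),
    function(br) {
      x <- data[[br]][tr_idx, , drop = FALSE]
      s <- stats::sd(x)
      list(mean = mean(x), sd = if (s > 0) s else 1)
    })
  y_tr_pat <- patient_level_labels(data, split$train)
  model$class_weights <- class_weights(y_tr_pat)
  if (length(va_idx)) {
    y_va_pat <- patient_level_labels(data, split$val)
    va_single <- colSums(y_va_pat) == 0 | colSums(y_va_pat) == nrow(y_va_pat)
    if (any(va_single))
      warning("validation label(s) single-class, excluded from early ",
              "stopping: ", paste(LABELS[va_single], collapse = ", "))
  }
  opt <- adam_init(model$params)
  set.seed(cf$seed + 1L)
  best <- list(metric = -Inf, params = model$params, bn = model$bn,
               epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auc_pr = numeric(0))
  wait <- 0L
  for (epoch in seq_len(cf$epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / cf$batch_size)
    tot_loss <- 0
    for (b in seq_len(nb)) {
      bi <- ord[((b - 1L) * cf$batch_size + 1L):min(b * cf$batch_size,
                                                    length(ord))]
      yb <- data$y[bi, , drop = FALSE]
      if (engine == "cpp") {
        st <- nn_step_cpp(model, data, bi, training = TRUE, y = yb,
                          mask_seed = sample.int(2147483647L, 1L))
        model$bn <- st$bn
        grads <- st$grads
        batch_loss <- st$loss
      } else {
        fw <- model_forward(model, data, bi, training = TRUE)
        model <- fw$model
        batch_loss <- weighted_loss(fw$prob, yb, model$class_weights,
                                    cf$loss, cf$gamma)
        dlog <- loss_grad_logits(fw$prob, yb, model$class_weights, cf$loss,
                                 cf$gamma)
        grads <- model_backward(model, data, fw$cache, dlog)
      }
      tot_loss <- tot_loss + batch_loss * length(bi)
      upd <- adam_step(model$params, grads, opt, cf$lr)
      model$params <- upd$params
      opt <- upd$state
    }
    train_loss <- tot_loss / length(tr_idx)
    val_metric <- NA_real_
    if (length(va_idx)) {
      pv <- predict_patients(model, data, ids = split$val)
      use <- !va_single
      val_metric <- if (any(use)) {
        suppressWarnings(auc_metrics(pv$prob[, use, drop = FALSE],
                                     y_va_pat[rownames(pv$prob), use,
                                              drop = FALSE])$auc_pr_macro)
      } else -train_loss
    } else {
      val_metric <- -train_loss
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_auc_pr = val_metric))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val AUC-PR %.4f",
                      epoch, train_loss, val_metric))
    if (is.finite(val_metric) && val_metric > best$metric + 1e-9) {
      best <- list(metric = val_metric, params = model$params,
                   bn = model$bn, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cf$patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$best_epoch <- best$epoch
  list(model = model, history = history)
}

#' Window and patient-level predictions
#'
#' Patient probability is the mean of the patient's window probabilities;
#' labels are thresholded at `threshold`.
#'
#' @param model Trained [build_model()]/[train_cnn()] model.
#' @param data A [window_dataset()].
#' @param ids Patients to score (default: all in `data`).
#' @param threshold Decision threshold (default 0.5).
#' @param engine `"cpp"` or `"r"` forward path (numerically identical).
#' @return List with `prob` (patients x 3), `labels` (binary),
#'   `window_prob` and `window_id`.
#' @export
predict_patients <- function(model, data, ids = NULL, threshold = 0.5,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(ids)) ids <- unique(data$patient_id)
  idx <- which(data$patient_id %in% ids)
  missing_ids <- setdiff(ids, data$patient_id)
  if (length(missing_ids))
    stop("patient(s) without windows: ", paste(missing_ids, collapse = ", "))
  probs <- matrix(NA_real_, length(idx), 3L)
  chunk <- 512L
  for (s in seq(1L, length(idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(idx))
    probs[s:e, ] <- if (engine == "cpp") {
      nn_step_cpp(model, data, idx[s:e], training = FALSE)$prob
    } else {
      model_forward(model, data, idx[s:e], training = FALSE)$prob
    }
  }
  pid <- data$patient_id[idx]
  agg <- rowsum(probs, pid) / as.vector(table(pid)[sort(unique(pid))])
  agg <- agg[match(sort(unique(pid)), rownames(agg)), , drop = FALSE]
  colnames(agg) <- LABELS
  list(prob = agg, labels = (agg >= threshold) * 1L,
       window_prob = probs, window_id = pid)
}

#' Random hyperparameter search
#'
#' Seeded random search over a bounded space, maximizing validation macro
#' AUC-PR. Each space entry is a vector of candidate values; one value is
#' drawn per trial.
#'
#' @param data A [window_dataset()].
#' @param split List with `train`, `val` patient ids.
#' @param space Named list of candidate-value vectors for [model_config()]
#'   fields.
#' @param n_trials Number of trials (>= 1).
#' @param seed Search seed.
#' @param n_clinical Number of clinical features.
#' @return List with `best_config`, `best_metric` and `trials` (data frame).
#' @export
tune_cnn <- function(data, split, space = list(lr = c(3e-4, 1e-3, 3e-3),
                                               dropout = c(0.1, 0.3, 0.5)),
                     n_trials = 5, seed = 1L,
                     n_clinical = length(feature_columns())) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  draws <- lapply(seq_len(n_trials), function(i)
    lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
  best <- list(metric = -Inf, config = NULL)
  trials <- list()
  for (i in seq_len(n_trials)) {
    args <- draws[[i]]
    args$seed <- seed + i
    cfg <- do.call(model_config, args)
    mdl <- build_model(cfg, ncol(data$spo2), n_clinical)
    res <- train_cnn(mdl, data, split)
    metric <- max(res$history$val_auc_pr, na.rm = TRUE)
    trials[[i]] <- data.frame(trial = i, metric = metric,
                              as.data.frame(draws[[i]]))
    if (metric > best$metric) best <- list(metric = metric, config = cfg)
  }
  if (is.null(best$config)) stop("no completed trials")
  list(best_config = best$config, best_metric = best$metric,
       trials = do.call(rbind, trials))
}
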