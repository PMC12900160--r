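# Apnea-desaturation event detection, cessation/desaturation pairing and the
# engineered per-patient features.

# O(n) sliding-window maximum (block prefix/suffix cummax trick).
# Right-aligned: out[i] = max(x[max(1, i-k+1) .. i]). NA treated as -Inf.
roll_max_right <- function(x, k) {
  n <- length(x)
  k <- max(1L, min(as.integer(k), n))
  if (k == 1L) return(x)
  xx <- x
  xx[!is.finite(xx)] <- -Inf
  nb <- ceiling(n / k)
  pad <- nb * k - n
  xp <- c(xx, rep(-Inf, pad))
  m <- matrix(xp, nrow = k)
  left <- apply(m, 2, cummax)                      # block prefix max
  right <- apply(m[k:1, , drop = FALSE], 2, cummax)[k:1, , drop = FALSE]
  left <- as.vector(left)[seq_len(n)]
  right <- as.vector(right)[seq_len(n)]
  i <- seq_len(n)
  j <- i - k + 1L
  out <- left
  ok <- j >= 1L
  out[ok] <- pmax(right[j[ok]], left[i[ok]])
  out
}

# Centred window of about k samples
roll_max_center <- function(x, k) {
  h <- as.integer(k) %/% 2L
  r <- roll_max_right(x, 2L * h + 1L)
  n <- length(x)
  # shift left by h so the window is centred
  c(r[(h + 1L):n], rep(r[n], h))
}

#' Event-detection configuration
#'
#' @param min_depth Minimum desaturation depth (% SpO2).
#' @param min_duration Minimum event duration (s) for both desaturations and
#'   cessations.
#' @param amp_fraction Airflow cessation threshold as a fraction of baseline
#'   breathing amplitude (0.10 = at least 90 % amplitude reduction).
#' @param max_pair_delay Longest allowed onset delay t3 - t1 (s) when pairing
#'   a desaturation to a cessation.
#' @param baseline_window SpO2 baseline horizon (s): rolling maximum over the
#'   preceding window.
#' @param env_window Airflow envelope horizon (s); must cover at least one
#'   breathing cycle.
#' @param amp_baseline_window Horizon (s) of the rolling-median baseline
#'   amplitude of the airflow envelope.
#' @param onset_margin Threshold below baseline (%) that delimits candidate
#'   desaturation runs; markers are then extrapolated back to baseline.
#' @param merge_gap Sub-threshold runs separated by less than this many
#'   seconds are merged into one cessation (noise briefly lifting the
#'   envelope above threshold must not split one apnea into several).
#' @return A validated `events_config` list.
#' @export
events_config <- function(min_depth = 3, min_duration = 10,
                          amp_fraction = 0.10, max_pair_delay = 60,
                          baseline_window = 100, env_window = 5,
                          amp_baseline_window = 120, onset_margin = 1,
                          merge_gap = 10) {
  stopifnot(min_depth > 0, min_duration > 0, amp_fraction > 0,
            amp_fraction < 1, max_pair_delay > 0, onset_margin > 0,
            merge_gap >= 0)
  structure(as.list(environment()), class = "events_config")
}

# merge [start, end] index runs whose gaps are shorter than `gap` samples
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (k in 2:nrow(runs)) {
    if (runs[k, 1L] - out[nrow(out), 2L] <= gap) {
      out[nrow(out), 2L] <- runs[k, 2L]
    } else {
      out <- rbind(out, runs[k, , drop = FALSE])
    }
  }
  out
}

#' Detect oxygen desaturation events
#'
#' The local baseline is the rolling maximum of the preceding
#' `baseline_window` seconds. Candidate events are runs below
#' `baseline - onset_margin`; onset (t3) and recovery end (t4) are then
#' linearly extrapolated from the fall and recovery limbs back to the
#' baseline so the markers locate the true start/end of the excursion.
#' Events must reach `min_depth` below baseline and last at least
#' `min_duration` seconds. Masked (`NA`) regions never produce events.
#'
#' @param spo2 Preprocessed SpO2 [psg_trace()].
#' @param config An [events_config()].
#' @return Data frame with one row per event: `t3`, `t4`, `baseline`,
#'   `nadir`, `depth`, `fall_slope`, `nadir_time`.
#' @export
detect_desaturations <- function(spo2, config = events_config()) {
  stopifnot_trace(spo2)
  x <- spo2$samples
  rate <- spo2$rate
  tt <- trace_times(spo2)
  base <- roll_max_right(x, round(config$baseline_window * rate))
  below <- x < base - config$onset_margin
  below[is.na(below)] <- FALSE
  out <- data.frame(t3 = numeric(0), t4 = numeric(0), baseline = numeric(0),
                    nadir = numeric(0), depth = numeric(0),
                    fall_slope = numeric(0), nadir_time = numeric(0))
  if (!any(below)) return(out)
  runs <- invalid_runs(below)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    seg <- x[a:b]
    if (anyNA(seg)) next                      # masked region inside run
    bl <- base[a]
    nadir <- min(seg)
    depth <- bl - nadir
    # first arrival at the nadir level = end of the fall phase (the minimum
    # of a flat plateau is otherwise located arbitrarily within it)
    tol <- max(0.05 * depth, 0.1)
    i_nad <- a + which(seg <= nadir + tol)[1L] - 1L
    if (depth < config$min_depth) next
    t_on <- tt[max(a - 1L, 1L)]               # last sample at/above margin
    t_off <- tt[min(b + 1L, length(x))]
    margin_lvl <- bl - config$onset_margin
    # local limb slopes from the crossings of two levels one margin apart,
    # then extrapolate each limb back to the baseline
    lvl2 <- bl - 2 * config$onset_margin
    fall_idx <- a:i_nad
    i_b <- fall_idx[which(x[fall_idx] <= lvl2)[1L]]
    fall_dt <- if (!is.na(i_b) && tt[i_b] > t_on) tt[i_b] - t_on
               else (tt[i_nad] - t_on) * config$onset_margin /
                 max(margin_lvl - nadir, config$onset_margin)
    rec_idx <- i_nad:b
    below2 <- which(x[rec_idx] <= lvl2)
    i_a <- if (length(below2)) rec_idx[below2[length(below2)]] else NA_integer_
    rec_dt <- if (!is.na(i_a) && tt[i_a] < t_off) t_off - tt[i_a]
              else (t_off - tt[i_nad]) * config$onset_margin /
                max(margin_lvl - nadir, config$onset_margin)
    t3 <- t_on - fall_dt
    t4 <- t_off + rec_dt
    if (t4 - t3 < config$min_duration) next
    out <- rbind(out, data.frame(
      t3 = t3, t4 = t4, baseline = bl, nadir = nadir, depth = depth,
      fall_slope = depth / max(tt[i_nad] - t3, 1 / rate),
      nadir_time = tt[i_nad]
    ))
  }
  out
}

#' Detect airflow cessation events
#'
#' The breathing-amplitude envelope is the centred rolling maximum of the
#' rectified airflow over `env_window` seconds; the local baseline amplitude
#' is a rolling median of that envelope (floored at half its global 95th
#' percentile so dense event clusters cannot drag the baseline down).
#' Cessations are runs where the envelope stays below
#' `amp_fraction x baseline` for at least `min_duration` seconds; run edges
#' are corrected for the envelope half-window.
#'
#' @param fp0 Preprocessed airflow [psg_trace()].
#' @param config An [events_config()].
#' @return Data frame with one row per event: `t1`, `t2`.
#' @export
detect_cessations <- function(fp0, config = events_config()) {
  stopifnot_trace(fp0)
  x <- fp0$samples
  rate <- fp0$rate
  tt <- trace_times(fp0)
  k_env <- max(3L, round(config$env_window * rate))
  env <- roll_max_center(abs(x), k_env)
  env[!is.finite(env)] <- NA_real_
  g95 <- stats::quantile(env, 0.95, na.rm = TRUE, names = FALSE)
  if (!is.finite(g95) || g95 < 1e-6)
    stop("no breathing oscillation found in FP0; cannot establish a baseline amplitude")
  base_amp <- pmax(rolling_median(env, round(config$amp_baseline_window * rate)),
                   0.75 * g95)
  below <- env < config$amp_fraction * base_amp
  below[is.na(below)] <- FALSE
  out <- data.frame(t1 = numeric(0), t2 = numeric(0))
  if (!any(below)) return(out)
  half_w <- (k_env %/% 2L) / rate
  runs <- merge_runs(invalid_runs(below), round(config$merge_gap * rate))
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    t1 <- tt[a] - half_w
    t2 <- tt[b] + half_w
    if (t2 - t1 < config$min_duration) next
    out <- rbind(out, data.frame(t1 = t1, t2 = t2))
  }
  out
}

#' Pair airflow cessations with desaturations
#'
#' Greedy, causal, one-to-one: each cessation (in time order) claims the
#' earliest unclaimed desaturation whose onset t3 falls within
#' `[t1, t1 + max_pair_delay]`. Unpaired events on either side are dropped.
#'
#' @param cessations Data frame from [detect_cessations()].
#' @param desats Data frame from [detect_desaturations()].
#' @param config An [events_config()].
#' @return Data frame with one row per pair: the cessation and desaturation
#'   markers plus `onset_delay` (t3 - t1) and `recovery_delay` (t4 - t2).
#' @export
pair_events <- function(cessations, desats, config = events_config()) {
  empty <- data.frame(t1 = numeric(0), t2 = numeric(0), t3 = numeric(0),
                      t4 = numeric(0), depth = numeric(0),
                      fall_slope = numeric(0), onset_delay = numeric(0),
                      recovery_delay = numeric(0))
  if (!nrow(cessations) || !nrow(desats)) return(empty)
  cess <- cessations[order(cessations$t1), , drop = FALSE]
  des <- desats[order(desats$t3), , drop = FALSE]
  claimed <- rep(FALSE, nrow(des))
  rows <- vector("list", nrow(cess))
  for (i in seq_len(nrow(cess))) {
    ok <- which(!claimed & des$t3 >= cess$t1[i] &
                  des$t3 <= cess$t1[i] + config$max_pair_delay)
    if (!length(ok)) next
    j <- ok[1L]
    claimed[j] <- TRUE
    rows[[i]] <- data.frame(
      t1 = cess$t1[i], t2 = cess$t2[i], t3 = des$t3[j], t4 = des$t4[j],
      depth = des$depth[j], fall_slope = des$fall_slope[j],
      onset_delay = des$t3[j] - cess$t1[i],
      recovery_delay = des$t4[j] - cess$t2[i]
    )
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Engineered per-patient feature vector
#'
#' Event-derived fields are means over the patient's paired events:
#' onset delay (t3 - t1), recovery delay (t4 - t2), cessation duration
#' (t2 - t1), desaturation duration (t4 - t3), desaturation depth, and the
#' per-event fall slope. Clinical fields are copied through. With zero
#' pairs the six event features are `NA` (to be imputed at the cohort
#' median by [assemble_and_normalize()]).
#'
#' @param pairs Data frame from [pair_events()].
#' @param clinical One-row clinical data frame (`Age`, `Gender`, `BMI`,
#'   `AHI`, `HeartRate`, optionally `patient_id`).
#' @return One-row data frame with `patient_id` + the 11 canonical feature
#'   columns.
#' @export
compute_features <- function(pairs, clinical) {
  stopifnot(nrow(clinical) == 1L)
  ev <- if (nrow(pairs)) {
    data.frame(
      t3_t1_mean = mean(pairs$onset_delay),
      t4_t2_mean = mean(pairs$recovery_delay),
      delta_t_FP0_mean = mean(pairs$t2 - pairs$t1),
      delta_t_SpO2_mean = mean(pairs$t4 - pairs$t3),
      mean_delta_SpO2 = mean(pairs$depth),
      mean_slope = mean(pairs$fall_slope)
    )
  } else {
    warning("patient ", clinical$patient_id %||% "?",
            " has no paired events; event features flagged missing")
    data.frame(t3_t1_mean = NA_real_, t4_t2_mean = NA_real_,
               delta_t_FP0_mean = NA_real_, delta_t_SpO2_mean = NA_real_,
               mean_delta_SpO2 = NA_real_, mean_slope = NA_real_)
  }
  cbind(
    data.frame(patient_id = as.character(clinical$patient_id %||% NA)),
    clinical[, c("Age", "Gender", "BMI", "AHI", "HeartRate"), drop = FALSE],
    ev,
    row.names = NULL
  )
}

#' Assemble, impute and z-score the cohort feature matrix
#'
#' Missing event features (patients without paired events) are imputed at
#' the median of the fitting subset. Normalization statistics (mean/SD) are
#' estimated on `fit_ids` only - the training split - and applied to every
#' row; `Gender` passes through unscaled. Zero-variance columns on the fit
#' set pass through with a warning.
#'
#' @param vectors Data frame of stacked [compute_features()] rows.
#' @param fit_ids Patient ids of the fitting (training) subset; defaults to
#'   all rows.
#' @return List with `matrix` (normalized feature data frame, `patient_id`
#'   first) and `scaler` (reusable via [apply_scaler()]).
#' @export
assemble_and_normalize <- function(vectors, fit_ids = vectors$patient_id) {
  check_schema(names(vectors), feature_columns(with_id = TRUE),
               "feature matrix")
  stopifnot(length(fit_ids) >= 1L)
  df <- vectors[, feature_columns(with_id = TRUE), drop = FALSE]
  fit <- df[df$patient_id %in% fit_ids, , drop = FALSE]
  if (!nrow(fit)) stop("fit_ids match no rows")
  scaled_cols <- setdiff(feature_columns(), "Gender")
  medians <- vapply(fit[scaled_cols], stats::median, 0, na.rm = TRUE)
  for (cn in scaled_cols) {
    miss <- is.na(df[[cn]])
    if (any(miss)) df[[cn]][miss] <- medians[[cn]]
  }
  center <- vapply(df[df$patient_id %in% fit_ids, scaled_cols], mean, 0)
  scale_ <- vapply(df[df$patient_id %in% fit_ids, scaled_cols], stats::sd, 0)
  skipped <- scaled_cols[!is.finite(scale_) | scale_ == 0]
  if (length(skipped))
    warning("zero-variance column(s) on the fit set passed through unscaled: ",
            paste(skipped, collapse = ", "))
  scaler <- list(columns = scaled_cols, center = center, scale = scale_,
                 medians = medians, skipped = skipped)
  list(matrix = apply_scaler(scaler, vectors), scaler = scaler)
}

#' Apply a saved feature scaler to new rows
#'
#' @param scaler Scaler from [assemble_and_normalize()].
#' @param vectors Feature data frame (canonical columns).
#' @return Normalized feature data frame.
#' @export
apply_scaler <- function(scaler, vectors) {
  df <- vectors[, feature_columns(with_id = TRUE), drop = FALSE]
  for (cn in scaler$columns) {
    miss <- is.na(df[[cn]])
    if (any(miss)) df[[cn]][miss] <- scaler$medians[[cn]]
    if (!(cn %in% scaler$skipped))
      df[[cn]] <- (df[[cn]] - scaler$center[[cn]]) / scaler$scale[[cn]]
  }
  df
}

#' Detect, pair and summarize events for one preprocessed patient
#'
#' @param pp Output of [preprocess_patient()].
#' @param clinical One-row clinical data frame for the patient.
#' @param config An [events_config()].
#' @return List with `desats`, `cessations`, `pairs` and `features`
#'   (one-row data frame from [compute_features()]).
#' @export
patient_events <- function(pp, clinical, config = events_config()) {
  des <- detect_desaturations(pp$spo2, config)
  ces <- detect_cessations(pp$fp0, config)
  pairs <- pair_events(ces, des, config)
  list(desats = des, cessations = ces, pairs = pairs,
       features = suppressWarnings(compute_features(pairs, clinical)))
}
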