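# Raw-trace conditioning: uniform resampling, artifact repair, filtering,
# derivative estimation and fixed-length windowing.

#' Preprocessing configuration
#'
#' @param target_rate Uniform output rate, Hz.
#' @param spo2_valid_range Physiologically valid SpO2 interval (%).
#' @param max_gap_interp Longest invalid run (s) that is repaired by linear
#'   interpolation; longer runs are masked (`NA`) and excluded from event
#'   detection.
#' @param spike_rate_limit SpO2 slew-rate limit (%/s); faster changes are
#'   treated as sensor spikes. Physiological desaturation slopes are an
#'   order of magnitude below the default.
#' @param lowpass_cutoff_spo2,lowpass_cutoff_fp0 Zero-phase 4th-order
#'   Butterworth low-pass cutoffs (Hz) for the two channels.
#' @param ma_window Moving-average smoothing window, samples.
#' @param savgol_window,savgol_order Savitzky-Golay window (odd, samples) and
#'   polynomial order used for derivative estimation.
#' @param window_length,window_stride Model window length and stride, seconds.
#' @param drift_window Rolling horizon (s) for airflow baseline-drift removal.
#' @return A validated `preprocess_config` list.
#' @export
preprocess_config <- function(target_rate = 5,
                              spo2_valid_range = c(50, 100),
                              max_gap_interp = 5,
                              spike_rate_limit = 4,
                              lowpass_cutoff_spo2 = 0.5,
                              lowpass_cutoff_fp0 = 1.0,
                              ma_window = 5,
                              savgol_window = 11,
                              savgol_order = 3,
                              window_length = 60,
                              window_stride = 30,
                              drift_window = 30) {
  stopifnot(target_rate > 0,
            length(spo2_valid_range) == 2,
            spo2_valid_range[1] < spo2_valid_range[2],
            max_gap_interp >= 0,
            spike_rate_limit > 0,
            savgol_window %% 2 == 1,
            savgol_window > savgol_order,
            window_stride <= window_length, window_stride > 0)
  structure(as.list(environment()), class = "preprocess_config")
}

#' Resample a trace to a uniform target rate
#'
#' Linear interpolation onto the target grid. Masked (`NA`) regions of the
#' input stay masked on the output grid. Upsampling is permitted but noted
#' with a message.
#'
#' @param trace A [psg_trace()].
#' @param target_rate Output rate, Hz.
#' @return A [psg_trace()] at `target_rate`.
#' @export
resample_trace <- function(trace, target_rate) {
  stopifnot_trace(trace)
  stopifnot(target_rate > 0)
  if (abs(trace$rate - target_rate) < 1e-12) return(trace)
  if (target_rate > trace$rate)
    message("resample_trace: upsampling ", trace$channel, " from ",
            trace$rate, " to ", target_rate, " Hz")
  t_in <- trace_times(trace)
  n_out <- floor((length(trace$samples) - 1L) / trace$rate * target_rate) + 1L
  t_out <- trace$start_offset + (seq_len(n_out) - 1L) / target_rate
  x <- trace$samples
  bad <- !is.finite(x)
  if (all(bad)) stop("cannot resample an all-masked trace")
  y <- stats::approx(t_in[!bad], x[!bad], t_out, rule = 2)$y
  if (any(bad)) {
    m <- stats::approx(t_in, as.numeric(bad), t_out, method = "constant",
                       f = 0, rule = 2)$y
    y[m > 0] <- NA_real_
  }
  out <- trace
  out$rate <- target_rate
  out$samples <- y
  out
}

invalid_runs <- function(bad) {
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

repair_pass <- function(x, rate, valid_range, spike_limit, max_gap) {
  bad <- !is.finite(x)
  if (!is.null(valid_range))
    bad <- bad | x < valid_range[1] | x > valid_range[2]
  if (!is.null(spike_limit)) {
    # a spike is an isolated excursion: a fast change immediately followed
    # by a fast change in the opposite direction (a monotone physiological
    # desaturation never shows this signature)
    d <- diff(x) * rate
    d[!is.finite(d)] <- 0
    n <- length(x)
    up_down <- c(FALSE, abs(d[-(n - 1L)]) > spike_limit &
                          abs(d[-1L]) > spike_limit / 2 &
                          sign(d[-(n - 1L)]) != sign(d[-1L]), FALSE)
    bad <- bad | up_down
  }
  log <- data.frame(type = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  if (!any(bad)) return(list(x = x, log = log, changed = FALSE))
  if (all(bad)) stop("unrecoverable trace: every sample is invalid")
  runs <- invalid_runs(bad)
  good_idx <- which(!bad)
  n <- length(x)
  changed <- FALSE
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1L]; b <- runs[k, 2L]
    gap_s <- (b - a + 1L) / rate
    if (gap_s > max_gap && all(is.na(x[a:b]))) next   # already masked
    changed <- TRUE
    if (gap_s <= max_gap) {
      left <- good_idx[good_idx < a]
      right <- good_idx[good_idx > b]
      if (length(left) && length(right)) {
        i0 <- max(left); i1 <- min(right)
        x[a:b] <- x[i0] + (x[i1] - x[i0]) * ((a:b) - i0) / (i1 - i0)
      } else if (length(left)) {
        x[a:b] <- x[max(left)]
      } else {
        x[a:b] <- x[min(right)]
      }
      type <- "interpolated"
    } else {
      x[a:b] <- NA_real_
      type <- "masked"
    }
    log <- rbind(log, data.frame(type = type, start_s = (a - 1L) / rate,
                                 end_s = b / rate))
  }
  list(x = x, log = log, changed = changed)
}

rolling_median <- function(x, k) {
  # centred running median (Turlach algorithm via stats::runmed); NA runs are
  # bridged by linear interpolation for the purpose of drift estimation only
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  bad <- !is.finite(x)
  if (any(bad)) {
    if (all(bad)) return(rep(0, length(x)))
    idx <- seq_along(x)
    x[bad] <- stats::approx(idx[!bad], x[!bad], idx[bad], rule = 2)$y
  }
  if (k >= length(x)) return(rep(stats::median(x), length(x)))
  as.numeric(stats::runmed(x, k, endrule = "median"))
}

#' Repair sensor artifacts in a trace
#'
#' For SpO2: samples outside the valid physiological range, non-finite
#' samples and slew-rate spikes are invalidated; invalid runs no longer than
#' `max_gap_interp` are linearly interpolated, longer runs are masked (`NA`)
#' and reported. Detection and interpolation are iterated to a fixpoint so
#' the operation is idempotent. For FP0: short invalid runs are repaired the
#' same way and baseline drift is removed by subtracting a rolling median
#' (applied once; re-running the repair is a no-op).
#'
#' @param trace A [psg_trace()].
#' @param config A [preprocess_config()].
#' @return List with `trace` (repaired) and `log` (data frame of repairs).
#' @export
repair_artifacts <- function(trace, config) {
  stopifnot_trace(trace)
  x <- trace$samples
  log <- data.frame(type = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  is_spo2 <- trace$channel == "SpO2"
  for (iter in 1:10) {
    res <- repair_pass(
      x, trace$rate,
      valid_range = if (is_spo2) config$spo2_valid_range else NULL,
      spike_limit = if (is_spo2) config$spike_rate_limit else NULL,
      max_gap = config$max_gap_interp
    )
    x <- res$x
    log <- rbind(log, res$log)
    if (!res$changed) break
    if (iter == 10) warning("repair_artifacts: fixpoint not reached in 10 passes")
  }
  out <- trace
  if (!is_spo2 && !isTRUE(attr(trace$samples, "drift_removed"))) {
    k <- round(config$drift_window * trace$rate)
    drift <- rolling_median(x, k)
    drift[!is.finite(drift)] <- 0
    keep_na <- !is.finite(x)
    x <- x - drift
    x[keep_na] <- NA_real_
    attr(x, "drift_removed") <- TRUE
  } else if (!is_spo2) {
    attr(x, "drift_removed") <- TRUE
  }
  out$samples <- x
  list(trace = out, log = log)
}

filter_segments <- function(x, fun, min_len) {
  ok <- is.finite(x)
  if (all(ok)) return(fun(x))
  out <- x
  valid_runs <- invalid_runs(ok)
  for (k in seq_len(nrow(valid_runs))) {
    a <- valid_runs[k, 1L]; b <- valid_runs[k, 2L]
    if (b - a + 1L >= min_len) out[a:b] <- fun(x[a:b])
  }
  out
}

#' Smooth a repaired trace
#'
#' Composition of a zero-phase 4th-order Butterworth low-pass (channel-specific
#' cutoff) and a centred moving average. Masked regions are left untouched;
#' each contiguous valid segment is filtered independently.
#'
#' @param trace A repaired, uniformly sampled [psg_trace()].
#' @param config A [preprocess_config()].
#' @return Filtered [psg_trace()] of identical length.
#' @export
filter_trace <- function(trace, config) {
  stopifnot_trace(trace)
  n <- length(trace$samples)
  if (config$ma_window > n || config$savgol_window > n)
    stop("filter window longer than trace (", n, " samples)")
  cutoff <- if (trace$channel == "SpO2") config$lowpass_cutoff_spo2
            else config$lowpass_cutoff_fp0
  nyq <- trace$rate / 2
  lp <- if (cutoff < nyq) {
    bf <- signal::butter(4, cutoff / nyq, type = "low")
    function(x) {
      # remove the mean (filtfilt starts from zero initial conditions, so a
      # DC offset would ring) and odd-reflect at both ends so the padded
      # signal stays value- and slope-continuous
      n <- length(x)
      mu <- mean(x)
      x0 <- x - mu
      p <- min(n - 1L, as.integer(round(10 * trace$rate)))
      if (p < 3L) return(as.numeric(signal::filtfilt(bf, x0)) + mu)
      xp <- c(2 * x0[1] - x0[(p + 1L):2L], x0,
              2 * x0[n] - x0[(n - 1L):(n - p)])
      as.numeric(signal::filtfilt(bf, xp))[(p + 1L):(p + n)] + mu
    }
  } else identity
  k <- max(1L, as.integer(config$ma_window))
  ma <- function(x) {
    half <- (k - 1L) %/% 2L
    xp <- c(rep(x[1], half), x, rep(x[length(x)], k - 1L - half))
    as.numeric(stats::filter(xp, rep(1 / k, k), sides = 1))[k:(length(xp))]
  }
  fun <- function(x) ma(lp(x))
  out <- trace
  out$samples <- filter_segments(trace$samples, fun, min_len = 25L)
  out
}

#' Savitzky-Golay first derivative of an SpO2 trace
#'
#' @param trace A filtered SpO2 [psg_trace()].
#' @param config A [preprocess_config()] (`savgol_window`, `savgol_order`).
#' @return A [psg_trace()] holding dSpO2/dt in %/s (channel kept as
#'   `"SpO2"`; the derivative is a view of the same channel).
#' @export
derivative_spo2 <- function(trace, config) {
  stopifnot_trace(trace)
  n <- length(trace$samples)
  if (config$savgol_window > n) stop("Savitzky-Golay window longer than trace")
  fun <- function(x) as.numeric(
    signal::sgolayfilt(x, p = config$savgol_order, n = config$savgol_window,
                       m = 1, ts = 1 / trace$rate)
  )
  out <- trace
  out$samples <- filter_segments(trace$samples, fun,
                                 min_len = config$savgol_window)
  out$samples[!is.finite(trace$samples)] <- NA_real_
  out
}

#' Cut aligned traces into fixed-length model windows
#'
#' Produces `floor((T - L) / S) + 1` windows for a recording of duration `T`,
#' window length `L` and stride `S`; the trailing remainder is dropped.
#'
#' @param spo2,dspo2,fp0 Aligned [psg_trace()]s sharing rate and length.
#' @param config A [preprocess_config()].
#' @return A `window_set`: list with `patient_id`, `start_times` (s),
#'   matrices `spo2`, `dspo2`, `fp0` (one row per window) and `complete`
#'   (logical; `FALSE` where a window touches masked samples).
#' @export
make_windows <- function(spo2, dspo2, fp0, config) {
  for (tr in list(spo2, dspo2, fp0)) stopifnot_trace(tr)
  if (length(unique(c(spo2$rate, dspo2$rate, fp0$rate))) != 1L ||
      length(unique(c(length(spo2$samples), length(dspo2$samples),
                      length(fp0$samples)))) != 1L)
    stop("the three traces must share rate and length")
  rate <- spo2$rate
  L <- round(config$window_length * rate)
  S <- round(config$window_stride * rate)
  n <- length(spo2$samples)
  n_win <- if (n < L) 0L else (n - L) %/% S + 1L
  if (n_win == 0L)
    warning("recording shorter than one window; empty window set")
  take <- function(x) {
    m <- matrix(NA_real_, n_win, L)
    for (w in seq_len(n_win)) m[w, ] <- x[((w - 1L) * S + 1L):((w - 1L) * S + L)]
    m
  }
  m_spo2 <- take(spo2$samples)
  m_dspo2 <- take(dspo2$samples)
  m_fp0 <- take(fp0$samples)
  structure(list(
    patient_id = spo2$patient_id,
    rate = rate,
    start_times = (seq_len(n_win) - 1L) * config$window_stride,
    spo2 = m_spo2, dspo2 = m_dspo2, fp0 = m_fp0,
    complete = if (n_win) rowSums(!is.finite(m_spo2)) +
      rowSums(!is.finite(m_dspo2)) + rowSums(!is.finite(m_fp0)) == 0
    else logical(0)
  ), class = "window_set")
}

#' Full preprocessing chain for one patient
#'
#' Resample both channels to the target rate, repair artifacts, filter,
#' differentiate SpO2 and window.
#'
#' @param spo2,fp0 Raw [psg_trace()]s.
#' @param config A [preprocess_config()].
#' @return List with the processed `spo2`, `dspo2`, `fp0` traces, the
#'   `windows` ([make_windows()] result) and the combined repair `log`.
#' @export
preprocess_patient <- function(spo2, fp0, config = preprocess_config()) {
  s <- resample_trace(spo2, config$target_rate)
  f <- resample_trace(fp0, config$target_rate)
  rs <- repair_artifacts(s, config)
  rf <- repair_artifacts(f, config)
  s <- filter_trace(rs$trace, config)
  f <- filter_trace(rf$trace, config)
  d <- derivative_spo2(s, config)
  list(spo2 = s, dspo2 = d, fp0 = f,
       windows = make_windows(s, d, f, config),
       log = rbind(
         if (nrow(rs$log)) cbind(channel = "SpO2", rs$log),
         if (nrow(rf$log)) cbind(channel = "FP0", rf$log)
       ) %||% data.frame(channel = character(0), type = character(0),
                         start_s = numeric(0), end_s = numeric(0)))
}
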