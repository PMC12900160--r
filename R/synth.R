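# Synthetic overnight PSG cohort simulator.
#
# Generates paired SpO2 / nasal-airflow recordings with scheduled
# apnea-desaturation events whose markers (t1 airflow-cessation onset,
# t2 airflow resumption, t3 desaturation onset, t4 recovery end) are known
# exactly, plus clinical covariates and a logistic label model for the three
# comorbidities. Every downstream stage is validated against this ground
# truth.

# Deterministic per-patient seed, kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1009) %% 2147483647)
}

# Truncated-normal sampling by inverse-CDF so draws are a deterministic
# function of the RNG stream.
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

dist_spec <- function(mean, sd, lo = -Inf, hi = Inf) {
  list(mean = mean, sd = sd, lo = lo, hi = hi)
}

#' Solve a logistic-model intercept for a target prevalence
#'
#' Finds `b0` such that the mean of `plogis(b0 + z)` over
#' `z ~ N(0, sigma^2)` equals `target`, by Gauss-Hermite quadrature.
#'
#' @param target Target marginal prevalence in (0, 1).
#' @param sigma Standard deviation of the linear predictor around the
#'   intercept.
#' @return The intercept (log-odds scale).
#' @export
calibrate_intercept <- function(target, sigma) {
  stopifnot(target > 0, target < 1, sigma >= 0)
  if (sigma == 0) return(stats::qlogis(target))
  gh_n <- 40L
  # Golub-Welsch nodes/weights for Gauss-Hermite via the Jacobi matrix
  k <- seq_len(gh_n - 1L)
  J <- diag(0, gh_n)
  J[cbind(k, k + 1L)] <- sqrt(k / 2)
  J[cbind(k + 1L, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- e$vectors[1L, ]^2          # normalized: sum = 1
  f <- function(b0) sum(weights * stats::plogis(b0 + sqrt(2) * sigma * nodes)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Default comorbidity label model
#'
#' Logistic model on standardized covariates and patient-level event
#' morphology, with per-label morphology shifts that imprint the labels on
#' the signals themselves. Modify a copy of this list to change effect
#' structure or prevalences.
#'
#' @return Per-label list of `prevalence`, `coef`, `depth_shift`,
#'   `slope_shift`.
#' @export
default_label_model <- function() {
  # Directions follow the observed cohort structure: hypertension rises with
  # age, BMI and AHI; each label also shifts the patient's desaturation
  # morphology (depth %, fall slope %/s) so the signal branches carry label
  # information.
  # Coefficient scales put each label's ideal (Bayes) one-vs-rest AUC near
  # 0.72-0.75, the discriminability regime the modelling framework targets.
  list(
    hypertension = list(
      prevalence = 79 / 144,
      coef = c(zAge = 0.60, zBMI = 0.60, zAHI = 0.40, zDepth = 0.30),
      depth_shift = 0.8, slope_shift = 0.02
    ),
    diabetes = list(
      prevalence = 65 / 144,
      coef = c(zAge = -0.45, zBMI = -0.45, zGender = 0.40, zSlope = 0.45),
      depth_shift = -0.6, slope_shift = 0.06
    ),
    asthma_copd = list(
      prevalence = 65 / 144,
      coef = c(zAHI = 0.55, zDepth = 0.50, zSlope = 0.40),
      depth_shift = 0.6, slope_shift = -0.04
    )
  )
}

#' Configuration for a synthetic PSG cohort
#'
#' Defaults emulate the clinical cohort the package models: 144 patients,
#' overnight (6 h) two-channel recordings, desaturations of depth >= 3 %
#' lasting >= 10 s, covariates in adult sleep-clinic ranges, and label
#' prevalences of roughly 55/45/45 % for
#' hypertension/diabetes/asthma-COPD.
#'
#' @param n_patients Number of patients.
#' @param duration Recording duration in hours.
#' @param sample_rate Raw sampling rate in Hz (downstream preprocessing
#'   resamples to its own target rate).
#' @param ahi_distribution Log-normal spec for the per-patient event rate
#'   (events/hour): list with `meanlog`, `sdlog`, `lo`, `hi`.
#' @param template_distributions Per-field truncated-normal specs for the
#'   event template (`cessation_duration`, `desat_delay`, `resat_delay`,
#'   `desat_depth`, `fall_slope`) and their within-patient SDs
#'   (`within_sd` sub-list).
#' @param covariate_distributions Truncated-normal specs for `Age`, `BMI`,
#'   `HeartRate` plus `p_female`.
#' @param label_model Per-label list of `prevalence` (or explicit
#'   `intercept`), named `coef` vector on standardized predictors
#'   (`zAge`, `zGender`, `zBMI`, `zAHI`, `zHeartRate`, `zDepth`, `zSlope`)
#'   and morphology shifts `depth_shift` (%), `slope_shift` (%/s).
#' @param noise_sd_spo2 Additive Gaussian noise SD on SpO2 (%).
#' @param noise_frac_fp0 Airflow noise SD as a fraction of breathing
#'   amplitude.
#' @param artifact_rates Per-hour rates for `dropout`, `spike`, `clipping`
#'   used by [inject_artifacts()]; all zero by default (artifacts are opt-in).
#' @param baseline_spo2 Truncated-normal spec for the per-patient SpO2
#'   baseline (%).
#' @param min_event_spacing Minimum spacing between consecutive event onsets
#'   (s).
#' @param seed Integer seed; with the patient index it fully determines each
#'   patient.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 144,
                          duration = 6,
                          sample_rate = 25,
                          ahi_distribution = list(meanlog = 3.21, sdlog = 0.71,
                                                  lo = 0, hi = 90),
                          template_distributions = list(
                            cessation_duration = dist_spec(50, 8, 15, 80),
                            desat_delay = dist_spec(14.8, 4.5, 2, 28),
                            resat_delay = dist_spec(13.2, 4.0, 2, 26),
                            desat_depth = dist_spec(6.5, 2.5, 3, 20),
                            fall_slope = dist_spec(0.24, 0.10, 0.08, 1.0),
                            within_sd = list(cessation_duration = 6,
                                             desat_delay = 2,
                                             resat_delay = 2,
                                             desat_depth = 1.0,
                                             fall_slope = 0.04)
                          ),
                          covariate_distributions = list(
                            Age = dist_spec(57.6, 11.1, 18, 90),
                            BMI = dist_spec(31.8, 5.9, 18, 60),
                            HeartRate = dist_spec(68.3, 15.9, 40, 120),
                            p_female = 0.42
                          ),
                          label_model = default_label_model(),
                          noise_sd_spo2 = 0.3,
                          noise_frac_fp0 = 0.05,
                          artifact_rates = list(dropout = 0, spike = 0,
                                                clipping = 0),
                          baseline_spo2 = dist_spec(96, 1, 94, 98),
                          min_event_spacing = 30,
                          seed = 1L) {
  cfg <- list(
    n_patients = n_patients, duration = duration, sample_rate = sample_rate,
    ahi_distribution = ahi_distribution,
    template_distributions = template_distributions,
    covariate_distributions = covariate_distributions,
    label_model = label_model,
    noise_sd_spo2 = noise_sd_spo2, noise_frac_fp0 = noise_frac_fp0,
    artifact_rates = artifact_rates, baseline_spo2 = baseline_spo2,
    min_event_spacing = min_event_spacing, seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  # resolve intercepts once so every patient shares the same label model
  cfg$label_model <- lapply(cfg$label_model, function(lm) {
    if (is.null(lm$intercept)) {
      sigma <- sqrt(sum(lm$coef^2))
      lm$intercept <- calibrate_intercept(lm$prevalence, sigma)
    }
    lm
  })
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$sample_rate > 0, cfg$duration > 0,
            cfg$noise_sd_spo2 >= 0, cfg$noise_frac_fp0 >= 0,
            all(unlist(cfg$artifact_rates) >= 0),
            cfg$min_event_spacing >= 0)
  td <- cfg$template_distributions
  if (td$cessation_duration$lo < 10)
    stop("cessation_duration truncation must respect the 10 s clinical minimum")
  if (td$desat_depth$lo < 3)
    stop("desat_depth truncation must respect the 3 % clinical minimum")
  if (td$fall_slope$lo <= 0) stop("fall_slope must be positive")
  if (td$desat_delay$lo < 0) stop("desat_delay must be non-negative")
  for (lm in cfg$label_model) {
    if (is.null(lm$intercept) && (is.null(lm$prevalence) ||
        lm$prevalence <= 0 || lm$prevalence >= 1))
      stop("each label needs an intercept or a prevalence in (0,1)")
  }
  invisible(cfg)
}

draw_spec <- function(n, spec) rtnorm(n, spec$mean, spec$sd, spec$lo, spec$hi)

# Sample per-patient covariates, patient-level event-template means, label
# probabilities and labels. Everything consumed from the current RNG stream.
sample_patient_state <- function(config) {
  cov_d <- config$covariate_distributions
  td <- config$template_distributions
  age <- draw_spec(1, cov_d$Age)
  bmi <- draw_spec(1, cov_d$BMI)
  hr <- draw_spec(1, cov_d$HeartRate)
  gender <- stats::rbinom(1, 1, cov_d$p_female)
  ahi_target <- exp(rtnorm(1, config$ahi_distribution$meanlog,
                           config$ahi_distribution$sdlog,
                           log(max(config$ahi_distribution$lo, 1e-6)),
                           log(config$ahi_distribution$hi)))
  tmpl <- list(
    cessation_duration = draw_spec(1, td$cessation_duration),
    desat_delay = draw_spec(1, td$desat_delay),
    resat_delay = draw_spec(1, td$resat_delay),
    desat_depth = draw_spec(1, td$desat_depth),
    fall_slope = draw_spec(1, td$fall_slope)
  )
  pf <- cov_d$p_female
  z <- c(
    zAge = (age - cov_d$Age$mean) / cov_d$Age$sd,
    zGender = (gender - pf) / sqrt(pf * (1 - pf)),
    zBMI = (bmi - cov_d$BMI$mean) / cov_d$BMI$sd,
    zAHI = (log(ahi_target) - config$ahi_distribution$meanlog) /
      config$ahi_distribution$sdlog,
    zHeartRate = (hr - cov_d$HeartRate$mean) / cov_d$HeartRate$sd,
    zDepth = (tmpl$desat_depth - td$desat_depth$mean) / td$desat_depth$sd,
    zSlope = (tmpl$fall_slope - td$fall_slope$mean) / td$fall_slope$sd
  )
  probs <- vapply(config$label_model, function(lm) {
    eta <- lm$intercept + sum(lm$coef * z[names(lm$coef)])
    stats::plogis(eta)
  }, 0)
  labels <- stats::rbinom(length(probs), 1, probs)
  names(labels) <- names(probs)
  # label-dependent morphology shift feeds comorbidity structure into the
  # signal shape itself
  for (j in seq_along(config$label_model)) {
    if (labels[j] == 1) {
      lm <- config$label_model[[j]]
      tmpl$desat_depth <- tmpl$desat_depth + (lm$depth_shift %||% 0)
      tmpl$fall_slope <- tmpl$fall_slope + (lm$slope_shift %||% 0)
    }
  }
  tmpl$desat_depth <- max(tmpl$desat_depth, 3)
  tmpl$fall_slope <- max(tmpl$fall_slope, 0.05)
  list(age = age, gender = gender, bmi = bmi, hr = hr,
       ahi_target = ahi_target, template = tmpl, probs = probs,
       labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Schedule n events inside [warmup, duration - tail], honouring the minimum
# onset spacing and per-event footprints. Errors when infeasible.
schedule_events <- function(n_events, event_span, duration_s, spacing,
                            warmup = 120, tail = 30) {
  if (n_events == 0) return(numeric(0))
  footprint <- pmax(event_span, spacing)
  avail <- duration_s - warmup - tail
  slack <- avail - sum(footprint)
  if (slack < 0)
    stop("infeasible event schedule: ", n_events, " events need ",
         round(sum(footprint)), " s but only ", round(avail),
         " s are available")
  gaps <- stats::runif(n_events + 1L)
  gaps <- gaps / sum(gaps) * slack
  onsets <- warmup + cumsum(gaps[seq_len(n_events)]) +
    c(0, cumsum(footprint[-n_events]))
  onsets
}

# Evaluate the piecewise-linear desaturation waveform of one event on the
# sample grid and subtract it from the running SpO2 vector.
apply_desat <- function(spo2, t, baseline, t3, t4, depth, slope) {
  fall_end <- t3 + depth / slope
  rec_dur <- min(15, t4 - fall_end)
  rec_start <- t4 - rec_dur
  idx <- which(t >= t3 & t <= t4)
  ti <- t[idx]
  drop <- numeric(length(ti))
  drop[ti <= fall_end] <- slope * (ti[ti <= fall_end] - t3)
  drop[ti > fall_end & ti <= rec_start] <- depth
  rec <- ti > rec_start
  drop[rec] <- depth * (t4 - ti[rec]) / rec_dur
  spo2[idx] <- spo2[idx] - drop
  spo2
}

#' Generate one synthetic patient
#'
#' Deterministic given `(config$seed, patient_index)`. The SpO2 channel is a
#' per-patient baseline with piecewise-linear desaturation events; the
#' airflow channel is a 0.25 Hz breathing oscillation whose amplitude
#' envelope collapses to 5 % of baseline during each cessation.
#'
#' @param config A [cohort_config()].
#' @param patient_index 1-based patient index (`<= config$n_patients`).
#' @return List with elements `spo2`, `fp0` ([psg_trace()]s), `clinical`
#'   (one-row data frame), and `ground_truth` (`events` data frame with
#'   t1/t2/t3/t4/depth/slope, `ahi_true`, `label_probs`, `labels`,
#'   `baseline`).
#' @export
generate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "cohort_config"),
            patient_index >= 1, patient_index <= config$n_patients)
  set.seed(derive_seed(config$seed, patient_index))
  st <- sample_patient_state(config)
  duration_s <- config$duration * 3600
  n <- round(duration_s * config$sample_rate)
  t <- (seq_len(n) - 1L) / config$sample_rate
  baseline <- draw_spec(1, config$baseline_spo2)
  td <- config$template_distributions
  wsd <- td$within_sd

  n_events <- round(st$ahi_target * config$duration)
  ev <- NULL
  if (n_events > 0) {
    tm <- st$template
    cess <- rtnorm(n_events, tm$cessation_duration, wsd$cessation_duration,
                   td$cessation_duration$lo, td$cessation_duration$hi)
    d_delay <- rtnorm(n_events, tm$desat_delay, wsd$desat_delay,
                      max(td$desat_delay$lo, 0), td$desat_delay$hi)
    r_delay <- rtnorm(n_events, tm$resat_delay, wsd$resat_delay,
                      max(td$resat_delay$lo, 0), td$resat_delay$hi)
    depth <- rtnorm(n_events, tm$desat_depth, wsd$desat_depth,
                    max(td$desat_depth$lo, 3), 30)
    slope <- rtnorm(n_events, tm$fall_slope, wsd$fall_slope,
                    td$fall_slope$lo, td$fall_slope$hi)
    dt_spo2 <- cess + r_delay - d_delay        # implied desaturation duration
    # keep the fall phase inside the event window
    slope <- pmax(slope, depth / (0.8 * dt_spo2))
    span <- cess + r_delay + 5                 # event footprint on the night
    t1 <- schedule_events(n_events, span, duration_s,
                          config$min_event_spacing)
    ev <- data.frame(
      t1 = t1, t2 = t1 + cess, t3 = t1 + d_delay,
      t4 = t1 + cess + r_delay, depth = depth, slope = slope,
      cessation_duration = cess
    )
  }

  spo2 <- rep(baseline, n)
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev)))
      spo2 <- apply_desat(spo2, t, baseline, ev$t3[i], ev$t4[i],
                          ev$depth[i], ev$slope[i])
  }
  amp <- rtnorm(1, 1, 0.15, 0.5, 1.5)
  phase <- stats::runif(1, 0, 2 * pi)
  env <- rep(amp, n)
  if (!is.null(ev)) {
    ramp <- 2  # s of smooth envelope transition at each cessation edge
    for (i in seq_len(nrow(ev))) {
      a <- ev$t1[i]; b <- ev$t2[i]
      idx <- which(t >= a - ramp & t <= b + ramp)
      ti <- t[idx]
      f <- rep(0.05, length(ti))
      lead <- ti < a
      f[lead] <- 1 - 0.95 * (ti[lead] - (a - ramp)) / ramp
      trail <- ti > b
      f[trail] <- 0.05 + 0.95 * (ti[trail] - b) / ramp
      env[idx] <- pmin(env[idx], amp * f)
    }
  }
  fp0 <- env * sin(2 * pi * 0.25 * t + phase)

  if (config$noise_sd_spo2 > 0)
    spo2 <- spo2 + stats::rnorm(n, 0, config$noise_sd_spo2)
  if (config$noise_frac_fp0 > 0)
    fp0 <- fp0 + stats::rnorm(n, 0, config$noise_frac_fp0 * amp)
  spo2 <- pmin(pmax(spo2, 50), 100)

  pid <- sprintf("P%04d", patient_index)
  ahi_true <- n_events / config$duration
  clinical <- data.frame(
    patient_id = pid,
    Age = st$age, Gender = st$gender, BMI = st$bmi,
    AHI = ahi_true, HeartRate = st$hr,
    hypertension = unname(st$labels["hypertension"]),
    diabetes = unname(st$labels["diabetes"]),
    asthma_copd = unname(st$labels["asthma_copd"])
  )
  list(
    spo2 = psg_trace(pid, "SpO2", config$sample_rate, spo2),
    fp0 = psg_trace(pid, "FP0", config$sample_rate, fp0),
    clinical = clinical,
    ground_truth = list(
      events = if (is.null(ev))
        data.frame(t1 = numeric(0), t2 = numeric(0), t3 = numeric(0),
                   t4 = numeric(0), depth = numeric(0), slope = numeric(0),
                   cessation_duration = numeric(0))
      else ev,
      ahi_true = ahi_true,
      label_probs = st$probs,
      labels = st$labels,
      baseline = baseline,
      template = st$template
    )
  )
}

#' Generate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory; when given, one EDF per patient, a
#'   clinical/label CSV (`clinical.csv`) and a JSON-lines ground-truth event
#'   file (`ground_truth.jsonl`) are written there.
#' @return List with `patients` (list of [generate_patient()] results) and
#'   `clinical` (cohort clinical/label table).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  patients <- lapply(seq_len(config$n_patients),
                     function(i) generate_patient(config, i))
  clinical <- do.call(rbind, lapply(patients, function(p) p$clinical))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in patients)
      write_edf(list(p$spo2, p$fp0),
                file.path(dir, paste0(p$clinical$patient_id, ".edf")))
    write_clinical(clinical, file.path(dir, "clinical.csv"))
    con <- file(file.path(dir, "ground_truth.jsonl"), "w")
    for (p in patients) {
      evs <- p$ground_truth$events
      if (nrow(evs)) for (i in seq_len(nrow(evs))) {
        rec <- c(list(patient_id = p$clinical$patient_id),
                 as.list(evs[i, ]))
        writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
      }
    }
    close(con)
  }
  list(patients = patients, clinical = clinical)
}

#' Inject sensor artifacts into a trace
#'
#' Corruption types: `dropout` (a run forced to a sentinel value of 0),
#' `spike` (a short out-of-range excursion) and `clipping` (a flat run at
#' the saturation ceiling). Every corrupted interval is recorded in the log.
#'
#' @param trace A [psg_trace()].
#' @param rates List with per-hour rates `dropout`, `spike`, `clipping`.
#' @param seed Integer seed for artifact placement.
#' @param dropout_duration,clipping_duration Artifact durations in seconds.
#' @return List with `trace` (corrupted copy) and `log` (data frame with
#'   `type`, `start_s`, `end_s`).
#' @export
inject_artifacts <- function(trace, rates, seed = 1L,
                             dropout_duration = 2, clipping_duration = 5) {
  stopifnot_trace(trace)
  stopifnot(all(unlist(rates) >= 0))
  set.seed(as.integer(seed))
  x <- trace$samples
  n <- length(x)
  dur_h <- trace_duration(trace) / 3600
  log <- data.frame(type = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  draw_starts <- function(rate_per_h) {
    k <- stats::rpois(1, rate_per_h * dur_h)
    sort(stats::runif(k, 0, trace_duration(trace)))
  }
  add <- function(type, s, e) {
    log <<- rbind(log, data.frame(type = type, start_s = s, end_s = e))
  }
  for (s in draw_starts(rates$dropout %||% 0)) {
    e <- min(s + dropout_duration, trace_duration(trace))
    i <- which(trace_times(trace) >= s & trace_times(trace) < e)
    if (length(i)) { x[i] <- 0; add("dropout", s, e) }
  }
  for (s in draw_starts(rates$spike %||% 0)) {
    i <- which.min(abs(trace_times(trace) - s))
    x[i] <- if (trace$channel == "SpO2") 120 else max(abs(x), 1) * 5
    add("spike", s, s + 1 / trace$rate)
  }
  for (s in draw_starts(rates$clipping %||% 0)) {
    e <- min(s + clipping_duration, trace_duration(trace))
    i <- which(trace_times(trace) >= s & trace_times(trace) < e)
    if (length(i)) {
      x[i] <- if (trace$channel == "SpO2") 100 else max(abs(x), 1)
      add("clipping", s, e)
    }
  }
  out <- trace
  out$samples <- x
  list(trace = out, log = log)
}
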