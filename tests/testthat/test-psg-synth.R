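zero_event_config <- function(n = 1, seed = 5, ...) {
  cohort_config(
    n_patients = n, duration = 0.2, sample_rate = 10,
    ahi_distribution = list(meanlog = -10, sdlog = 1e-6, lo = 0, hi = 1),
    seed = seed, ...
  )
}

test_that("an event-free configuration produces a flat SpO2 trace", {
  cfg <- zero_event_config(noise_sd_spo2 = 0.3, noise_frac_fp0 = 0.05)
  p <- generate_patient(cfg, 1)
  expect_equal(nrow(p$ground_truth$events), 0)
  bl <- p$ground_truth$baseline
  expect_lt(max(abs(p$spo2$samples - bl)), 5 * 0.3)   # baseline +/- noise
  expect_equal(p$ground_truth$ahi_true, 0)
})

test_that("the scheduled event waveform matches its closed form", {
  cfg <- cohort_config(
    n_patients = 1, duration = 0.5, sample_rate = 25,
    ahi_distribution = list(meanlog = log(2), sdlog = 1e-6, lo = 0, hi = 5),
    noise_sd_spo2 = 0, noise_frac_fp0 = 0, seed = 7
  )
  p <- generate_patient(cfg, 1)
  ev <- p$ground_truth$events
  bl <- p$ground_truth$baseline
  tt <- trace_times(p$spo2)
  x <- p$spo2$samples
  for (i in seq_len(nrow(ev))) {
    # SpO2 equals baseline at t3 and t4 (within one sample of interpolation)
    expect_lt(abs(x[which.min(abs(tt - ev$t3[i]))] - bl), 0.1)
    expect_lt(abs(x[which.min(abs(tt - ev$t4[i]))] - bl), 0.1)
    inside <- tt > ev$t3[i] & tt < ev$t4[i]
    expect_lt(abs(min(x[inside]) - (bl - ev$depth[i])), 1e-3)
    # the fall reaches the nadir at depth/slope seconds after t3
    t_fall_end <- ev$t3[i] + ev$depth[i] / ev$slope[i]
    expect_lt(abs(x[which.min(abs(tt - t_fall_end))] - (bl - ev$depth[i])),
              0.05)
    # cessation suppresses the airflow envelope
    cess <- tt > ev$t1[i] + 1 & tt < ev$t2[i] - 1
    expect_lt(max(abs(p$fp0$samples[cess])), 0.10)
  }
})

test_that("generation is bit-identical for a repeated (seed, index)", {
  cfg <- cohort_config(n_patients = 3, duration = 0.2, sample_rate = 10,
                       seed = 42,
                       ahi_distribution = list(meanlog = log(10), sdlog = 0.3,
                                               lo = 0, hi = 20))
  a <- generate_patient(cfg, 2)
  b <- generate_patient(cfg, 2)
  expect_identical(a$spo2$samples, b$spo2$samples)
  expect_identical(a$fp0$samples, b$fp0$samples)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$ground_truth$events, b$ground_truth$events)
  # different index gives a different patient
  c <- generate_patient(cfg, 3)
  expect_false(identical(a$spo2$samples, c$spo2$samples))
})

test_that("ground-truth AHI equals scheduled events per hour exactly", {
  cfg <- cohort_config(n_patients = 2, duration = 0.5, sample_rate = 10,
                       ahi_distribution = list(meanlog = log(12), sdlog = 0.4,
                                               lo = 0, hi = 25), seed = 9)
  for (i in 1:2) {
    p <- generate_patient(cfg, i)
    expect_equal(p$ground_truth$ahi_true,
                 nrow(p$ground_truth$events) / cfg$duration)
    expect_equal(p$clinical$AHI, p$ground_truth$ahi_true)
    ev <- p$ground_truth$events
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$t1) >= cfg$min_event_spacing))
      expect_true(all(ev$t1[-1] >= ev$t4[-nrow(ev)]))  # non-overlap
    }
    expect_true(all(ev$t2 > ev$t1 & ev$t4 > ev$t3 & ev$t3 >= ev$t1))
  }
})

test_that("an infeasible schedule raises an explicit error", {
  cfg <- cohort_config(n_patients = 1, duration = 0.2, sample_rate = 5,
                       ahi_distribution = list(meanlog = log(60), sdlog = 1e-6,
                                               lo = 0, hi = 80), seed = 1)
  expect_error(generate_patient(cfg, 1), "infeasible")
})

test_that("label prevalences track the configured model", {
  # many cheap (short, event-free) patients: the label machinery is what
  # is being exercised, not the signals
  cfg <- zero_event_config(n = 600, seed = 33)
  coh <- generate_cohort(cfg)
  probs <- t(vapply(coh$patients,
                    function(p) p$ground_truth$label_probs, numeric(3)))
  emp <- colMeans(coh$clinical[, c("hypertension", "diabetes", "asthma_copd")])
  # empirical prevalence within 3 binomial SEs of the model-implied mean
  for (j in 1:3) {
    se <- sqrt(sum(probs[, j] * (1 - probs[, j]))) / nrow(probs)
    expect_lt(abs(emp[j] - mean(probs[, j])), 3 * se + 1e-12)
  }
  # and near the published prevalences the defaults encode
  expect_lt(abs(emp[1] - 79 / 144), 0.08)
  expect_lt(abs(emp[2] - 65 / 144), 0.08)
  expect_lt(abs(emp[3] - 65 / 144), 0.08)
})

test_that("degenerate label models yield all-zero labels and n = 1 works", {
  lm0 <- default_label_model()
  for (nm in names(lm0)) {
    lm0[[nm]]$intercept <- -50
    lm0[[nm]]$prevalence <- NULL
  }
  cfg <- zero_event_config(n = 20, seed = 2, label_model = lm0)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$clinical[, c("hypertension", "diabetes",
                                   "asthma_copd")] == 0))
  one <- generate_cohort(zero_event_config(n = 1, seed = 3))
  expect_equal(nrow(one$clinical), 1)
})

test_that("cohort output files are written and readable", {
  cfg <- cohort_config(n_patients = 2, duration = 0.2, sample_rate = 10,
                       ahi_distribution = list(meanlog = log(10), sdlog = 0.2,
                                               lo = 0, hi = 20), seed = 12)
  dir <- withr::local_tempdir()
  generate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "P0001.edf")))
  clin <- read_clinical(file.path(dir, "clinical.csv"), require_labels = TRUE)
  expect_equal(nrow(clin), 2)
  gt <- readLines(file.path(dir, "ground_truth.jsonl"))
  expect_gt(length(gt), 0)
  rec <- jsonlite::fromJSON(gt[1])
  expect_true(all(c("patient_id", "t1", "t2", "t3", "t4") %in% names(rec)))
  back <- read_edf(file.path(dir, "P0001.edf"))
  expect_equal(back$SpO2$rate, 10)
})

test_that("artifact injection is logged and typed correctly", {
  tr <- psg_trace("a", "SpO2", 5, rep(96, 5 * 600))
  none <- inject_artifacts(tr, list(dropout = 0, spike = 0, clipping = 0))
  expect_identical(none$trace$samples, tr$samples)
  expect_equal(nrow(none$log), 0)

  res <- inject_artifacts(tr, list(dropout = 3, spike = 20, clipping = 3),
                          seed = 8)
  expect_gt(nrow(res$log), 0)
  drops <- res$log[res$log$type == "dropout", ]
  for (k in seq_len(nrow(drops))) {
    idx <- which(trace_times(tr) >= drops$start_s[k] &
                   trace_times(tr) < drops$end_s[k])
    expect_true(all(res$trace$samples[idx] == 0))
  }
  if (any(res$log$type == "spike"))
    expect_gt(max(res$trace$samples), 100)   # outside physiological range
  expect_identical(
    inject_artifacts(tr, list(dropout = 3, spike = 20, clipping = 3),
                     seed = 8)$trace$samples,
    res$trace$samples
  )
})
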