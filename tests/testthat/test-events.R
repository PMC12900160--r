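ecfg <- events_config()

# hand-built desaturation: baseline `bl`, linear fall, plateau, linear
# recovery, all at `rate` Hz
synth_desat <- function(bl = 96, depth = 6, fall = 15, plateau = 10,
                        recovery = 15, lead = 300, tail = 300, rate = 5) {
  x <- c(rep(bl, lead * rate),
         bl - seq(0, depth, length.out = fall * rate),
         rep(bl - depth, plateau * rate),
         bl - seq(depth, 0, length.out = recovery * rate),
         rep(bl, tail * rate))
  psg_trace("a", "SpO2", rate, x)
}

test_that("desaturation detection finds constructed events and respects thresholds", {
  expect_equal(nrow(detect_desaturations(
    psg_trace("a", "SpO2", 5, rep(96, 3000)), ecfg)), 0)

  d <- detect_desaturations(synth_desat(), ecfg)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$depth - 6), 0.3)
  expect_lt(abs((d$t4 - d$t3) - 40), 1)
  expect_lt(abs(d$fall_slope - 6 / 15), 0.05)

  # a 2 % dip stays below the 3 % depth threshold
  shallow <- detect_desaturations(synth_desat(depth = 2), ecfg)
  expect_equal(nrow(shallow), 0)

  # masked regions never produce events
  tr <- synth_desat()
  tr$samples[1501:1700] <- NA
  masked <- detect_desaturations(tr, ecfg)
  expect_equal(nrow(masked), 0)
})

synth_airflow <- function(suppress_at = 600, duration = 40, total = 1500,
                          rate = 5, frac = 0.05) {
  tt <- (0:(total * rate - 1)) / rate
  env <- rep(1, length(tt))
  env[tt >= suppress_at & tt < suppress_at + duration] <- frac
  psg_trace("a", "FP0", rate, env * sin(2 * pi * 0.25 * tt))
}

test_that("cessation detection locates envelope suppressions", {
  none <- detect_cessations(synth_airflow(duration = 0), ecfg)
  expect_equal(nrow(none), 0)

  one <- detect_cessations(synth_airflow(), ecfg)
  expect_equal(nrow(one), 1)
  expect_lt(abs(one$t1 - 600), 1)
  expect_lt(abs(one$t2 - 640), 1)

  # 8 s suppression is below the 10 s minimum
  short <- detect_cessations(synth_airflow(duration = 8), ecfg)
  expect_equal(nrow(short), 0)

  expect_error(detect_cessations(psg_trace("a", "FP0", 5, rep(0, 3000)), ecfg),
               "baseline")
})

test_that("pairing is causal, one-to-one and order-independent", {
  cess <- data.frame(t1 = 100, t2 = 140)
  des <- data.frame(t3 = 112, t4 = 150, depth = 5, fall_slope = 0.3)
  p <- pair_events(cess, des, ecfg)
  expect_equal(nrow(p), 1)
  expect_equal(p$onset_delay, 12)
  expect_equal(p$recovery_delay, 10)

  # a desaturation preceding every cessation is never paired
  p0 <- pair_events(data.frame(t1 = 200, t2 = 240),
                    data.frame(t3 = 150, t4 = 190, depth = 5,
                               fall_slope = 0.3), ecfg)
  expect_equal(nrow(p0), 0)

  # two cessations, one desaturation reachable only from the first
  cess2 <- data.frame(t1 = c(100, 300), t2 = c(140, 340))
  p1 <- pair_events(cess2, des, ecfg)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$t1, 100)

  # shuffling input order changes nothing
  cessN <- data.frame(t1 = c(500, 100, 300), t2 = c(540, 140, 340))
  desN <- data.frame(t3 = c(310, 505, 112), t4 = c(350, 545, 150),
                     depth = c(4, 5, 6), fall_slope = c(0.2, 0.3, 0.4))
  a <- pair_events(cessN, desN, ecfg)
  b <- pair_events(cessN[c(2, 3, 1), ], desN[c(3, 1, 2), ], ecfg)
  expect_equal(a[order(a$t1), ], b[order(b$t1), ], ignore_attr = TRUE)
})

test_that("feature computation follows the stated definitions", {
  clin <- data.frame(patient_id = "p", Age = 50, Gender = 1, BMI = 30,
                     AHI = 20, HeartRate = 70)
  pairs <- data.frame(t1 = c(0, 100), t2 = c(40, 150), t3 = c(10, 114),
                      t4 = c(50, 160), depth = c(6, 4),
                      fall_slope = c(0.2, 0.3),
                      onset_delay = c(10, 14), recovery_delay = c(10, 10))
  fv <- compute_features(pairs, clin)
  expect_equal(fv$t3_t1_mean, 12)
  expect_equal(fv$t4_t2_mean, 10)
  expect_equal(fv$delta_t_FP0_mean, mean(c(40, 50)))
  expect_equal(fv$delta_t_SpO2_mean, mean(c(40, 46)))
  expect_equal(fv$mean_delta_SpO2, 5)
  expect_equal(fv$mean_slope, 0.25)
  # one event falling 6 % over 30 s has slope 0.2
  one <- pairs[1, ]; one$depth <- 6; one$fall_slope <- 6 / 30
  expect_equal(compute_features(one, clin)$mean_slope, 0.2)
  # the mean-of-per-event-slope definition equals brute force
  expect_equal(fv$mean_slope, mean(pairs$depth / (pairs$depth / pairs$fall_slope)))

  expect_warning(miss <- compute_features(pairs[0, ], clin), "no paired")
  expect_true(is.na(miss$mean_slope))
})

test_that("noiseless detection recovers all ground-truth markers within 1 s", {
  fx <- noiseless_patient()
  ev <- patient_events(fx$pp, fx$patient$clinical, ecfg)
  gt <- fx$patient$ground_truth$events
  expect_equal(nrow(ev$pairs), nrow(gt))      # recall 1 at precision 1
  expect_equal(nrow(ev$desats), nrow(gt))
  expect_equal(nrow(ev$cessations), nrow(gt))
  for (m in c("t1", "t2", "t3", "t4"))
    expect_lt(max(abs(sort(ev$pairs[[m]]) - sort(gt[[m]]))), 1)
  expect_lt(max(abs(sort(ev$pairs$depth) - sort(gt$depth))), 0.3)
})

test_that("feature means recover generator parameters within 2 SEs", {
  fx <- noiseless_patient()
  ev <- patient_events(fx$pp, fx$patient$clinical, ecfg)
  gt <- fx$patient$ground_truth$events
  n <- nrow(gt)
  for (spec in list(
    list(est = ev$features$t3_t1_mean, tru = gt$t3 - gt$t1),
    list(est = ev$features$t4_t2_mean, tru = gt$t4 - gt$t2),
    list(est = ev$features$delta_t_FP0_mean, tru = gt$t2 - gt$t1),
    list(est = ev$features$mean_delta_SpO2, tru = gt$depth),
    list(est = ev$features$mean_slope, tru = gt$slope)
  )) {
    se <- stats::sd(spec$tru) / sqrt(n)
    expect_lt(abs(spec$est - mean(spec$tru)), 2 * se + 0.05 * mean(spec$tru))
  }
})

test_that("desaturation recall stays high under default noise", {
  cfg <- cohort_config(
    n_patients = 5, duration = 1.0, sample_rate = 25,
    ahi_distribution = list(meanlog = log(35), sdlog = 1e-6, lo = 0, hi = 45),
    seed = 5
  )
  tot <- 0; det <- 0
  for (i in 1:5) {
    p <- generate_patient(cfg, i)
    pp <- preprocess_patient(p$spo2, p$fp0)
    d <- detect_desaturations(pp$spo2, ecfg)
    deep <- p$ground_truth$events[p$ground_truth$events$depth >= 4, ]
    tot <- tot + nrow(deep)
    for (k in seq_len(nrow(deep)))
      det <- det + any(abs(d$t3 - deep$t3[k]) < 5)
  }
  expect_gte(tot, 100)
  expect_gte(det / tot, 0.9)
})

test_that("normalization is fit on the training subset only", {
  fx <- small_cohort()
  norm <- assemble_and_normalize(fx$features, fit_ids = fx$features$patient_id)
  m <- norm$matrix
  for (cn in setdiff(feature_columns(), "Gender")) {
    expect_lt(abs(mean(m[[cn]])), 1e-9)
    expect_lt(abs(stats::sd(m[[cn]]) - 1), 1e-9)
  }
  expect_identical(m$Gender, fx$features$Gender)   # passed through

  # a saved scaler applied to new rows equals the explicit formula
  fit_ids <- fx$features$patient_id[1:25]
  norm2 <- assemble_and_normalize(fx$features, fit_ids = fit_ids)
  newrows <- fx$features[26:40, ]
  again <- apply_scaler(norm2$scaler, newrows)
  for (cn in setdiff(feature_columns(), "Gender")) {
    v <- newrows[[cn]]
    v[is.na(v)] <- norm2$scaler$medians[[cn]]
    manual <- (v - norm2$scaler$center[[cn]]) / norm2$scaler$scale[[cn]]
    expect_equal(again[[cn]], manual)
  }

  # single-row fit set: every column is zero-variance
  expect_warning(
    one <- assemble_and_normalize(fx$features, fit_ids = fx$features$patient_id[1]),
    "zero-variance"
  )
  expect_equal(length(one$scaler$skipped),
               length(setdiff(feature_columns(), "Gender")))
})
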