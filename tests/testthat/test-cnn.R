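test_that("class weights are inverse-frequency", {
  bal <- matrix(rep(c(1, 0), each = 50), 100, 3)
  expect_equal(unname(class_weights(bal)), rep(1, 3))
  quarter <- matrix(0, 100, 3); quarter[1:25, ] <- 1
  expect_equal(unname(class_weights(quarter)), rep(3, 3))
  # the reference cohort's prevalences (79, 65, 65 of 144)
  m <- matrix(0, 144, 3)
  m[1:79, 1] <- 1; m[1:65, 2] <- 1; m[1:65, 3] <- 1
  expect_equal(unname(class_weights(m)),
               c((144 - 79) / 79, (144 - 65) / 65, (144 - 65) / 65),
               tolerance = 1e-12)
  none <- matrix(0, 10, 3); none[, 1] <- 1
  expect_error(class_weights(none), "without positives")
})

test_that("weighted loss has its closed-form values and linearity", {
  y <- matrix(c(1, 0, 1, 0, 1, 0), 2, 3)
  half <- matrix(0.5, 2, 3)
  expect_equal(weighted_loss(half, y, rep(1, 3)), log(2), tolerance = 1e-12)

  near <- ifelse(y == 1, 1 - 1e-9, 1e-9)
  expect_lt(weighted_loss(near, y, rep(1, 3)), 1e-6)

  # doubling w_j doubles that label's positive-term contribution
  p <- matrix(runif(6, 0.2, 0.8), 2, 3)
  base <- weighted_loss(p, y, c(1, 1, 1))
  dbl <- weighted_loss(p, y, c(2, 1, 1))
  pos_term <- -mean(y[, 1] * log(p[, 1])) / 3
  expect_equal(dbl - base, pos_term, tolerance = 1e-12)

  # w = 1 weighted BCE equals plain binary cross-entropy
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_loss(p, y, rep(1, 3)), plain, tolerance = 1e-9)

  # focal with gamma = 0 reduces to weighted BCE
  expect_equal(weighted_loss(p, y, c(1.5, 1, 2), mode = "focal", gamma = 0),
               weighted_loss(p, y, c(1.5, 1, 2)), tolerance = 1e-12)
})

fake_window_data <- function(B = 24, L = 60, seed = 1) {
  set.seed(seed)
  list(spo2 = matrix(rnorm(B * L), B), dspo2 = matrix(rnorm(B * L), B),
       fp0 = matrix(rnorm(B * L), B), clin = matrix(rnorm(B * 11), B),
       y = matrix(rbinom(B * 3, 1, 0.5), B),
       patient_id = sprintf("w%03d", seq_len(B)))
}

test_that("model construction is seeded and architecture arithmetic holds", {
  mc <- model_config(seed = 5)
  m1 <- build_model(mc, 300, 11)
  m2 <- build_model(mc, 300, 11)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$fused_width, 32 * 3 + 32)

  no_clin <- build_model(model_config(use_clinical_branch = FALSE, seed = 5),
                         300, 11)
  expect_equal(m1$fused_width - no_clin$fused_width, mc$clinical_dense)
  no_deriv <- build_model(model_config(use_derivative_branch = FALSE,
                                       seed = 5), 300, 11)
  expect_equal(no_deriv$fused_width, 32 * 2 + 32)

  expect_error(build_model(model_config(kernel = 301), 300, 11),
               "larger than window")
})

test_that("forward passes give probabilities and both engines agree", {
  data <- fake_window_data()
  for (pool in c(1L, 2L)) {
    mc <- model_config(dropout = 0, pool = pool, seed = 3)
    mdl <- build_model(mc, 60, 11)
    mdl$input_norm <- lapply(stats::setNames(nm = c("spo2", "dspo2", "fp0")),
                             function(b) list(mean = 0, sd = 1))
    mdl$class_weights <- c(1.2, 1, 0.9)
    fwR <- psgcomorb:::model_forward(mdl, data, 1:24, training = TRUE)
    expect_true(all(fwR$prob > 0 & fwR$prob < 1))
    dl <- psgcomorb:::loss_grad_logits(fwR$prob, data$y, mdl$class_weights,
                                       "weighted_bce", 2)
    gR <- psgcomorb:::model_backward(mdl, data, fwR$cache, dl)
    st <- psgcomorb:::nn_step_cpp(mdl, data, 1:24, training = TRUE,
                                  y = data$y, mask_seed = 1)
    expect_equal(st$prob, fwR$prob, tolerance = 1e-12)
    for (nm in names(gR))
      expect_equal(st$grads[[nm]], gR[[nm]], tolerance = 1e-10,
                   ignore_attr = TRUE)
    # eval mode too
    pR <- psgcomorb:::model_forward(mdl, data, 1:10, training = FALSE)$prob
    pC <- psgcomorb:::nn_step_cpp(mdl, data, 1:10, training = FALSE)$prob
    expect_equal(pC, pR, tolerance = 1e-12)
  }
})

test_that("analytic gradients match numerical differentiation", {
  data <- fake_window_data(B = 6, L = 20, seed = 4)
  mc <- model_config(conv_filters = c(3, 4), kernel = 3, dropout = 0,
                     clinical_dense = 4, fusion_dense = 5, seed = 2)
  mdl <- build_model(mc, 20, 11)
  mdl$input_norm <- lapply(stats::setNames(nm = c("spo2", "dspo2", "fp0")),
                           function(b) list(mean = 0, sd = 1))
  w <- c(1.5, 1, 2)
  lossf <- function(m) {
    fw <- psgcomorb:::model_forward(m, data, 1:6, training = TRUE)
    weighted_loss(fw$prob, data$y, w)
  }
  fw <- psgcomorb:::model_forward(mdl, data, 1:6, training = TRUE)
  dl <- psgcomorb:::loss_grad_logits(fw$prob, data$y, w, "weighted_bce", 2)
  g <- psgcomorb:::model_backward(mdl, data, fw$cache, dl)
  eps <- 1e-5
  set.seed(1)
  for (nm in names(g)) {
    p <- mdl$params[[nm]]
    for (j in sample(length(p), min(3, length(p)))) {
      up <- mdl; up$params[[nm]][j] <- p[j] + eps
      dn <- mdl; dn$params[[nm]][j] <- p[j] - eps
      num <- (lossf(up) - lossf(dn)) / (2 * eps)
      expect_lt(abs(num - g[[nm]][j]) /
                  max(1e-6, abs(num) + abs(g[[nm]][j])), 1e-5)
    }
  }
})

test_that("focal-loss gradients match numerical differentiation", {
  set.seed(2)
  p <- matrix(runif(12, 0.1, 0.9), 4, 3)
  logits <- qlogis(p)
  y <- matrix(rbinom(12, 1, 0.5), 4, 3)
  w <- c(1.2, 0.8, 1.5)
  g <- psgcomorb:::loss_grad_logits(p, y, w, "focal", 2)
  eps <- 1e-6
  for (j in sample(12, 6)) {
    lp <- logits; lp[j] <- lp[j] + eps
    lm <- logits; lm[j] <- lm[j] - eps
    num <- (weighted_loss(plogis(lp), y, w, "focal", 2) -
              weighted_loss(plogis(lm), y, w, "focal", 2)) / (2 * eps)
    expect_lt(abs(num - g[j]), 1e-6)
  }
})

test_that("patient aggregation is the mean of window probabilities", {
  fx <- small_cohort()
  mc <- model_config(pool = 4, epochs = 1, seed = 7)
  mdl <- build_model(mc, ncol(fx$data$spo2), 11)
  fit <- train_cnn(mdl, fx$data, fx$split)
  pv <- predict_patients(fit$model, fx$data)
  for (pid in rownames(pv$prob)[1:5]) {
    rows <- pv$window_id == pid
    expect_equal(unname(pv$prob[pid, ]), unname(colMeans(pv$window_prob[rows, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  # threshold extremes
  p0 <- predict_patients(fit$model, fx$data, threshold = 0)
  expect_true(all(p0$labels == 1))
  p2 <- predict_patients(fit$model, fx$data, threshold = 1.01)
  expect_true(all(p2$labels == 0))
  expect_error(predict_patients(fit$model, fx$data, ids = "nonexistent"),
               "without windows")
})

test_that("training is deterministic and leak-free given a seed", {
  fx <- small_cohort()
  expect_length(intersect(fx$split$train, fx$split$val), 0)
  expect_length(intersect(fx$split$train, fx$split$test), 0)
  mc <- model_config(pool = 4, epochs = 2, seed = 11)
  f1 <- train_cnn(build_model(mc, ncol(fx$data$spo2), 11), fx$data, fx$split)
  f2 <- train_cnn(build_model(mc, ncol(fx$data$spo2), 11), fx$data, fx$split)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("random search is seeded and respects degenerate spaces", {
  fx <- small_cohort()
  space <- list(lr = c(1e-3, 3e-3), epochs = 1, pool = 4)
  t1 <- tune_cnn(fx$data, fx$split, space, n_trials = 2, seed = 5)
  t2 <- tune_cnn(fx$data, fx$split, space, n_trials = 2, seed = 5)
  expect_identical(t1$trials$lr, t2$trials$lr)
  expect_s3_class(t1$best_config, "model_config")

  one <- tune_cnn(fx$data, fx$split, list(lr = 2e-3, epochs = 1, pool = 4),
                  n_trials = 1, seed = 1)
  expect_equal(one$best_config$lr, 2e-3)
  expect_equal(nrow(one$trials), 1)

  degen <- tune_cnn(fx$data, fx$split, list(lr = 5e-4, epochs = 1, pool = 4),
                    n_trials = 3, seed = 2)
  expect_equal(degen$best_config$lr, 5e-4)
})
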