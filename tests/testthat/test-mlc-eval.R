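test_that("per-label binary metrics follow the defining formulas", {
  c1 <- data.frame(label = "x", TP = 3, FP = 1, TN = 6, FN = 0)
  m <- binary_metrics(c1)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 1.0)
  expect_equal(m$F1, 6 / 7)
  expect_equal(m$accuracy, 0.9)

  perfect <- binary_metrics(data.frame(label = "x", TP = 4, FP = 0, TN = 6,
                                       FN = 0))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall",
                                   "F1")]) == 1))
  # vacuous case: no positives exist, none predicted
  vac <- binary_metrics(data.frame(label = "x", TP = 0, FP = 0, TN = 10,
                                   FN = 0))
  expect_equal(vac$precision, 1)
  expect_equal(vac$recall, 1)
})

test_that("macro/micro/weighted aggregation behave as defined", {
  same <- data.frame(label = c("a", "b"), TP = c(3, 3), FP = c(1, 1),
                     TN = c(5, 5), FN = c(1, 1))
  expect_equal(aggregate_metric(same, "F1", "macro"),
               aggregate_metric(same, "F1", "micro"))
  expect_equal(aggregate_metric(same, "F1", "macro"),
               aggregate_metric(same, "F1", "weighted"))

  # two labels with F1 = {1, 0} and supports {1, 3}
  two <- data.frame(label = c("a", "b"), TP = c(1, 0), FP = c(0, 0),
                    TN = c(3, 1), FN = c(0, 3))
  expect_equal(aggregate_metric(two, "F1", "macro"), 0.5)
  expect_equal(aggregate_metric(two, "F1", "weighted"), 0.25)
})

test_that("example-based accuracies match the worked single-sample case", {
  truth <- matrix(c(1, 0, 0), 1)
  pred <- matrix(c(1, 1, 0), 1)
  em <- example_metrics(truth, pred)
  expect_equal(em$subset_accuracy, 0)
  expect_equal(em$flat_accuracy, 2 / 3)
  expect_equal(em$partial_accuracy, 1 / 2)
  expect_equal(em$hamming_loss, 1 / 3)

  perfect <- example_metrics(truth, truth)
  expect_equal(perfect$subset_accuracy, 1)
  expect_equal(perfect$hamming_loss, 0)
})

test_that("all metrics agree with the brute-force oracle on random matrices", {
  set.seed(42)
  for (rep in 1:60) {
    truth <- random_label_matrix(20)
    pred <- random_label_matrix(20)
    bf <- brute_force_metrics(truth, pred)
    em <- example_metrics(truth, pred)
    counts <- confusion_counts(truth, pred)
    expect_equal(em$subset_accuracy, bf$subset_accuracy, tolerance = 1e-12)
    expect_equal(em$flat_accuracy, bf$flat_accuracy, tolerance = 1e-12)
    expect_equal(em$partial_accuracy, bf$partial_accuracy, tolerance = 1e-12)
    expect_equal(em$hamming_loss, bf$hamming_loss, tolerance = 1e-12)
    expect_equal(aggregate_metric(counts, "F1", "macro"), bf$f1_macro,
                 tolerance = 1e-12)
    expect_equal(aggregate_metric(counts, "F1", "micro"), bf$f1_micro,
                 tolerance = 1e-12)
    expect_equal(aggregate_metric(counts, "F1", "weighted"), bf$f1_weighted,
                 tolerance = 1e-12)
  }
})

test_that("flat accuracy + Hamming loss is exactly 1, always", {
  set.seed(7)
  for (rep in 1:50) {
    truth <- random_label_matrix(sample(1:40, 1))
    pred <- random_label_matrix(nrow(truth))
    em <- example_metrics(truth, pred)
    expect_identical(em$hamming_loss, 1 - em$flat_accuracy)
  }
})

test_that("subset <= partial <= flat holds on 1000 random matrices", {
  set.seed(99)
  for (rep in 1:1000) {
    truth <- random_label_matrix(12, p = runif(1, 0.1, 0.9))
    pred <- random_label_matrix(12, p = runif(1, 0.1, 0.9))
    em <- example_metrics(truth, pred)
    expect_lte(em$subset_accuracy, em$partial_accuracy + 1e-12)
    expect_lte(em$partial_accuracy, em$flat_accuracy + 1e-12)
  }
})

test_that("AUC metrics match exhaustive pair counting and pROC", {
  scores <- c(0.9, 0.8, 0.3, 0.1)
  expect_equal(psgcomorb:::roc_auc(scores, c(1, 1, 0, 0)), 1.0)
  expect_equal(psgcomorb:::roc_auc(scores, c(0, 0, 1, 1)), 0.0)
  # exhaustive pair counting for interleaved truth: positives {0.9, 0.3}
  # vs negatives {0.8, 0.1} -> 3 of 4 pairs concordant
  expect_equal(psgcomorb:::roc_auc(scores, c(1, 0, 1, 0)), 0.75)
  # ties earn half credit
  expect_equal(psgcomorb:::roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)

  set.seed(5)
  s <- runif(200); y <- rbinom(200, 1, 0.4)
  ours <- psgcomorb:::roc_auc(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        levels = c(0, 1), direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)

  # permutation null
  set.seed(6)
  s2 <- runif(10000); y2 <- rbinom(10000, 1, 0.5)
  a <- auc_metrics(cbind(s2, s2, s2), cbind(y2, y2, y2))
  expect_lt(abs(a$auc_roc_macro - 0.5), 0.02)

  # perfectly ranked scores give AP = 1 as well
  p <- auc_metrics(matrix(scores, 4, 3), matrix(c(1, 1, 0, 0), 4, 3))
  expect_equal(p$auc_pr_macro, 1.0)

  expect_error(auc_metrics(matrix(runif(9), 3), matrix(1, 3, 3)),
               "single-class")
})

test_that("average precision matches a brute-force step-wise computation", {
  set.seed(8)
  for (rep in 1:20) {
    s <- runif(30); y <- rbinom(30, 1, 0.4)
    if (!any(y == 1) || !any(y == 0)) next
    o <- order(s, decreasing = TRUE)
    ys <- y[o]
    ap <- 0; hits <- 0
    for (k in seq_along(ys)) if (ys[k] == 1) {
      hits <- hits + 1
      ap <- ap + hits / k
    }
    expect_equal(psgcomorb:::average_precision(s, y), ap / sum(y),
                 tolerance = 1e-12)
  }
})

test_that("the MLCM equal-split rule produces the documented allocations", {
  # true {l3}, predicted {l1, l2}: half a unit to each false positive
  truth <- matrix(c(0, 0, 1), 1)
  pred <- matrix(c(1, 1, 0), 1)
  m <- build_mlcm(truth, pred)
  expect_equal(m$raw[3, 1], 0.5)
  expect_equal(m$raw[3, 2], 0.5)
  expect_equal(m$raw[3, 3], 0)

  # all-correct predictions give a diagonal matrix and identity P/R matrices
  t2 <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 1, 1))
  m2 <- build_mlcm(t2, t2)
  expect_true(all(m2$raw[upper.tri(m2$raw) | lower.tri(m2$raw)] == 0))
  expect_equal(unname(m2$precision), rep(1, 3))
  expect_equal(unname(m2$recall), rep(1, 3))

  # a missed label with no false positive goes to the unallocated tally
  t3 <- matrix(c(1, 0, 0), 1)
  p3 <- matrix(c(0, 0, 0), 1)
  m3 <- build_mlcm(t3, p3)
  expect_equal(unname(m3$unallocated[1]), 1)
  expect_equal(sum(m3$raw), 0)
})

test_that("MLCM mass is conserved on random data", {
  set.seed(13)
  for (rep in 1:30) {
    truth <- random_label_matrix(25)
    pred <- random_label_matrix(25)
    m <- build_mlcm(truth, pred)
    support <- colSums(truth)
    expect_equal(unname(rowSums(m$raw) + m$unallocated), unname(support),
                 tolerance = 1e-12)
    cs <- colSums(m$raw)
    expect_equal(unname(colSums(m$precision_matrix)[cs > 0]),
                 rep(1, sum(cs > 0)), tolerance = 1e-12)
    rs <- rowSums(m$raw)
    expect_equal(unname(rowSums(m$recall_matrix)[rs > 0]),
                 rep(1, sum(rs > 0)), tolerance = 1e-12)
  }
})

test_that("the bundled fixture regenerates the reference MLCM exactly", {
  fx <- mlcm_example_labels()
  m <- build_mlcm(fx$truth, fx$pred)
  expect_equal(unname(m$raw), unname(mlcm_reference_raw()), tolerance = 1e-12)
  expect_equal(unname(round(m$precision, 2)), c(0.89, 0.55, 0.64))
  expect_equal(unname(round(m$recall, 2)), c(0.50, 1.00, 0.70))
})

test_that("stratified evaluation matches an independent recount", {
  set.seed(77)
  n <- 50
  truth <- random_label_matrix(n)
  pred <- random_label_matrix(n)
  clinical <- data.frame(Age = runif(n, 20, 85))
  rep_ <- stratified_eval(truth, pred, clinical, by = "Age",
                          breaks = demographic_bins()$Age)
  # per subgroup per label: TP+FN = label-present count, TN+FP = absent
  for (r in seq_len(nrow(rep_))) {
    expect_equal(rep_$TP[r] + rep_$FN[r] + rep_$TN[r] + rep_$FP[r], rep_$n[r])
  }
  # single all-encompassing bin equals the overall confusion counts
  one <- stratified_eval(truth, pred, clinical, by = "Age",
                         breaks = c(-Inf, Inf))
  cc <- confusion_counts(truth, pred)
  expect_equal(one$TP, cc$TP, ignore_attr = TRUE)
  expect_equal(one$FN, cc$FN, ignore_attr = TRUE)
  # brute-force recount of one stratum
  bin <- clinical$Age >= 40 & clinical$Age < 50
  if (any(bin)) {
    row <- rep_[rep_$stratum == "[40,50)" & rep_$label == "label2", ]
    expect_equal(row$TP, sum(truth[bin, 2] == 1 & pred[bin, 2] == 1))
  }
})
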