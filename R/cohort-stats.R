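# Baseline group comparisons: one-sided Welch tests, Cohen's d with pooled
# SD, and AHI-severity stratified slope summaries.

#' Cohen's d from group summary statistics
#'
#' Absolute standardized mean difference using the pooled standard
#' deviation: `|m1 - m0| / sqrt(((n0-1) s0^2 + (n1-1) s1^2) / (n0+n1-2))`.
#'
#' @param n0,m0,s0 Size, mean and SD of the first group.
#' @param n1,m1,s1 Size, mean and SD of the second group.
#' @return Non-negative effect size (vectorized over its arguments).
#' @export
cohens_d <- function(n0, m0, s0, n1, m1, s1) {
  stopifnot(all(n0 >= 2), all(n1 >= 2), all(s0 >= 0), all(s1 >= 0))
  sp <- sqrt(((n0 - 1) * s0^2 + (n1 - 1) * s1^2) / (n0 + n1 - 2))
  d <- abs(m1 - m0) / sp
  bad <- sp == 0
  if (any(bad)) {
    d[bad & m0 == m1] <- 0
    if (any(bad & m0 != m1))
      stop("pooled SD is zero with unequal means: infinite effect size")
  }
  d
}

#' One-sided Welch two-sample test from summary statistics
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; the one-sided p-value is taken in the direction of the observed
#' difference (p = 0.5 at a zero statistic).
#'
#' @inheritParams cohens_d
#' @return List with `statistic` (|t|), `df` and `p_value` (vectorized).
#' @export
welch_one_sided <- function(n0, m0, s0, n1, m1, s1) {
  stopifnot(all(n0 >= 2), all(n1 >= 2))
  v0 <- s0^2 / n0
  v1 <- s1^2 / n1
  se <- sqrt(v0 + v1)
  t <- abs(m1 - m0) / se
  df <- (v0 + v1)^2 / (v0^2 / (n0 - 1) + v1^2 / (n1 - 1))
  p <- stats::pt(t, df, lower.tail = FALSE)
  p[se == 0 & m0 == m1] <- 0.5
  list(statistic = t, df = df, p_value = p)
}

#' Compare all model variables between two patient groups
#'
#' One row per canonical feature column: group sizes, means, SDs, the
#' one-sided Welch p-value (direction of the observed difference) and the
#' absolute Cohen's d. `Gender` is compared on its 0/1 coding like any other
#' variable.
#'
#' @param features Feature data frame ([compute_features()] rows, with
#'   `patient_id`).
#' @param labels Data frame with `patient_id` and the three label columns.
#' @param split `"any"` (no comorbidity vs at least one) or one of
#'   `"hypertension"`, `"diabetes"`, `"asthma_copd"`.
#' @param p_adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) mirrors plain
#'   per-variable reporting.
#' @return Data frame with columns `variable`, `n_no`, `mean_no`, `sd_no`,
#'   `n_yes`, `mean_yes`, `sd_yes`, `p_value`, `effect_size`.
#' @export
compare_groups <- function(features, labels,
                           split = c("any", "hypertension", "diabetes",
                                     "asthma_copd"),
                           p_adjust = "none") {
  split <- match.arg(split)
  lab_cols <- c("patient_id", "hypertension", "diabetes", "asthma_copd")
  df <- merge(features, labels[, lab_cols], by = "patient_id")
  grp <- if (split == "any") {
    as.integer(df$hypertension | df$diabetes | df$asthma_copd)
  } else df[[split]]
  if (sum(grp == 0) < 2 || sum(grp == 1) < 2)
    stop("both groups need at least 2 members (split = ", split, ")")
  rows <- lapply(feature_columns(), function(v) {
    x0 <- df[[v]][grp == 0]
    x1 <- df[[v]][grp == 1]
    x0 <- x0[is.finite(x0)]; x1 <- x1[is.finite(x1)]
    w <- welch_one_sided(length(x0), mean(x0), stats::sd(x0),
                         length(x1), mean(x1), stats::sd(x1))
    data.frame(
      variable = v,
      n_no = length(x0), mean_no = mean(x0), sd_no = stats::sd(x0),
      n_yes = length(x1), mean_yes = mean(x1), sd_yes = stats::sd(x1),
      p_value = w$p_value,
      effect_size = cohens_d(length(x0), mean(x0), stats::sd(x0),
                             length(x1), mean(x1), stats::sd(x1))
    )
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") out$p_value <- stats::p.adjust(out$p_value, p_adjust)
  out
}

#' Default AHI severity bin edges
#'
#' Standard clinical cut-offs: normal (< 5), mild (5-15), moderate (15-30),
#' severe (>= 30) events/hour.
#' @return Numeric vector of interior bin edges.
#' @export
ahi_severity_edges <- function() c(5, 15, 30)

#' Slope summaries across AHI severity strata
#'
#' Per severity category: size, mean/SD of `mean_slope`, of slope/Age and of
#' slope/BMI, plus a one-sided Welch comparison of `mean_slope` between
#' patients with and without any comorbidity inside the category.
#'
#' @param features Feature data frame with `patient_id`.
#' @param labels Label data frame with `patient_id`.
#' @param edges Interior AHI bin edges (default [ahi_severity_edges()]).
#' @return Data frame, one row per stratum.
#' @export
severity_strata <- function(features, labels, edges = ahi_severity_edges()) {
  lab_cols <- c("patient_id", "hypertension", "diabetes", "asthma_copd")
  df <- merge(features, labels[, lab_cols], by = "patient_id")
  if (any(!is.finite(df$AHI))) stop("AHI must be present for every patient")
  breaks <- c(-Inf, edges, Inf)
  lab <- c(paste0("<", edges[1]),
           paste(head2(edges), utils::tail(edges, -1), sep = "-"),
           paste0(">=", edges[length(edges)]))
  cat_ <- cut(df$AHI, breaks = breaks, labels = lab, right = FALSE)
  any_lbl <- as.integer(df$hypertension | df$diabetes | df$asthma_copd)
  rows <- lapply(levels(cat_), function(lv) {
    sub <- df[cat_ == lv, , drop = FALSE]
    g <- any_lbl[cat_ == lv]
    p <- NA_real_
    if (sum(g == 0) >= 2 && sum(g == 1) >= 2) {
      s0 <- sub$mean_slope[g == 0]; s1 <- sub$mean_slope[g == 1]
      p <- welch_one_sided(length(s0), mean(s0), stats::sd(s0),
                           length(s1), mean(s1), stats::sd(s1))$p_value
    }
    data.frame(
      stratum = lv, n = nrow(sub),
      mean_slope = if (nrow(sub)) mean(sub$mean_slope) else NA_real_,
      sd_slope = if (nrow(sub) > 1) stats::sd(sub$mean_slope) else NA_real_,
      mean_slope_over_age = if (nrow(sub)) mean(sub$mean_slope / sub$Age)
                            else NA_real_,
      mean_slope_over_bmi = if (nrow(sub)) mean(sub$mean_slope / sub$BMI)
                            else NA_real_,
      p_comorbidity = p
    )
  })
  do.call(rbind, rows)
}

head2 <- function(x) x[-length(x)]

#' Reference cohort group-comparison summaries
#'
#' Published per-variable group sizes, means, SDs, p-values and effect
#' sizes for four comparisons of a 144-patient OSA cohort ("any"
#' comorbidity vs none, and each single comorbidity vs its absence). Used
#' to validate [cohens_d()] and [welch_one_sided()] against printed values.
#'
#' @return Data frame (44 rows).
#' @export
reference_group_stats <- function() {
  utils::read.csv(system.file("extdata", "reference_group_stats.csv",
                              package = "psgcomorb"),
                  stringsAsFactors = FALSE)
}

#' Bundled example rows of the structured feature matrix
#'
#' Ten example patients' clinical + engineered feature rows (with synthetic
#' ids) in the canonical column order, used as an I/O and schema fixture.
#'
#' @return Data frame with `patient_id` plus the 11 feature columns.
#' @export
reference_example_features <- function() {
  read_feature_matrix(system.file("extdata", "reference_example_features.csv",
                                  package = "psgcomorb"))
}
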