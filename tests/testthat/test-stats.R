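test_that("odds ratios and Woolf CIs reproduce the published contingency rows", {
  fx <- fixture_paper_tables()$tables
  check <- function(tab, or, lo = NA, hi = NA) {
    res <- odds_ratio(tab)
    expect_equal(round(res$odds_ratio, 2), or)
    if (!is.na(lo)) expect_equal(round(res$ci_low, 2), lo)
    if (!is.na(hi)) expect_equal(round(res$ci_high, 2), hi)
  }
  check(fx$sns_le8_all, 14.41, 5.06, 41.02)
  check(fx$eos_all, 1.12, 0.42, 2.99)
  check(fx$eos_term, 1.50, 0.29, 7.64)
  check(fx$eos_preterm, 1.36, 0.36, 5.12)
  check(fx$sns_le8_term, 1.80, 0.20, 16.27)
})

test_that("balanced table gives OR 1 with a log-symmetric CI", {
  res <- odds_ratio(two_by_two(10, 10, 10, 10))
  expect_equal(res$odds_ratio, 1)
  expect_equal(log(res$ci_low), -log(res$ci_high))
})

test_that("zero cells are undefined unless the Haldane correction is asked for", {
  tab <- fixture_paper_tables()$tables$sns_le8_preterm  # 0 unexposed deaths
  res <- odds_ratio(tab)
  expect_true(res$undefined)
  expect_true(is.na(res$odds_ratio))
  resh <- odds_ratio(tab, haldane = TRUE)
  expect_false(resh$undefined)
  expect_true(is.finite(resh$odds_ratio) && resh$odds_ratio > 1)
  expect_error(two_by_two(-1, 2, 3, 4), "non-negative")
})

test_that("OR transformation invariances", {
  set.seed(4)
  for (i in 1:20) {
    cells <- sample(1:50, 4)
    or0 <- odds_ratio(do.call(two_by_two, as.list(cells)))$odds_ratio
    # swap exposure rows only: inverts
    or_r <- odds_ratio(two_by_two(cells[3], cells[4], cells[1], cells[2]))
    expect_equal(or_r$odds_ratio, 1 / or0)
    # swap outcome columns only: inverts
    or_c <- odds_ratio(two_by_two(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(or_c$odds_ratio, 1 / or0)
    # swap both: unchanged
    or_b <- odds_ratio(two_by_two(cells[4], cells[3], cells[2], cells[1]))
    expect_equal(or_b$odds_ratio, or0)
  }
})

test_that("Pearson chi-square matches the base-R oracle and the z^2 identity", {
  # proportional rows: no association at all
  prop <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  res0 <- chi_square_2xk(prop)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  set.seed(9)
  for (i in 1:20) {
    m <- matrix(sample(1:40, 6), 2, 3)
    ours <- chi_square_2xk(m)
    oracle <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(ours$statistic, unname(oracle$statistic))
    expect_equal(ours$df, unname(oracle$parameter))
    expect_equal(ours$p_value, oracle$p.value)
  }

  # 2x2 statistic equals the squared two-proportion z with pooled variance
  m <- matrix(c(15, 5, 66, 317), 2, byrow = TRUE)
  n1 <- sum(m[1, ]); n2 <- sum(m[2, ])
  p1 <- m[1, 1] / n1; p2 <- m[2, 1] / n2; pp <- sum(m[, 1]) / sum(m)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(chi_square_2xk(m)$statistic, z^2)

  # a near-null published row evaluates as non-significant
  expect_gt(chi_square_2xk(matrix(c(2, 17, 39, 344), 2, byrow = TRUE))$p_value,
            0.9)
  expect_error(chi_square_2xk(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("Mann-Whitney U: structure, exact agreement and tie handling", {
  expect_equal(mann_whitney_u(1:4, 1:4)$statistic, 8)  # m*n/2
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")

  # tie-free small samples: exact enumeration equals wilcox.test's exact law
  set.seed(31)
  for (i in 1:25) {
    v <- sample(1:500, 11)
    x <- v[1:5]; y <- v[6:11]
    ours <- mann_whitney_u(x, y)
    oracle <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$statistic, unname(oracle$statistic))
    expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-12)
  }

  # continuous m = n = 6 samples: the corrected normal approximation stays
  # within 0.02 of the exact enumeration
  set.seed(32)
  for (i in 1:25) {
    x <- runif(6); y <- runif(6, 0.2, 1.2)
    exact <- mann_whitney_u(x, y)
    approx <- mann_whitney_u(x, y, exact_max = 0L)
    expect_lt(abs(approx$p_value - exact$p_value), 0.02)
  }

  # large-sample tied path agrees with wilcox.test's tie-corrected normal p
  set.seed(33)
  x <- sample(1:10, 30, replace = TRUE); y <- sample(3:12, 25, replace = TRUE)
  ours <- mann_whitney_u(x, y)
  oracle <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, oracle$p.value, tolerance = 1e-10)
})

test_that("ROC: degenerate geometries and the Youden optimum", {
  sep <- roc_curve(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                   "higher_is_event")
  expect_equal(sep$auc, 1)
  expect_equal(sep$optimal_sens, 1)
  expect_equal(sep$optimal_spec, 1)

  # identical score distributions in both classes: no discrimination
  flat <- roc_curve(rep(c(1, 2), 10), rep(c(TRUE, FALSE), each = 10),
                    "higher_is_event")
  expect_equal(flat$auc, 0.5)

  expect_error(roc_curve(1:5, rep(TRUE, 5), "higher_is_event"), "classes")

  # tied Youden maxima resolve to the smaller threshold
  tie <- roc_curve(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE),
                   "higher_is_event")
  js <- tie$operating_points$sensitivity + tie$operating_points$specificity - 1
  cands <- tie$operating_points$threshold[js == max(js)]
  expect_equal(tie$optimal_cutoff, min(cands))
})

test_that("AUC equals pair counting, in both directions, on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:14, 1)
    scores <- sample(1:8, n, replace = TRUE)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    hi <- roc_curve(scores, labels, "higher_is_event")
    expect_equal(hi$auc, pair_count_auc(scores, labels))
    lo <- roc_curve(scores, labels, "lower_is_event")
    expect_equal(lo$auc, pair_count_auc(-scores, labels))
    # complement and monotone-transform invariances
    expect_equal(hi$auc + lo$auc, 1)
    expect_equal(roc_curve(exp(scores / 2), labels, "higher_is_event")$auc,
                 hi$auc)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(80) + rep(c(0, 1), each = 40)
  labels <- rep(c(FALSE, TRUE), each = 40)
  ours <- roc_curve(scores, labels, "higher_is_event")
  oracle <- pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                direction = "<"))
  expect_equal(ours$auc, as.numeric(oracle))
})

test_that("AUC equals the trapezoidal area under the operating points", {
  set.seed(29)
  scores <- sample(1:6, 40, replace = TRUE)
  labels <- runif(40) < plogis(scores - 3)
  labels[1:2] <- c(TRUE, FALSE)
  r <- roc_curve(scores, labels, "higher_is_event")
  fpr <- c(1, 1 - r$operating_points$specificity, 0)
  tpr <- c(1, r$operating_points$sensitivity, 0)
  trap <- sum(diff(rev(fpr)) * (rev(tpr)[-1] + rev(tpr)[-length(tpr)]) / 2)
  expect_equal(r$auc, trap)
})
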