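# Outcome dichotomization, group comparison gating, summary statistics,
# correlation analyses, MCA.

test_that("GOS dichotomization splits at 3 and validates input", {
  gos <- rep(1:5, times = c(39, 20, 10, 7, 5))
  out <- dichotomize_outcome(gos)
  expect_equal(unname(table(out)["favorable"]), 22, ignore_attr = TRUE)
  expect_equal(unname(table(out)["unfavorable"]), 59, ignore_attr = TRUE)
  expect_equal(as.character(dichotomize_outcome(3)), "favorable")
  expect_equal(as.character(dichotomize_outcome(2)), "unfavorable")
  expect_error(dichotomize_outcome(c(1, 6)), "1..5")
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.5, 10)), rep(0.5, 10))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  # manual step-up: p_(i) * m / i, cumulative minimum from the top, cap at 1
  m <- length(p)
  manual <- rev(cummin(rev(sort(p) * m / seq_len(m))))[order(order(p))]
  expect_equal(bh_adjust(p), pmin(1, manual))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("group comparison picks t for clean normal shifts and U for skewed data", {
  mk <- function(x1, x2) {
    tibble::tibble(outcome = factor(rep(c("favorable", "unfavorable"),
                                        c(length(x1), length(x2))),
                                    levels = c("favorable", "unfavorable")),
                   f = c(x1, x2))
  }
  set.seed(101)
  shifted <- mk(rnorm(30), rnorm(30, mean = 2))
  cmp <- compare_groups(shifted, feature_cols = "f")
  expect_equal(cmp$test, "t")
  expect_lt(cmp$p_adj, 0.05)
  expect_match(cmp$summary_favorable, "±")

  set.seed(102)
  skewed <- mk(rlnorm(30), rlnorm(30, meanlog = 1))
  cmp2 <- compare_groups(skewed, feature_cols = "f")
  expect_equal(cmp2$test, "U")
  expect_match(cmp2$summary_favorable, "\\(")

  # z sign convention: favorable ranking higher gives positive z
  high_fav <- mk(rnorm(30, 10), rnorm(30, 0))
  expect_gt(compare_groups(high_fav, feature_cols = "f")$statistic, 0)
  low_fav <- mk(rlnorm(30), rlnorm(30, meanlog = 2))
  expect_lt(compare_groups(low_fav, feature_cols = "f")$statistic, 0)

  # zero-variance feature reported with missing test
  flat <- mk(rep(1, 10), rep(1, 12))
  cmp3 <- compare_groups(flat, feature_cols = "f")
  expect_true(is.na(cmp3$test))
  expect_true(is.na(cmp3$p))
})

test_that("BH keeps the false discovery rate near zero on null feature panels", {
  n_feat <- 24
  hits <- 0L
  total <- 0L
  set.seed(2024)
  for (rep in 1:20) {
    d <- tibble::tibble(outcome = factor(rep(c("favorable", "unfavorable"),
                                             c(25, 25)),
                                         levels = c("favorable", "unfavorable")))
    for (j in seq_len(n_feat)) d[[paste0("f", j)]] <- rnorm(50)
    cmp <- compare_groups(d, feature_cols = paste0("f", seq_len(n_feat)))
    hits <- hits + sum(cmp$p_adj < 0.05, na.rm = TRUE)
    total <- total + n_feat
  }
  expect_lt(hits / total, 0.01)
})

test_that("summary-table t and chi-squared statistics are recomputed correctly", {
  # closed-form check of the pooled t
  tt <- ttest_from_summary(1, 1, 10, 0, 1, 10)
  sp <- sqrt(((9 * 1 + 9 * 1) / 18) * (1 / 10 + 1 / 10))
  expect_equal(tt$t, 1 / sp, tolerance = 1e-12)
  expect_equal(tt$df, 18)
  expect_equal(ttest_from_summary(5, 2, 12, 5, 3, 15)$t, 0)

  expect_equal(chi2_contingency(rbind(c(10, 0), c(0, 10)))$chisq, 20)
  expect_equal(chi2_contingency(rbind(c(10, 0), c(0, 10)))$df, 1)
  prop <- rbind(c(10, 20), c(30, 60))
  expect_equal(chi2_contingency(prop)$chisq, 0, tolerance = 1e-12)
  expect_error(chi2_contingency(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("partial correlation removes control-mediated association", {
  set.seed(55)
  n <- 500
  z <- rnorm(n)
  pc1 <- partial_correlation(z + rnorm(n, sd = 0.1), z * 2, z + rnorm(n, sd = 3))
  expect_gt(pc1$rho, 0.9)  # y is a monotone function of x

  x <- z + rnorm(n); y <- z + rnorm(n)
  pc2 <- partial_correlation(x, y, z)
  expect_lt(abs(pc2$rho), 0.12)  # association entirely via z
  expect_gt(pc2$p, 0.01)

  # controlling for a close proxy of x itself leaves nothing
  pc3 <- partial_correlation(x, y, x + rnorm(n, sd = 0.5))
  expect_lt(abs(pc3$rho), 0.15)

  # a perfectly collinear control is reported missing
  pc4 <- partial_correlation(x, y, x)
  expect_true(is.na(pc4$rho))
})

test_that("Spearman correlation handles monotone and noisy ordinal outcomes", {
  x <- c(3, 9, 27, 81, 243, 729)
  expect_equal(spearman_with_gos(x, 1:6)$rho, 1)
  expect_equal(spearman_with_gos(x, 6:1)$rho, -1)
  set.seed(66)
  n <- 200
  u <- rnorm(n)
  v <- 0.5 * u + sqrt(1 - 0.25) * rnorm(n)
  sp <- spearman_with_gos(u, v)
  expect_equal(sp$rho, 0.48, tolerance = 0.12)
  expect_true(is.na(spearman_with_gos(rep(1, 10), 1:10)$rho))
})

test_that("MCA discrimination measures reflect association with the outcome", {
  # balanced classes: a median split can only align exactly with the outcome
  # when the groups are of equal size
  set.seed(88)
  n <- 80
  outcome <- factor(rep(c("favorable", "unfavorable"), c(40, 40)),
                    levels = c("favorable", "unfavorable"))
  sep <- ifelse(outcome == "unfavorable", 1, 0) + rnorm(n, sd = 0.01)
  sep2 <- ifelse(outcome == "unfavorable", 5, -5) + rnorm(n, sd = 0.01)
  indep <- rnorm(n)
  d <- tibble::tibble(outcome = outcome, a = sep, b = sep2, c = indep)

  m <- mca_discriminate(d, c("a", "b"))
  disc <- m$discrimination
  expect_gt(disc$dim1[disc$variable == "a"], 0.95)
  expect_gt(disc$dim1[disc$variable == "b"], 0.95)
  expect_gt(disc$dim1[disc$variable == "outcome"], 0.95)
  # sign convention: unfavorable category positive on dimension 1
  cats <- m$categories
  expect_gt(cats$dim1[cats$variable == "outcome" & cats$category == "unfavorable"], 0)

  m2 <- mca_discriminate(d, c("a", "b", "c"))
  d2 <- m2$discrimination
  expect_lt(d2$dim1[d2$variable == "c"], 0.2)

  # duplicated variable gets identical category coordinates
  d$dup <- d$a
  m3 <- mca_discriminate(d, c("a", "dup", "c"))
  ca <- m3$categories
  expect_equal(ca$dim1[ca$variable == "a"], ca$dim1[ca$variable == "dup"],
               tolerance = 1e-9)

  # single-category variables are dropped with a warning
  d$flat <- 1
  expect_warning(mca_discriminate(d, c("a", "flat")), "flat")
})
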