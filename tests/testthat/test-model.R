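# Logistic models, stepwise selection, stratified folds, prognostic
# characteristics, ROC/AUC.

mk_outcome <- function(y) {
  factor(ifelse(y == 1, "unfavorable", "favorable"),
         levels = c("favorable", "unfavorable"))
}

test_that("single-feature logistic recovers parameters and flags degeneracy", {
  # null feature: OR ~ 1, p ~ 1
  set.seed(10)
  d0 <- tibble::tibble(outcome = mk_outcome(rbinom(200, 1, 0.5)), x = rnorm(200))
  f0 <- fit_logistic_single(d0, "x")
  expect_equal(f0$or, 1, tolerance = 0.35)
  expect_gt(f0$p, 0.05)

  # recovery of logit p = -1 + 2x at n = 2000
  set.seed(11)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(-1 + 2 * x))
  fr <- fit_logistic_single(tibble::tibble(outcome = mk_outcome(y), x = x), "x")
  expect_equal(fr$estimate, 2, tolerance = 0.15 / 2)
  expect_true(fr$or_low <= fr$or && fr$or <= fr$or_high)

  # complete separation is flagged with an unbounded CI
  dsep <- tibble::tibble(outcome = mk_outcome(rep(c(0, 1), each = 20)),
                         x = c(rnorm(20, -5), rnorm(20, 5)))
  fs <- fit_logistic_single(dsep, "x")
  expect_true(fs$separation)
  expect_equal(fs$or_high, Inf)
})

test_that("stepwise LR selection keeps signal, rejects noise, breaks collinear ties", {
  sim_once <- function(seed) {
    set.seed(seed)
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(-0.5 + 1.5 * x))
    tibble::tibble(outcome = mk_outcome(y), signal = x, noise = rnorm(400))
  }
  only_signal <- 0L
  for (seed in 1:100) {
    sw <- fit_logistic_stepwise_lr(sim_once(seed), c("signal", "noise"))
    if (identical(sw$terms, "signal")) only_signal <- only_signal + 1L
  }
  expect_gte(only_signal, 90)

  # identical copies: exactly one enters
  d <- sim_once(7)
  d$copy <- d$signal
  sw2 <- fit_logistic_stepwise_lr(d, c("signal", "copy"))
  expect_equal(sw2$terms, "signal")

  # all-noise candidates: intercept-only in ~95% of replicates
  null_rate <- 0L
  for (seed in 1:100) {
    set.seed(seed + 500)
    dn <- tibble::tibble(outcome = mk_outcome(rbinom(150, 1, 0.5)),
                         z = rnorm(150))
    sw3 <- fit_logistic_stepwise_lr(dn, "z")
    if (sw3$intercept_only) null_rate <- null_rate + 1L
  }
  expect_gte(null_rate, 88)
})

test_that("stratified folds balance sizes and outcome-by-etiology cells", {
  gos <- rep(1:5, times = c(39, 20, 10, 7, 5))
  outcome <- dichotomize_outcome(gos)
  set.seed(3)
  etio <- sample(c("stroke", "tbi", "other"), 81, replace = TRUE)
  fold <- stratified_kfold(outcome, etio, k = 3, seed = 42)
  expect_equal(unname(table(fold)), rep(27, 3), ignore_attr = TRUE)
  fav_per_fold <- table(fold[outcome == "favorable"])
  expect_true(all(fav_per_fold %in% 7:8))
  # per-cell spread <= 1, and determinism
  for (cell in unique(paste(outcome, etio))) {
    idx <- paste(outcome, etio) == cell
    counts <- tabulate(fold[idx], 3)
    expect_lte(max(counts) - min(counts), 1)
  }
  expect_identical(fold, stratified_kfold(outcome, etio, k = 3, seed = 42))

  # property: random cases keep both balance rules
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:60, 1)
    oc <- sample(c("favorable", "unfavorable"), n, replace = TRUE)
    et <- sample(letters[1:4], n, replace = TRUE)
    f <- stratified_kfold(oc, et, k = 3, seed = seed)
    expect_lte(diff(range(tabulate(f, 3))), 1)
    for (cell in unique(paste(oc, et))) {
      counts <- tabulate(f[paste(oc, et) == cell], 3)
      expect_lte(max(counts) - min(counts), 1)
    }
  }
})

test_that("prognostic characteristics come from the confusion matrix with Wilson CIs", {
  perfect <- prognostic_characteristics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  est <- setNames(perfect$estimate, perfect$metric)
  expect_equal(unname(est[c("sensitivity", "specificity", "ppv", "npv")]),
               rep(1, 4))
  expect_equal(unname(est["fpr"]), 0)

  ranked <- prognostic_characteristics(c(0.9, 0.6, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(setNames(ranked$estimate, ranked$metric)[c("sensitivity", "specificity")],
               c(sensitivity = 1, specificity = 1))

  const <- prognostic_characteristics(rep(0.6, 10), rep(c(1, 0), 5))
  cst <- setNames(const$estimate, const$metric)
  expect_equal(unname(cst["sensitivity"]), 1)
  expect_equal(unname(cst["specificity"]), 0)
  expect_equal(unname(cst["fpr"]), 1)

  expect_error(prognostic_characteristics(numeric(0), numeric(0)), "empty")

  # Wilson CI property: contains the point estimate, lies in [0, 1]
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:50, 1); k <- sample(0:n, 1)
    w <- wilson_ci(k, n)
    expect_gte(w["estimate"], w["lower"] - 1e-12)
    expect_lte(w["estimate"], w["upper"] + 1e-12)
    expect_gte(w["lower"], 0); expect_lte(w["upper"], 1)
  }
})

test_that("merged-fold AUC matches the pairwise concordance oracle and pROC", {
  oracle_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(19)
  for (i in 1:50) {
    n <- sample(12:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    got <- roc_auc_merged(p, y)
    expect_equal(got$auc, oracle_auc(p, y), tolerance = 1e-12)
  }

  # perfect ranking
  expect_equal(roc_auc_merged(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)

  # null predictions at n = 2000
  set.seed(20)
  y <- rbinom(2000, 1, 0.5); p <- runif(2000)
  expect_equal(roc_auc_merged(p, y)$auc, 0.5, tolerance = 0.03)

  # complement symmetry
  expect_equal(roc_auc_merged(p, y)$auc + roc_auc_merged(1 - p, y)$auc, 1,
               tolerance = 1e-12)

  # DeLong interval cross-checked against pROC
  skip_if_not_installed("pROC")
  set.seed(21)
  y2 <- rbinom(120, 1, 0.5)
  p2 <- plogis(rnorm(120) + y2)
  got <- roc_auc_merged(p2, y2)
  ref <- pROC::ci.auc(pROC::roc(y2, p2, quiet = TRUE), method = "delong")
  expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-9)
  expect_equal(got$conf_low, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(got$conf_high, as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("cross-validated prognosis produces out-of-fold predictions and sane AUCs", {
  set.seed(30)
  n <- 90
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * x))
  d <- tibble::tibble(outcome = mk_outcome(y), strong = x, weak = rnorm(n),
                      etiology = sample(c("a", "b"), n, replace = TRUE))
  cv <- cv_prognosis(d, list(strong = "strong", weak = "weak"), k = 3, seed = 5)
  expect_true(all(!is.na(cv$predictions$prob)))
  auc <- setNames(cv$auc$auc, cv$auc$model)
  expect_gt(auc["strong"], 0.75)
  expect_lt(abs(auc["weak"] - 0.5), 0.2)
  chars <- cv$characteristics
  expect_true(all(chars$estimate >= 0 & chars$estimate <= 1, na.rm = TRUE))
  # FPR = 1 - specificity within each model x fold
  wide <- tidyr::pivot_wider(chars[, c("model", "fold", "metric", "estimate")],
                             names_from = "metric", values_from = "estimate")
  expect_equal(wide$fpr, 1 - wide$specificity, tolerance = 1e-12)
})
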