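# Prognostic modeling: logistic regression (single and stepwise LR-driven),
# stratified K-fold cross-validation, prognostic characteristics at a
# probability cutoff, and merged-fold ROC/AUC with DeLong intervals.

# 0/1 indicator of the positive (unfavorable) class
as_positive <- function(outcome) {
  if (is.numeric(outcome)) {
    stopifnot(all(outcome %in% c(0, 1)))
    return(as.integer(outcome))
  }
  as.integer(as.character(outcome) == "unfavorable")
}

# detect (quasi-)complete separation from a fitted binomial glm
detect_separation <- function(fit) {
  mu <- fitted(fit)
  all(mu > 1 - 1e-7 | mu < 1e-7) || any(abs(coef(fit)[-1]) > 15)
}

#' Logistic regression on a single feature
#'
#' Maximum-likelihood fit of unfavorable outcome on one feature, reporting the
#' odds ratio with a Wald 95% CI. Complete separation is flagged and the CI
#' reported as unbounded rather than as a numeric artifact.
#'
#' @param features Tibble of patients.
#' @param feature Feature column name.
#' @param outcome_col Outcome column ([dichotomize_outcome()] factor or 0/1
#'   with 1 = unfavorable).
#' @param conf Confidence level (default 0.95).
#' @return Tibble of class `fp_logistic`: `term`, `estimate` (log-odds),
#'   `or`, `or_low`, `or_high`, `p`, `separation`.
#' @export
fit_logistic_single <- function(features, feature, outcome_col = "outcome",
                                conf = 0.95) {
  y <- as_positive(features[[outcome_col]])
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  d <- data.frame(y = y, x = features[[feature]])
  fit <- suppressWarnings(glm(y ~ x, data = d, family = binomial()))
  sm <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf) / 2)
  sep <- detect_separation(fit)
  out <- tibble::tibble(
    term = feature,
    estimate = sm["x", "Estimate"],
    or = exp(sm["x", "Estimate"]),
    or_low = if (sep) 0 else exp(sm["x", "Estimate"] - z * sm["x", "Std. Error"]),
    or_high = if (sep) Inf else exp(sm["x", "Estimate"] + z * sm["x", "Std. Error"]),
    p = sm["x", "Pr(>|z|)"],
    separation = sep
  )
  class(out) <- c("fp_logistic", class(out))
  out
}

#' Stepwise logistic regression driven by likelihood-ratio tests
#'
#' Forward selection with backward pruning: at each forward step the candidate
#' whose addition gives the smallest likelihood-ratio chi-squared p-value
#' enters if that p < `p_enter` (ties broken by input order); after every
#' entry, any included term whose removal LR p exceeds `p_remove` is dropped
#' (largest first). Deterministic given the candidate order. If nothing
#' enters, the intercept-only model is returned with a flag.
#'
#' @param features Tibble of patients.
#' @param candidates Character vector of candidate feature columns.
#' @param outcome_col Outcome column.
#' @param p_enter,p_remove Entry/removal thresholds (defaults 0.05 / 0.10).
#' @return List of class `fp_stepwise`: `terms` (selected, in entry order),
#'   `coefficients` (tibble as in [fit_logistic_single()], one row per term),
#'   `fit` (the final `glm`), `intercept_only`, `trace` (entry/removal log).
#' @export
fit_logistic_stepwise_lr <- function(features, candidates,
                                     outcome_col = "outcome",
                                     p_enter = 0.05, p_remove = 0.10) {
  stopifnot(length(candidates) >= 1)
  y <- as_positive(features[[outcome_col]])
  d <- data.frame(features[, candidates, drop = FALSE], y = y, check.names = FALSE)
  dev_of <- function(terms) {
    f <- if (length(terms)) {
      stats::reformulate(sprintf("`%s`", terms), response = "y")
    } else y ~ 1
    suppressWarnings(glm(f, data = d, family = binomial()))
  }
  lr_p <- function(small, big) {
    stat <- small$deviance - big$deviance
    df <- small$df.residual - big$df.residual
    if (df <= 0 || stat < 0) return(1)
    pchisq(stat, df, lower.tail = FALSE)
  }
  included <- character(0)
  trace <- character(0)
  repeat {
    current <- dev_of(included)
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(tm) lr_p(current, dev_of(c(included, tm))),
                      numeric(1))
      best <- which(pvals == min(pvals))[1]  # ties: smaller p, then input order
      if (pvals[best] < p_enter) {
        included <- c(included, pool[best])
        trace <- c(trace, sprintf("+%s (LR p = %.4g)", pool[best], pvals[best]))
        # backward pruning
        repeat {
          full <- dev_of(included)
          if (length(included) < 2) break
          rp <- vapply(included, function(tm) {
            lr_p(dev_of(setdiff(included, tm)), full)
          }, numeric(1))
          worst <- which.max(rp)
          if (rp[worst] > p_remove) {
            trace <- c(trace, sprintf("-%s (LR p = %.4g)", included[worst], rp[worst]))
            included <- included[-worst]
          } else break
        }
        next
      }
    }
    break
  }
  fit <- dev_of(included)
  coefs <- if (length(included)) {
    sm <- summary(fit)$coefficients
    rownames(sm) <- gsub("`", "", rownames(sm))
    z <- qnorm(0.975)
    sep <- detect_separation(fit)
    dplyr::bind_rows(lapply(included, function(tm) {
      tibble::tibble(
        term = tm,
        estimate = sm[tm, "Estimate"],
        or = exp(sm[tm, "Estimate"]),
        or_low = if (sep) 0 else exp(sm[tm, "Estimate"] - z * sm[tm, "Std. Error"]),
        or_high = if (sep) Inf else exp(sm[tm, "Estimate"] + z * sm[tm, "Std. Error"]),
        p = sm[tm, "Pr(>|z|)"],
        separation = sep
      )
    }))
  } else tibble::tibble()
  structure(
    list(terms = included, coefficients = coefs, fit = fit,
         intercept_only = length(included) == 0, trace = trace),
    class = "fp_stepwise"
  )
}

#' Stratified K-fold assignment
#'
#' Folds are balanced jointly on outcome and etiology: within every
#' outcome-by-etiology cell, members are dealt (after a seeded shuffle) across
#' the folds in ascending order of current fold size, so per-cell counts
#' across folds differ by at most 1, and overall fold sizes differ by at most
#' 1. Cells are processed largest first. Reproducible from `seed`.
#'
#' @param outcome Outcome vector.
#' @param etiology Etiology category vector (optional; single stratum if
#'   `NULL`).
#' @param k Number of folds (default 3).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..k.
#' @export
stratified_kfold <- function(outcome, etiology = NULL, k = 3, seed = 1) {
  n <- length(outcome)
  stopifnot(n >= k)
  if (is.null(etiology)) etiology <- rep("all", n)
  cell <- paste(outcome, etiology, sep = "\r")
  rng <- local({
    set.seed(as.integer(seed %% .Machine$integer.max))
    lapply(split(seq_len(n), cell), function(v) v[sample.int(length(v))])
  })
  sizes <- vapply(rng, length, integer(1))
  fold <- integer(n)
  totals <- integer(k)
  for (idx in rng[order(-sizes)]) {
    # deal cycle by cycle; re-rank folds by current size at each cycle so the
    # smallest folds fill first (keeps overall sizes within 1)
    i <- 1L
    while (i <= length(idx)) {
      ord <- order(totals, seq_len(k))
      for (f in ord) {
        if (i > length(idx)) break
        fold[idx[i]] <- f
        totals[f] <- totals[f] + 1L
        i <- i + 1L
      }
    }
  }
  fold
}

#' Prognostic characteristics at a probability cutoff
#'
#' Confusion-matrix proportions for predicting the unfavorable (positive)
#' class at `prob >= cutoff`: sensitivity, specificity, PPV, NPV and the
#' false-positive rate (1 - specificity), each with a Wilson score 95% CI.
#'
#' @param prob Predicted probabilities of unfavorable outcome.
#' @param labels Outcome labels (factor or 0/1, 1 = unfavorable).
#' @param cutoff Probability cutoff (default 0.5).
#' @param conf Confidence level for the Wilson intervals.
#' @return Tibble: `metric`, `estimate`, `conf_low`, `conf_high`. Metrics
#'   whose denominator is empty are `NA`.
#' @export
prognostic_characteristics <- function(prob, labels, cutoff = 0.5, conf = 0.95) {
  if (length(prob) == 0) stop("empty prediction set")
  y <- as_positive(labels)
  pred <- as.integer(prob >= cutoff)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  fp <- sum(pred == 1 & y == 0); tn <- sum(pred == 0 & y == 0)
  rows <- list(
    sensitivity = wilson_ci(tp, tp + fn, conf),
    specificity = wilson_ci(tn, tn + fp, conf),
    ppv = wilson_ci(tp, tp + fp, conf),
    npv = wilson_ci(tn, tn + fn, conf),
    fpr = {
      w <- wilson_ci(fp, fp + tn, conf)
      w
    }
  )
  tibble::tibble(
    metric = names(rows),
    estimate = vapply(rows, `[[`, numeric(1), "estimate"),
    conf_low = vapply(rows, `[[`, numeric(1), "lower"),
    conf_high = vapply(rows, `[[`, numeric(1), "upper")
  )
}

# AUC by the rank (Mann-Whitney) formulation with tie handling
auc_rank <- function(prob, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC via placement values
delong_var <- function(prob, y) {
  pos <- prob[y == 1]; neg <- prob[y == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(p) (sum(p > neg) + 0.5 * sum(p == neg)) / n,
                numeric(1))
  v01 <- vapply(neg, function(q) (sum(pos > q) + 0.5 * sum(pos == q)) / m,
                numeric(1))
  var(v10) / m + var(v01) / n
}

#' Merged-fold ROC AUC with DeLong interval
#'
#' Pools out-of-fold predicted probabilities and computes the AUC by the rank
#' (Mann-Whitney) formulation with tie handling; the CI is DeLong's, truncated
#' to `[0, 1]`.
#'
#' @param prob Pooled out-of-fold probabilities of unfavorable outcome.
#' @param labels Outcome labels (1/unfavorable = positive).
#' @param conf Confidence level (default 0.95).
#' @return Tibble with `auc`, `conf_low`, `conf_high`.
#' @export
roc_auc_merged <- function(prob, labels, conf = 0.95) {
  y <- as_positive(labels)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  auc <- auc_rank(prob, y)
  se <- sqrt(delong_var(prob, y))
  z <- qnorm(1 - (1 - conf) / 2)
  tibble::tibble(auc = auc,
                 conf_low = max(0, auc - z * se),
                 conf_high = min(1, auc + z * se))
}

#' ROC curve coordinates
#'
#' @param prob Predicted probabilities (positive = unfavorable).
#' @param labels Outcome labels.
#' @return Tibble with `threshold`, `fpr`, `tpr`, sorted for plotting.
#' @export
roc_curve <- function(prob, labels) {
  y <- as_positive(labels)
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE), -Inf)
  res <- lapply(thr, function(t) {
    pred <- prob >= t
    c(fpr = sum(pred & y == 0) / sum(y == 0),
      tpr = sum(pred & y == 1) / sum(y == 1))
  })
  m <- do.call(rbind, res)
  tibble::tibble(threshold = thr, fpr = m[, "fpr"], tpr = m[, "tpr"])
}

#' Cross-validated prognostic evaluation of predictor sets
#'
#' Assigns stratified folds (outcome x etiology), then for each predictor set
#' fits a logistic model on the training folds and predicts the held-out
#' fold; reports per-fold prognostic characteristics at the cutoff and the
#' merged-fold ROC/AUC with DeLong CI.
#'
#' @param features Patient tibble with outcome (and optionally etiology).
#' @param predictors Named list of character vectors, each one predictor set
#'   (e.g. `list(bsr = "bsr", combined = c("bsr", "pli_f3_p4"))`).
#' @param outcome_col,etiology_col Column names; etiology may be absent.
#' @param k Number of folds (default 3).
#' @param seed Fold-assignment seed.
#' @param cutoff Probability cutoff for the characteristics.
#' @return List of class `fp_cv`: `folds` (assignment), `characteristics`
#'   (model x fold x metric tibble), `auc` (model-level merged tibble),
#'   `roc` (merged ROC coordinates per model), `predictions`.
#' @export
cv_prognosis <- function(features, predictors, outcome_col = "outcome",
                         etiology_col = "etiology", k = 3, seed = 1,
                         cutoff = 0.5) {
  if (is.null(names(predictors))) {
    names(predictors) <- vapply(predictors, paste, "", collapse = "+")
  }
  y <- as_positive(features[[outcome_col]])
  etio <- if (etiology_col %in% names(features)) features[[etiology_col]] else NULL
  fold <- stratified_kfold(y, etio, k = k, seed = seed)
  preds <- purrr::imap_dfr(predictors, function(vars, nm) {
    prob <- rep(NA_real_, nrow(features))
    for (f in seq_len(k)) {
      tr <- fold != f
      d <- data.frame(features[, vars, drop = FALSE], y = y, check.names = FALSE)
      fit <- suppressWarnings(
        glm(stats::reformulate(sprintf("`%s`", vars), "y"),
            data = d[tr, , drop = FALSE], family = binomial())
      )
      prob[!tr] <- predict(fit, newdata = d[!tr, , drop = FALSE],
                           type = "response")
    }
    tibble::tibble(model = nm, id = seq_len(nrow(features)),
                   fold = fold, y = y, prob = prob)
  })
  characteristics <- preds |>
    dplyr::group_by(.data$model, .data$fold) |>
    dplyr::reframe(prognostic_characteristics(.data$prob, .data$y, cutoff))
  auc <- preds |>
    dplyr::group_by(.data$model) |>
    dplyr::reframe(roc_auc_merged(.data$prob, .data$y))
  roc <- preds |>
    dplyr::group_by(.data$model) |>
    dplyr::reframe(roc_curve(.data$prob, .data$y))
  structure(
    list(folds = fold, characteristics = characteristics, auc = auc,
         roc = roc, predictions = preds, cutoff = cutoff, k = k, seed = seed),
    class = "fp_cv"
  )
}
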