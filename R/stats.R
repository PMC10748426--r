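# Group statistics: outcome dichotomization, normality-gated comparison with
# FDR correction, summary-table statistics, partial/Spearman correlation and
# multiple correspondence analysis.

#' Dichotomize the 60-day Glasgow Outcome Scale
#'
#' GOS 3-5 (moderate disability through full recovery) is favorable;
#' GOS 1-2 (death, vegetative state or severe disability) is unfavorable.
#'
#' @param gos Integer vector with values in 1..5.
#' @return Factor with levels `favorable`, `unfavorable`.
#' @export
dichotomize_outcome <- function(gos) {
  if (any(!gos %in% 1:5)) {
    stop("GOS values must be integers in 1..5; got: ",
         paste(unique(gos[!gos %in% 1:5]), collapse = ", "))
  }
  factor(ifelse(gos >= 3, "favorable", "unfavorable"),
         levels = c("favorable", "unfavorable"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values, returned in input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

# signed Mann-Whitney z with tie correction; positive when group1 ranks higher
mann_whitney_z <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  r <- rank(c(x1, x2))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(z = NA_real_, p = NA_real_))
  z <- (u1 - mu) / sqrt(sigma2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Compare features between outcome groups
#'
#' For each feature: Shapiro-Wilk normality per group and Levene's test of
#' variance homogeneity (classic, mean-centred) at alpha 0.05 decide the test.
#' If both groups are normal with homogeneous variances, a pooled two-sided
#' t-test is used and groups are summarised as mean +/- SD; otherwise a
#' two-sided Mann-Whitney U (normal approximation with tie correction,
#' reporting the standardised z signed so favorable-ranks-higher is positive)
#' with median (IQR) summaries. Benjamini-Hochberg correction is applied
#' across all compared features.
#'
#' @param features Tibble with one row per patient, an outcome column and the
#'   feature columns.
#' @param outcome_col Name of the outcome column (factor with `favorable` as
#'   the first level; see [dichotomize_outcome()]).
#' @param feature_cols Character vector of feature columns; defaults to all
#'   48 qEEG features present in the table.
#' @param alpha Gating level for the normality/homogeneity tests.
#' @return Tibble of class `fp_comparison`: one row per feature with group
#'   summaries, chosen `test` ("t" or "U"), `statistic`, `p`, `p_adj`,
#'   and the gating flags.
#' @export
compare_groups <- function(features, outcome_col = "outcome",
                           feature_cols = NULL, alpha = 0.05) {
  g <- features[[outcome_col]]
  if (is.null(g)) stop("outcome column '", outcome_col, "' not found")
  g <- factor(g, levels = c("favorable", "unfavorable"))
  if (any(table(g) < 2)) stop("need at least 2 subjects per outcome group")
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_names("all"), names(features))
  }
  one <- function(nm) {
    v <- features[[nm]]
    ok <- !is.na(v)
    x1 <- v[ok & g == "favorable"]
    x2 <- v[ok & g == "unfavorable"]
    base <- tibble::tibble(
      feature = nm,
      summary_favorable = NA_character_, summary_unfavorable = NA_character_,
      test = NA_character_, statistic = NA_real_, p = NA_real_,
      normal_favorable = NA, normal_unfavorable = NA, var_homogeneous = NA
    )
    if (length(x1) < 3 || length(x2) < 3 || pop_var(c(x1, x2)) == 0) {
      return(base)
    }
    norm1 <- if (pop_var(x1) > 0) shapiro.test(x1)$p.value > alpha else FALSE
    norm2 <- if (pop_var(x2) > 0) shapiro.test(x2)$p.value > alpha else FALSE
    lev <- car::leveneTest(c(x1, x2) ~ factor(rep(1:2, c(length(x1), length(x2)))),
                           center = mean)
    homog <- lev[["Pr(>F)"]][1] > alpha
    base$normal_favorable <- norm1
    base$normal_unfavorable <- norm2
    base$var_homogeneous <- homog
    if (norm1 && norm2 && homog) {
      tt <- t.test(x1, x2, var.equal = TRUE)
      base$test <- "t"
      base$statistic <- unname(tt$statistic)
      base$p <- tt$p.value
      base$summary_favorable <- sprintf("%.3f ± %.3f", mean(x1), sd(x1))
      base$summary_unfavorable <- sprintf("%.3f ± %.3f", mean(x2), sd(x2))
    } else {
      mw <- mann_whitney_z(x1, x2)
      base$test <- "U"
      base$statistic <- mw$z
      base$p <- mw$p
      base$summary_favorable <- sprintf("%.3f (%.3f)", median(x1), IQR(x1))
      base$summary_unfavorable <- sprintf("%.3f (%.3f)", median(x2), IQR(x2))
    }
    base
  }
  out <- purrr::map_dfr(feature_cols, one)
  out$p_adj <- bh_adjust(out$p)
  class(out) <- c("fp_comparison", class(out))
  out
}

#' @importFrom stats IQR
NULL

#' Pooled two-sample t-test from printed summaries
#'
#' Recomputes the pooled-variance two-sample t statistic from group means,
#' SDs and sizes, as printed in a demographics table.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @return Tibble with `t`, `df`, `p` (two-sided).
#' @export
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pearson chi-squared test on a contingency table
#'
#' Without continuity correction, as used for etiology-by-outcome tables.
#'
#' @param tab Matrix of nonnegative counts, at least 2 x 2.
#' @return Tibble with `chisq`, `df`, `p`.
#' @export
chi2_contingency <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2, ncol(tab) >= 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(chisq = unname(ct$statistic), df = unname(ct$parameter),
                 p = ct$p.value)
}

#' First-order partial correlation
#'
#' Correlation between `x` and `y` controlling for `z`:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. The default
#' rank-based (Spearman) flavour suits ordinal outcomes such as GOS; the raw
#' Pearson flavour is available by flag. p-value from the t approximation on
#' `n - 3` degrees of freedom.
#'
#' @param x,y,z Numeric vectors of equal length (>= 5).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble with `rho` and `p`; `NA` when a control correlation is
#'   degenerate (`|r| = 1`).
#' @export
partial_correlation <- function(x, y, z, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(y) == length(z), length(x) >= 5)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y); z <- rank(z)
  }
  n <- length(x)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  if (anyNA(c(rxy, rxz, ryz)) || abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_))
  }
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  rho <- max(-1, min(1, rho))
  tstat <- rho * sqrt((n - 3) / max(1e-300, 1 - rho^2))
  tibble::tibble(rho = rho, p = 2 * pt(-abs(tstat), n - 3))
}

#' Spearman correlation with an ordinal outcome
#'
#' Tie-corrected Spearman rho and its asymptotic p-value.
#'
#' @param x Feature values.
#' @param gos Ordinal outcome values (e.g. 60-day GOS).
#' @return Tibble with `rho` and `p`; `NA` for constant input.
#' @export
spearman_with_gos <- function(x, gos) {
  stopifnot(length(x) == length(gos), length(x) >= 5)
  if (pop_var(x) == 0 || pop_var(as.numeric(gos)) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, as.numeric(gos), method = "spearman",
                                  exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value)
}

#' Multiple correspondence analysis of discretized features vs outcome
#'
#' Continuous features are discretized by a within-cohort median split
#' (`low`/`high`); the outcome enters as its own categorical variable.
#' Indicator-matrix correspondence analysis (SVD of the standardised
#' residuals) yields 2-D category coordinates; discrimination measures are
#' the correlation ratios (eta-squared) of the object scores across each
#' variable's categories, per dimension, so a variable identical to the
#' outcome scores ~1 on the separating dimension. The sign of dimension 1 is
#' fixed so the `unfavorable` outcome category has a positive coordinate.
#' Variables with a single category are dropped with a warning.
#'
#' @param features Tibble of patients.
#' @param feature_cols Continuous columns to discretize and include.
#' @param outcome_col Outcome column name.
#' @param n_dims Number of dimensions to keep (default 2).
#' @return List of class `fp_mca`: `categories` (variable, category, mass,
#'   dim1..), `discrimination` (variable, dim1..), `eigenvalues`,
#'   `object_scores`.
#' @export
mca_discriminate <- function(features, feature_cols, outcome_col = "outcome",
                             n_dims = 2) {
  disc <- lapply(feature_cols, function(nm) {
    v <- features[[nm]]
    factor(ifelse(v > median(v, na.rm = TRUE), "high", "low"),
           levels = c("low", "high"))
  })
  names(disc) <- feature_cols
  disc[[outcome_col]] <- factor(features[[outcome_col]])
  keep <- vapply(disc, function(f) length(unique(f[!is.na(f)])) >= 2, logical(1))
  if (any(!keep)) {
    warning("dropping single-category variable(s): ",
            paste(names(disc)[!keep], collapse = ", "))
    disc <- disc[keep]
  }
  if (length(disc) < 2) stop("need at least 2 categorical variables for MCA")
  df <- as.data.frame(disc, check.names = FALSE)
  cc <- complete.cases(df)
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  q <- ncol(df)

  ind <- do.call(cbind, lapply(names(df), function(nm) {
    f <- df[[nm]]
    z <- outer(f, levels(f), `==`) * 1
    colnames(z) <- paste(nm, levels(f), sep = "=")
    z
  }))
  p <- ind / sum(ind)
  r <- rowSums(p)
  cm <- colSums(p)
  s <- diag(1 / sqrt(r)) %*% (p - r %o% cm) %*% diag(1 / sqrt(cm))
  sv <- svd(s)
  # degenerate trailing dimensions (zero inertia) are kept as zero coordinates
  d_use <- sv$d[seq_len(n_dims)]
  d_use[d_use <= 1e-10] <- 0
  # object scores: row standard coordinates (weighted variance 1)
  phi <- diag(1 / sqrt(r)) %*% sv$u[, seq_len(n_dims), drop = FALSE]
  phi[, d_use == 0] <- 0
  # category principal coordinates = per-category means of object scores
  gcoord <- diag(1 / sqrt(cm)) %*% sv$v[, seq_len(n_dims), drop = FALSE] %*%
    diag(d_use, n_dims)
  rownames(gcoord) <- colnames(ind)

  # fix sign: outcome's unfavorable category positive on dimension 1
  anchor <- paste0(outcome_col, "=unfavorable")
  if (anchor %in% rownames(gcoord) && gcoord[anchor, 1] < 0) {
    gcoord[, 1] <- -gcoord[, 1]
    phi[, 1] <- -phi[, 1]
  }

  var_of <- sub("=.*$", "", colnames(ind))
  discm <- do.call(rbind, lapply(unique(var_of), function(v) {
    j <- var_of == v
    colSums((cm[j] * q) * gcoord[j, , drop = FALSE]^2)
  }))
  rownames(discm) <- unique(var_of)
  dims <- paste0("dim", seq_len(n_dims))
  categories <- tibble::tibble(
    variable = var_of,
    category = sub("^[^=]*=", "", colnames(ind)),
    mass = cm
  )
  categories[dims] <- as.data.frame(gcoord)
  discrimination <- tibble::tibble(variable = rownames(discm))
  discrimination[dims] <- as.data.frame(discm)
  structure(
    list(categories = categories, discrimination = discrimination,
         eigenvalues = d_use^2,
         object_scores = phi),
    class = "fp_mca"
  )
}
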