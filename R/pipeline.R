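# The full prognostic analysis chain on a patient feature table, plus
# broom-style tidiers and a report writer.

#' Run the full prognostic analysis on a feature table
#'
#' Reproduces the analysis chain on a patient-by-feature table:
#' \enumerate{
#'   \item group comparison of all features with normality-gated test choice
#'     and Benjamini-Hochberg correction ([compare_groups()]);
#'   \item partial-correlation pruning: every BH-significant feature except
#'     RMS is partially correlated (rank-based) with GOS controlling for RMS,
#'     and features no longer significant are dropped as voltage surrogates;
#'   \item Spearman correlation of the surviving features (plus RMS) with GOS;
#'   \item MCA of the surviving features against the outcome;
#'   \item single-feature logistic models ([fit_logistic_single()]);
#'   \item stepwise multiple logistic regression by likelihood-ratio tests
#'     ([fit_logistic_stepwise_lr()]);
#'   \item stratified K-fold cross-validation of the single-feature predictors
#'     and the stepwise model, with per-fold prognostic characteristics and
#'     merged-fold ROC/AUC ([cv_prognosis()]).
#' }
#'
#' @param features Tibble with the 48 feature columns plus `gos` and
#'   (optionally) `etiology`; an `outcome` column is derived from `gos` if
#'   absent.
#' @param alpha Significance level for pruning decisions (default 0.05).
#' @param k Cross-validation folds (default 3).
#' @param seed Fold-assignment seed.
#' @param control_feature Feature used as the partial-correlation control
#'   (default `"rms"`).
#' @return List of class `fp_prognosis` with elements `comparison`,
#'   `partial`, `spearman`, `mca`, `single_models`, `stepwise`, `cv`,
#'   `selected`, `candidates`.
#' @export
run_prognosis <- function(features, alpha = 0.05, k = 3, seed = 1,
                          control_feature = "rms") {
  if (!"outcome" %in% names(features)) {
    features$outcome <- dichotomize_outcome(features$gos)
  }
  comparison <- compare_groups(features)
  sig <- comparison$feature[!is.na(comparison$p_adj) & comparison$p_adj < alpha]

  prune_pool <- setdiff(sig, control_feature)
  partial <- purrr::map_dfr(prune_pool, function(nm) {
    pc <- partial_correlation(features[[nm]], features$gos,
                              features[[control_feature]])
    tibble::tibble(feature = nm, rho = pc$rho, p = pc$p)
  })
  kept <- partial$feature[!is.na(partial$p) & partial$p < alpha]
  selected <- unique(c(kept, intersect(control_feature, sig)))

  spearman <- purrr::map_dfr(selected, function(nm) {
    sp <- spearman_with_gos(features[[nm]], features$gos)
    tibble::tibble(feature = nm, rho = sp$rho, p = sp$p)
  })

  mca <- if (length(selected) >= 2) {
    mca_discriminate(features, selected)
  } else NULL

  single_models <- purrr::map_dfr(selected, function(nm) {
    fit_logistic_single(features, nm)
  })

  stepwise <- if (length(selected)) {
    fit_logistic_stepwise_lr(features, selected)
  } else NULL

  predictors <- c(
    setNames(as.list(selected), selected),
    if (!is.null(stepwise) && !stepwise$intercept_only) {
      list(combined = stepwise$terms)
    }
  )
  cv <- if (length(predictors)) {
    cv_prognosis(features, predictors, k = k, seed = seed)
  } else NULL

  structure(
    list(comparison = comparison, partial = partial, spearman = spearman,
         mca = mca, single_models = single_models, stepwise = stepwise,
         cv = cv, selected = selected, candidates = sig,
         alpha = alpha, k = k, seed = seed),
    class = "fp_prognosis"
  )
}

#' @export
print.fp_prognosis <- function(x, ...) {
  cat("<fp_prognosis>\n")
  cat("  BH-significant features: ", paste(x$candidates, collapse = ", "), "\n")
  cat("  after partial-correlation pruning: ",
      paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$stepwise)) {
    cat("  stepwise model: ",
        if (x$stepwise$intercept_only) "(intercept only)"
        else paste(x$stepwise$terms, collapse = " + "), "\n")
  }
  if (!is.null(x$cv)) {
    cat("  merged-fold AUC:\n")
    print(as.data.frame(x$cv$auc), row.names = FALSE)
  }
  invisible(x)
}

#' @rdname run_prognosis
#' @param x An `fp_prognosis` object (for the tidier methods).
#' @param ... Unused.
#' @method tidy fp_prognosis
#' @export
tidy.fp_prognosis <- function(x, ...) x$comparison

#' @rdname run_prognosis
#' @method glance fp_prognosis
#' @export
glance.fp_prognosis <- function(x, ...) {
  if (is.null(x$cv)) return(tibble::tibble())
  x$cv$auc
}

#' @method tidy fp_stepwise
#' @export
tidy.fp_stepwise <- function(x, ...) x$coefficients

#' @method glance fp_stepwise
#' @export
glance.fp_stepwise <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$terms),
    deviance = x$fit$deviance,
    aic = x$fit$aic,
    intercept_only = x$intercept_only
  )
}

#' @method tidy fp_cv
#' @export
tidy.fp_cv <- function(x, ...) x$characteristics

#' @method glance fp_cv
#' @export
glance.fp_cv <- function(x, ...) x$auc

#' ROC plot for cross-validated predictors
#'
#' @param object An `fp_cv` from [cv_prognosis()].
#' @param ... Unused.
#' @return A ggplot of the merged-fold ROC curves, one per predictor.
#' @method autoplot fp_cv
#' @export
autoplot.fp_cv <- function(object, ...) {
  lab <- object$auc
  lab$label <- sprintf("%s (AUC %.3f)", lab$model, lab$auc)
  roc <- dplyr::left_join(object$roc, lab[, c("model", "label")], by = "model")
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr, colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "Sensitivity",
                  colour = NULL, title = "Merged-fold ROC curves") +
    ggplot2::theme_minimal()
}

#' MCA joint plot of category points
#'
#' @param object An `fp_mca` from [mca_discriminate()].
#' @param ... Unused.
#' @return A ggplot of the 2-D category coordinates.
#' @method autoplot fp_mca
#' @export
autoplot.fp_mca <- function(object, ...) {
  cats <- object$categories
  cats$label <- paste(cats$variable, cats$category, sep = "=")
  ggplot2::ggplot(cats, ggplot2::aes(.data$dim1, .data$dim2,
                                     colour = .data$variable)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8,
                       size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  title = "MCA category points") +
    ggplot2::theme_minimal()
}

#' Group-comparison effect plot
#'
#' @param object An `fp_comparison` from [compare_groups()].
#' @param alpha Highlighting threshold on the adjusted p (default 0.05).
#' @param ... Unused.
#' @return A ggplot of the standardised statistics with significance marks.
#' @method autoplot fp_comparison
#' @export
autoplot.fp_comparison <- function(object, alpha = 0.05, ...) {
  d <- object[!is.na(object$p), ]
  d$significant <- !is.na(d$p_adj) & d$p_adj < alpha
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(.data$statistic, .data$feature,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "Standardised statistic (t or z)", y = NULL,
                  fill = "BH-significant",
                  title = "Feature contrasts between outcome groups") +
    ggplot2::theme_minimal()
}

#' Write the analysis report as delimited text
#'
#' Writes the comparison table, correlation tables, model coefficient tables,
#' per-fold prognostic characteristics, merged AUCs and ROC coordinates as
#' TSV files.
#'
#' @param x An `fp_prognosis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "fp_prognosis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    if (is.null(tbl) || !nrow(tbl)) return()
    utils::write.table(tbl, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(x$comparison, "comparison")
  wr(x$partial, "partial_correlation")
  wr(x$spearman, "spearman_gos")
  wr(x$single_models, "single_models")
  if (!is.null(x$stepwise)) wr(x$stepwise$coefficients, "stepwise_model")
  if (!is.null(x$cv)) {
    wr(x$cv$characteristics, "prognostic_characteristics")
    wr(x$cv$auc, "merged_auc")
    wr(x$cv$roc, "roc_coordinates")
  }
  if (!is.null(x$mca)) {
    wr(x$mca$categories, "mca_categories")
    wr(x$mca$discrimination, "mca_discrimination")
  }
  invisible(dir)
}
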