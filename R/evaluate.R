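#' Tally predictions against experimentally verified sites
#'
#' Compares a predicted site list against disjoint sets of experimentally
#' verified true and false editing sites, keyed by (contig, pos, ref, alt).
#' Counts are relative to the verified universe: `tp` and `fp` are verified
#' sites the method predicted, `fn` and `tn` verified sites it did not.
#' `n_predicted_total` records all predictions, verified or not, and is the
#' denominator of the validation and misclassification rates.
#'
#' @param predicted,verified_true,verified_false Site tibbles with columns
#'   `contig`, `pos`, `ref`, `alt`.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`,
#'   `n_predicted_total`.
#' @export
verify_predictions <- function(predicted, verified_true, verified_false) {
  kp <- site_key(predicted)
  kt <- site_key(verified_true)
  kf <- site_key(verified_false)
  overlap <- intersect(kt, kf)
  if (length(overlap) > 0) {
    stop_("verified true and false sets overlap (", length(overlap), " site(s))")
  }
  tibble::tibble(
    tp = length(intersect(kp, kt)),
    fp = length(intersect(kp, kf)),
    fn = length(setdiff(kt, kp)),
    tn = length(setdiff(kf, kp)),
    n_predicted_total = length(unique(kp))
  )
}

#' Confusion-matrix metric suite
#'
#' Computes the eight-indicator suite from verification counts. Note two
#' operational definitions carried over from the comparison tables this
#' suite mirrors:
#'
#' * `f1_published` is the harmonic mean of sensitivity and specificity — this
#'   (not the textbook precision/recall F1) reproduces the published
#'   comparison rows; the textbook value is exposed as `f1_textbook`.
#' * `validation_rate` = (verified predictions)/(all predictions) and
#'   `misclassification_rate` = (verified-false predictions)/(all
#'   predictions), both relative to `n_predicted_total`.
#'
#' Ratios with a zero denominator are reported as `NA`, never 0.
#'
#' @param counts One-row tibble or list with `tp`, `fp`, `fn`, `tn` and
#'   optionally `n_predicted_total`.
#' @return A one-row tibble of proportions: `accuracy`, `sensitivity`,
#'   `specificity`, `gm`, `ppv`, `f1_published`, `f1_textbook`,
#'   `validation_rate`, `misclassification_rate`, plus the counts.
#' @export
confusion_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  stopifnot(is_count(tp), is_count(fp), is_count(fn), is_count(tn))
  npt <- counts$n_predicted_total %||% NA_integer_
  div <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  gm <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  f1p <- if (is.na(sens) || is.na(spec) || sens + spec == 0) NA_real_ else
    2 * sens * spec / (sens + spec)
  f1t <- if (is.na(sens) || is.na(ppv) || sens + ppv == 0) NA_real_ else
    2 * sens * ppv / (sens + ppv)
  tibble::tibble(
    accuracy = div(tp + tn, tp + fp + fn + tn),
    sensitivity = sens, specificity = spec, gm = gm, ppv = ppv,
    f1_published = f1p, f1_textbook = f1t,
    validation_rate = div(tp + fp, npt),
    misclassification_rate = div(fp, npt),
    tp = tp, fp = fp, fn = fn, tn = tn, n_predicted_total = npt
  )
}

#' ROC AUC (Mann–Whitney statistic)
#'
#' Area under the ROC curve, computed as the Mann–Whitney rank statistic:
#' the probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) labels; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision–recall AUC
#'
#' Area under the precision–recall curve by the step-wise integral over the
#' distinct score thresholds (descending): AUCPR = sum over thresholds of
#' (recall increment) x (precision at that threshold). Tied scores form a
#' single threshold group. With a single threshold (all scores equal) this
#' reduces to the prevalence.
#'
#' @inheritParams roc_auc
#' @return The AUCPR in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0 || sum(!labels) == 0) stop_("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  cum_tp <- cumsum(y)
  cum_n <- seq_along(y)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)  # threshold group ends
  tp <- cum_tp[last_of_group]
  n_pred <- cum_n[last_of_group]
  precision <- tp / n_pred
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' A-to-I ratio of a called site set
#'
#' Fraction of called sites whose mismatch is the A-to-I signature (A>G on
#' the reference strand). Used as a precision proxy for editing calls.
#'
#' @param sites Site tibble with `ref`/`alt` (or an `is_a_to_i` column), or
#'   a logical vector of A-to-I indicators.
#' @param collapse_revcomp_a2i Passed to [classify_mismatch()] when the
#'   indicator column is absent.
#' @return Proportion in `[0, 1]`, or `NA` for an empty set.
#' @export
a_to_i_ratio <- function(sites, collapse_revcomp_a2i = FALSE) {
  flags <- if (is.logical(sites)) {
    sites
  } else if ("is_a_to_i" %in% names(sites)) {
    sites$is_a_to_i
  } else {
    classify_mismatch(sites, collapse_revcomp_a2i)$is_a_to_i
  }
  if (length(flags) == 0) return(NA_real_)
  mean(flags)
}

#' Equal-error-rate FDR over mismatch types
#'
#' Estimates the false-discovery rate among A-to-I calls under the
#' assumption that every non-A-to-I call is false and that errors
#' distribute equally across the 11 non-A-to-I mismatch types: the
#' estimated number of false A-to-I calls is `(n_total - n_a_to_i) / 11`,
#' and the FDR is that estimate divided by `n_a_to_i`.
#'
#' @param n_total Total number of called sites (all 12 mismatch types).
#' @param n_a_to_i Number of A-to-I calls among them.
#' @return Estimated FDR as a proportion, or `NA` when `n_a_to_i` is 0.
#' @export
fdr_equal_error <- function(n_total, n_a_to_i) {
  stopifnot(length(n_total) == length(n_a_to_i))
  if (any(n_a_to_i > n_total, na.rm = TRUE) ||
      any(n_total < 0 | n_a_to_i < 0, na.rm = TRUE)) {
    stop_("need 0 <= n_a_to_i <= n_total")
  }
  ifelse(n_a_to_i == 0, NA_real_, ((n_total - n_a_to_i) / 11) / n_a_to_i)
}

#' Reproducibility overlap between two site sets
#'
#' Overlap ratio of sites called under two conditions, keyed by
#' (contig, pos, ref, alt). Because "overlap ratio" admits more than one
#' denominator, both are offered: `"jaccard"` divides by the union,
#' `"min"` by the smaller set.
#'
#' @param a,b Site tibbles (or character key vectors).
#' @param mode `"jaccard"` (default) or `"min"`.
#' @return Proportion in `[0, 1]`, or `NA` when both sets are empty.
#' @export
reproducibility_overlap <- function(a, b, mode = c("jaccard", "min")) {
  mode <- match.arg(mode)
  ka <- unique(if (is.character(a)) a else site_key(a))
  kb <- unique(if (is.character(b)) b else site_key(b))
  if (length(ka) == 0 && length(kb) == 0) return(NA_real_)
  inter <- length(intersect(ka, kb))
  if (mode == "jaccard") {
    inter / length(union(ka, kb))
  } else {
    if (min(length(ka), length(kb)) == 0) return(NA_real_)
    inter / min(length(ka), length(kb))
  }
}

#' Homologous ratio
#'
#' Number of editing sites with a homologous (orthologous-position) match
#' in another species, over the number of identified sites.
#'
#' @param n_homologous,n_identified Nonnegative counts with
#'   `n_homologous <= n_identified`.
#' @return Proportion, or `NA` when `n_identified` is 0.
#' @export
homologous_ratio <- function(n_homologous, n_identified) {
  stopifnot(length(n_homologous) == length(n_identified))
  if (any(n_homologous > n_identified) || any(n_homologous < 0)) {
    stop_("need 0 <= n_homologous <= n_identified")
  }
  ifelse(n_identified == 0, NA_real_, n_homologous / n_identified)
}

#' Full evaluation report
#'
#' Assembles the complete metric suite for one method/condition: confusion
#' metrics against verified sites, threshold-free AUC/AUCPR when scores and
#' binary labels are supplied, and the A-to-I ratio / equal-error FDR of
#' the predicted set.
#'
#' @param predicted Predicted site tibble (`contig`, `pos`, `ref`, `alt`).
#' @param verified_true,verified_false Verified site tibbles.
#' @param scores,labels Optional score vector and binary truth for
#'   AUC/AUCPR.
#' @return A one-row tibble (confusion metrics, `auc`, `aucpr`,
#'   `a_to_i_ratio`, `fdr_equal_error`, counts).
#' @export
eval_report <- function(predicted, verified_true, verified_false,
                        scores = NULL, labels = NULL) {
  counts <- verify_predictions(predicted, verified_true, verified_false)
  metrics <- confusion_metrics(counts)
  a2i <- a_to_i_ratio(predicted)
  n_a2i <- if (is.na(a2i)) 0L else round(a2i * nrow(predicted))
  fdr <- if (nrow(predicted) == 0 || n_a2i == 0) NA_real_ else
    fdr_equal_error(nrow(predicted), n_a2i)
  auc <- if (!is.null(scores)) roc_auc(scores, labels) else NA_real_
  aucpr <- if (!is.null(scores)) pr_auc(scores, labels) else NA_real_
  dplyr::bind_cols(
    metrics,
    tibble::tibble(auc = auc, aucpr = aucpr,
                   a_to_i_ratio = a2i, fdr_equal_error = fdr)
  )
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble of class `editnet_roc` with columns `fpr`, `tpr`,
#'   `threshold`; plot with [ggplot2::autoplot()].
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]; fpn <- (seq_along(y) - cumsum(y))[last]
  out <- tibble::tibble(
    threshold = c(Inf, s[last]),
    tpr = c(0, tp / sum(y)),
    fpr = c(0, fpn / sum(!y))
  )
  structure(out, class = c("editnet_roc", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.editnet_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}
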