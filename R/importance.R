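#' Per-position importance of the sequence window
#'
#' Scores how much each window position contributes to separating editing
#' sites from the other classes. Two estimators are exposed:
#'
#' * `"permutation"` (default, model-agnostic): the base identities at one
#'   position are shuffled across examples and the drop in editing-vs-rest
#'   ROC AUC of the supplied model is recorded, averaged over `n_repeats`
#'   shuffles. Negative drops (noise) are clamped to zero.
#' * `"gini"`: mean decrease in Gini impurity from a random-forest fit on
#'   the one-hot features (no trained model needed; channel importances are
#'   summed per position).
#'
#' @param object A trained editnet object (required for `"permutation"`;
#'   ignored by `"gini"`, which may be given `NULL`).
#' @param examples Labeled window tibble (columns `seq`, `label`).
#' @param n_repeats Number of shuffles per position (permutation mode).
#' @param seed Integer seed.
#' @param method `"permutation"` or `"gini"`.
#' @param n_trees Forest size for `"gini"`.
#' @return A tibble of class `editnet_importance` with columns `position`
#'   (1-based within the window), `offset` (position minus the centre), and
#'   nonnegative `importance`.
#' @export
position_importance <- function(object, examples, n_repeats = 5L, seed = 1L,
                                method = c("permutation", "gini"),
                                n_trees = 200L) {
  method <- match.arg(method)
  check_examples(examples)
  if (n_repeats < 1) stop_("n_repeats must be >= 1")
  flank <- example_flank(examples)
  W <- 2L * flank + 1L
  imp <- if (method == "permutation") {
    importance_permutation(object, examples, W, n_repeats, seed)
  } else {
    importance_gini(examples, W, seed, n_trees)
  }
  structure(
    tibble::tibble(position = seq_len(W), offset = seq_len(W) - flank - 1L,
                   importance = imp, method = method),
    class = c("editnet_importance", "tbl_df", "tbl", "data.frame")
  )
}

importance_permutation <- function(object, examples, W, n_repeats, seed) {
  if (is.null(object)) stop_("permutation importance needs a trained model")
  y <- as.character(examples$label) == "EDITING"
  if (!any(y) || all(y)) stop_("need both editing and non-editing examples")
  seqs <- examples$seq
  n <- length(seqs)
  base_auc <- roc_auc(predict_scores(object, seqs)$p_editing, y)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  imp <- numeric(W)
  with_seed(seed, {
    for (p in seq_len(W)) {
      drops <- numeric(n_repeats)
      for (r in seq_len(n_repeats)) {
        shuffled <- chars
        shuffled[, p] <- chars[sample.int(n), p]
        perm_seqs <- apply(shuffled, 1L, paste, collapse = "")
        drops[r] <- base_auc -
          roc_auc(predict_scores(object, perm_seqs)$p_editing, y)
      }
      imp[p] <- max(mean(drops), 0)
    }
  })
  imp
}

importance_gini <- function(examples, W, seed, n_trees) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop_("the 'gini' method requires the randomForest package")
  }
  X <- encode_windows(examples$seq)
  y <- factor(as.character(examples$label), levels = CLASS_LEVELS)
  fit <- with_seed(seed, {
    randomForest::randomForest(X, y, ntree = n_trees, importance = FALSE)
  })
  gini <- fit$importance[, "MeanDecreaseGini"]
  # 4 channels per position, row-major by position
  colSums(matrix(gini, nrow = 4L))
}

#' @export
autoplot.editnet_importance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$importance)) +
    ggplot2::geom_col(width = 0.8, fill = "steelblue") +
    ggplot2::labs(
      x = "offset from candidate site (bp)",
      y = if (object$method[1] == "gini") "mean decrease in Gini" else
        "AUC drop under permutation",
      title = "Per-position importance of the sequence window"
    ) +
    ggplot2::theme_minimal()
}
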