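#' Ensemble, module and hierarchy specifications
#'
#' An ensemble combines `n_members` individual nets, each trained on its own
#' class-balanced bootstrap draw, by simple probability averaging (default
#' 20 members). A module combines one ensemble per input scale (default
#' scales 50 and 20, i.e. 101-bp and 41-bp windows) by the same averaging.
#'
#' @param n_members Number of individual nets per ensemble.
#' @param member_spec An [net_spec()] for the members (its `input_flank` is
#'   overridden per scale when used inside a module).
#' @param resample_per_class Bootstrap draw size per class, or `"min-class"`
#'   to use the size of the smallest class.
#' @return `ensemble_spec()` returns an `editnet_ensemble_spec`;
#'   `module_spec()` an `editnet_module_spec`.
#' @export
ensemble_spec <- function(n_members = 20L, member_spec = net_spec(),
                          resample_per_class = "min-class") {
  if (n_members < 1) stop_("n_members must be >= 1")
  if (!identical(resample_per_class, "min-class") &&
      !is_count(resample_per_class)) {
    stop_("resample_per_class must be 'min-class' or a nonnegative integer")
  }
  structure(list(n_members = as.integer(n_members), member_spec = member_spec,
                 resample_per_class = resample_per_class),
            class = "editnet_ensemble_spec")
}

#' @rdname ensemble_spec
#' @param scales Distinct input flanks, one ensemble per scale.
#' @export
module_spec <- function(scales = c(50L, 20L), n_members = 20L,
                        member_spec = net_spec(),
                        resample_per_class = "min-class") {
  if (length(scales) < 1 || anyDuplicated(scales)) {
    stop_("scales must be a non-empty set of distinct flanks")
  }
  structure(list(scales = as.integer(scales),
                 ensemble_spec = ensemble_spec(n_members, member_spec,
                                               resample_per_class)),
            class = "editnet_module_spec")
}

check_examples <- function(examples, need_label = TRUE) {
  if (!is.data.frame(examples) || !"seq" %in% names(examples)) {
    stop_("examples must be a data frame with a 'seq' column")
  }
  if (need_label) {
    if (!"label" %in% names(examples)) stop_("examples must carry a 'label' column")
    bad <- setdiff(unique(as.character(examples$label)), CLASS_LEVELS)
    if (length(bad) > 0) {
      stop_("unknown class label(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(examples)
}

example_flank <- function(examples) {
  L <- unique(nchar(examples$seq))
  if (length(L) != 1) stop_("examples must share one window width")
  if (L %% 2 != 1) stop_("window width must be odd")
  (L - 1L) %/% 2L
}

#' Class-balanced bootstrap resampling
#'
#' Bagging-style bootstrapped resampling used to counter class imbalance:
#' the same number of examples is drawn, with replacement and independently,
#' from each of the three classes.
#'
#' @param examples Labeled window tibble (columns `seq`, `label`).
#' @param n_per_class Draw size per class; `"min-class"` uses the smallest
#'   class size.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return A tibble with exactly `n_per_class` rows per class.
#' @export
balanced_bootstrap <- function(examples, n_per_class = "min-class", seed = 1L) {
  check_examples(examples)
  lab <- as.character(examples$label)
  counts <- table(factor(lab, levels = CLASS_LEVELS))
  missing <- CLASS_LEVELS[counts == 0]
  if (length(missing) > 0) {
    stop_("class(es) absent from training examples: ",
          paste(missing, collapse = ", "))
  }
  if (identical(n_per_class, "min-class")) n_per_class <- min(counts)
  if (!is_count(n_per_class)) stop_("n_per_class must be a nonnegative integer")
  idx <- with_seed(seed, {
    unlist(lapply(CLASS_LEVELS, function(cl) {
      pool <- which(lab == cl)
      pool[sample.int(length(pool), n_per_class, replace = TRUE)]
    }), use.names = FALSE)
  })
  examples[idx, , drop = FALSE]
}

#' Train one individual net
#'
#' Trains a single feed-forward softmax net on labeled windows whose width
#' must equal the spec's input width `2 * input_flank + 1`.
#'
#' @param examples Labeled window tibble (columns `seq`, `label`).
#' @param spec An [net_spec()].
#' @param config A [train_config()].
#' @param seed Seed controlling minibatch shuffling (weight initialisation
#'   is governed by `spec$seed`).
#' @return An object of class `editnet_net`.
#' @export
train_individual_net <- function(examples, spec = net_spec(),
                                 config = train_config(), seed = 1L) {
  check_examples(examples)
  if (nrow(examples) == 0) stop_("empty training set")
  flank <- example_flank(examples)
  if (flank != spec$input_flank) {
    stop_("window flank ", flank, " does not match spec input_flank ",
          spec$input_flank)
  }
  X <- encode_windows(examples$seq)
  y <- match(as.character(examples$label), CLASS_LEVELS)
  layers <- mlp_train(X, y, spec, config, seed)
  structure(list(spec = spec, config = config, layers = layers,
                 d_in = ncol(X), seed = as.integer(seed),
                 classes = CLASS_LEVELS),
            class = "editnet_net")
}

#' Train a bagged ensemble of individual nets
#'
#' Trains `spec$n_members` nets, each on an independent class-balanced
#' bootstrap draw (the member index is folded into the seed derivation), and
#' predicts by simple averaging of member probabilities.
#'
#' @inheritParams train_individual_net
#' @param spec An [ensemble_spec()].
#' @return An object of class `editnet_ensemble`.
#' @export
train_ensemble <- function(examples, spec = ensemble_spec(),
                           config = train_config(), seed = 1L) {
  check_examples(examples)
  flank <- example_flank(examples)
  sc <- spec$member_spec$input_flank
  if (flank < sc) {
    stop_("windows (flank ", flank, ") narrower than the member scale ", sc)
  }
  if (flank > sc) {
    examples <- dplyr::mutate(examples,
                              seq = crop_windows(.data$seq, flank, sc))
  }
  members <- lapply(seq_len(spec$n_members), function(i) {
    boot_seed <- derive_seed(seed, 1L, i)
    boot <- balanced_bootstrap(examples, spec$resample_per_class, boot_seed)
    mspec <- spec$member_spec
    mspec$seed <- derive_seed(seed, 2L, i)
    train_individual_net(boot, mspec, config, seed = derive_seed(seed, 3L, i))
  })
  structure(list(spec = spec, members = members,
                 input_flank = spec$member_spec$input_flank,
                 seed = as.integer(seed)),
            class = "editnet_ensemble")
}

#' Train a two-scale module
#'
#' Trains one ensemble per input scale on centre-cropped views of the same
#' labeled windows (the candidate base stays at the midpoint of every
#' scale), and predicts by averaging the per-scale ensemble probabilities.
#' The windows supplied must be at least as wide as the widest scale.
#'
#' @inheritParams train_individual_net
#' @param spec A [module_spec()].
#' @return An object of class `editnet_module`.
#' @export
train_module <- function(examples, spec = module_spec(),
                         config = train_config(), seed = 1L) {
  check_examples(examples)
  flank <- example_flank(examples)
  if (flank < max(spec$scales)) {
    stop_("windows (flank ", flank, ") narrower than the widest scale ",
          max(spec$scales))
  }
  ensembles <- lapply(seq_along(spec$scales), function(si) {
    sc <- spec$scales[si]
    espec <- spec$ensemble_spec
    espec$member_spec$input_flank <- sc
    cropped <- dplyr::mutate(examples, seq = crop_windows(.data$seq, flank, sc))
    train_ensemble(cropped, espec, config, seed = derive_seed(seed, 10L, si))
  })
  structure(list(spec = spec, ensembles = ensembles, scales = spec$scales,
                 seed = as.integer(seed)),
            class = "editnet_module")
}

#' Train a component from several gold-standard sets
#'
#' Trains one module per gold-standard set (the training design uses 11
#' cell-type sets per component) and predicts by averaging module
#' probabilities.
#'
#' @param gold_sets A non-empty list of labeled window tibbles.
#' @inheritParams train_module
#' @return An object of class `editnet_component`.
#' @export
train_component <- function(gold_sets, spec = module_spec(),
                            config = train_config(), seed = 1L) {
  if (!is.list(gold_sets) || length(gold_sets) == 0 || is.data.frame(gold_sets)) {
    stop_("gold_sets must be a non-empty list of labeled window tables")
  }
  modules <- lapply(seq_along(gold_sets), function(gi) {
    train_module(gold_sets[[gi]], spec, config, seed = derive_seed(seed, 20L, gi))
  })
  structure(list(spec = spec, modules = modules, scales = spec$scales,
                 seed = as.integer(seed)),
            class = "editnet_component")
}

#' Assemble the final two-component classifier
#'
#' Combines a component trained on separate-samples gold sets and one
#' trained on pooled-samples gold sets into the final classifier, whose
#' prediction is the simple average of the two component predictions.
#'
#' @param separate,pooled Trained `editnet_component` objects with
#'   compatible scales.
#' @return An object of class `editnet_model`.
#' @export
assemble_model <- function(separate, pooled) {
  stopifnot(inherits(separate, "editnet_component"),
            inherits(pooled, "editnet_component"))
  if (!setequal(separate$scales, pooled$scales)) {
    stop_("components have incompatible scales: ",
          paste(separate$scales, collapse = "/"), " vs ",
          paste(pooled$scales, collapse = "/"))
  }
  structure(list(separate = separate, pooled = pooled,
                 scales = separate$scales),
            class = "editnet_model")
}

#' Average class-probability triples
#'
#' Componentwise arithmetic mean of probability triples — the simple
#' averaging rule used at every level of the hierarchy.
#'
#' @param triples A non-empty list of score tibbles (columns `p_editing`,
#'   `p_snp`, `p_other`) of equal row count, or a list of numeric
#'   length-3 vectors.
#' @return A single averaged score tibble (or numeric triple).
#' @export
average_probabilities <- function(triples) {
  if (length(triples) == 0) stop_("cannot average an empty list")
  if (is.numeric(triples[[1]])) {
    return(Reduce(`+`, triples) / length(triples))
  }
  mats <- lapply(triples, function(t) as.matrix(t[, c("p_editing", "p_snp", "p_other")]))
  avg <- Reduce(`+`, mats) / length(mats)
  tibble::as_tibble(as.data.frame(avg))
}

score_tibble <- function(probs) {
  colnames(probs) <- c("p_editing", "p_snp", "p_other")
  tibble::as_tibble(as.data.frame(probs))
}

# Internal matrix-level scorers (rows = windows, cols = 3 classes).
probs_net <- function(net, seqs) {
  flank <- (unique(nchar(seqs)) - 1L) %/% 2L
  if (flank < net$spec$input_flank) {
    stop_("windows narrower than the net's input scale ", net$spec$input_flank)
  }
  X <- encode_windows(crop_windows(seqs, flank, net$spec$input_flank))
  mlp_forward(net$layers, X)
}

probs_ensemble <- function(ens, seqs) {
  Reduce(`+`, lapply(ens$members, probs_net, seqs = seqs)) / length(ens$members)
}

probs_module <- function(mod, seqs) {
  Reduce(`+`, lapply(mod$ensembles, probs_ensemble, seqs = seqs)) /
    length(mod$ensembles)
}

probs_component <- function(comp, seqs) {
  Reduce(`+`, lapply(comp$modules, probs_module, seqs = seqs)) /
    length(comp$modules)
}

probs_model <- function(model, seqs) {
  (probs_component(model$separate, seqs) + probs_component(model$pooled, seqs)) / 2
}

predict_scores <- function(object, seqs) {
  if (length(seqs) == 0) {
    return(tibble::tibble(p_editing = numeric(), p_snp = numeric(),
                          p_other = numeric()))
  }
  probs <- switch(class(object)[1],
    editnet_net = probs_net(object, seqs),
    editnet_ensemble = probs_ensemble(object, seqs),
    editnet_module = probs_module(object, seqs),
    editnet_component = probs_component(object, seqs),
    editnet_model = probs_model(object, seqs),
    stop_("not a trained editnet object")
  )
  score_tibble(probs)
}

#' Predict class probabilities
#'
#' All trained objects — individual net, ensemble, module, component, and
#' the assembled two-component model — predict the same way: one probability
#' triple per window, rows summing to 1. Windows must be at least as wide
#' as the object's widest input scale; wider windows are centre-cropped.
#'
#' @param object A trained editnet object.
#' @param newdata A window tibble with a `seq` column, or a character vector
#'   of window sequences.
#' @param ... Unused.
#' @return A tibble with columns `p_editing`, `p_snp`, `p_other`.
#' @export
predict.editnet_net <- function(object, newdata, ...) {
  predict_scores(object, as_window_seqs(newdata))
}

#' @rdname predict.editnet_net
#' @export
predict.editnet_ensemble <- function(object, newdata, ...) {
  predict_scores(object, as_window_seqs(newdata))
}

#' @rdname predict.editnet_net
#' @export
predict.editnet_module <- function(object, newdata, ...) {
  predict_scores(object, as_window_seqs(newdata))
}

#' @rdname predict.editnet_net
#' @export
predict.editnet_component <- function(object, newdata, ...) {
  predict_scores(object, as_window_seqs(newdata))
}

#' @rdname predict.editnet_net
#' @export
predict.editnet_model <- function(object, newdata, ...) {
  predict_scores(object, as_window_seqs(newdata))
}

as_window_seqs <- function(newdata) {
  if (is.character(newdata)) return(newdata)
  if (is.data.frame(newdata) && "seq" %in% names(newdata)) return(newdata$seq)
  stop_("newdata must be a window tibble with a 'seq' column or a character vector")
}

#' Score candidates with a trained model
#'
#' @param object Any trained editnet object.
#' @param windows Window tibble from [extract_windows()] (must be at least
#'   as wide as the object's widest scale).
#' @return `windows` with score columns `p_editing`, `p_snp`, `p_other`
#'   appended; input order preserved.
#' @export
score_candidates <- function(object, windows) {
  scores <- predict_scores(object, as_window_seqs(windows))
  if (is.data.frame(windows)) dplyr::bind_cols(windows, scores) else scores
}

#' Call editing sites at a probability cutoff
#'
#' Retains candidates whose editing probability is strictly greater than
#' the cutoff, tagging each with its score and mismatch type. The strict
#' inequality means a score exactly equal to the cutoff is excluded.
#'
#' @param scored Tibble with a `p_editing` column plus candidate columns
#'   (as produced by [score_candidates()]).
#' @param cutoff Probability threshold in `[0, 1]`.
#' @param collapse_revcomp_a2i Passed to [classify_mismatch()].
#' @return The called-site tibble (subset of `scored`, with `mismatch` and
#'   `is_a_to_i` columns).
#' @export
call_editing_sites <- function(scored, cutoff = 0.5,
                               collapse_revcomp_a2i = FALSE) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1) {
    stop_("cutoff must be a probability in [0, 1]")
  }
  if (!"p_editing" %in% names(scored)) stop_("scored must carry a p_editing column")
  called <- dplyr::filter(scored, .data$p_editing > cutoff)
  if (all(c("ref", "alt") %in% names(called))) {
    called <- classify_mismatch(called, collapse_revcomp_a2i)
  }
  called
}

#' Stratified k-fold split
#'
#' Partitions examples into `k` folds, stratified by class label so that
#' per-fold class proportions stay within one example of the global ones.
#' Bootstrap balancing is applied (by the training functions) inside
#' training folds only, never to test folds.
#'
#' @param examples Labeled window tibble.
#' @param k Number of folds (>= 2, and at most the dataset size).
#' @param seed Integer seed.
#' @return A list of `k` elements, each `list(train = <idx>, test = <idx>)`;
#'   the test folds partition `seq_len(nrow(examples))`.
#' @export
kfold_split <- function(examples, k = 5L, seed = 1L) {
  check_examples(examples)
  n <- nrow(examples)
  if (k < 2) stop_("k must be >= 2")
  if (n < k) stop_("dataset smaller than k")
  lab <- as.character(examples$label)
  small <- names(which(table(lab) < k))
  if (length(small) > 0) {
    warning("class(es) smaller than k; stratification is degenerate for: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  fold <- integer(n)
  with_seed(seed, {
    for (cl in unique(lab)) {
      pool <- which(lab == cl)
      fold[pool] <- sample(rep_len(seq_len(k), length(pool)))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold != f), test = which(fold == f))
  })
}
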