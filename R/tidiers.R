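#' Tidy the structure of a trained classifier
#'
#' `tidy()` enumerates every individual net in the hierarchy — one row per
#' leaf, with its component, module, scale and member coordinates and
#' parameter count. `glance()` gives a one-row structural summary.
#'
#' @param x A trained editnet object (any level).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.editnet_model <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$separate), component = "separate", .before = 1),
    dplyr::mutate(tidy(x$pooled), component = "pooled", .before = 1)
  )
}

#' @rdname tidy.editnet_model
#' @export
tidy.editnet_component <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x$modules, function(mod, mi) {
    dplyr::mutate(tidy(mod), module = mi, .before = 1)
  }))
}

#' @rdname tidy.editnet_model
#' @export
tidy.editnet_module <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x$ensembles, function(ens, si) {
    dplyr::mutate(tidy(ens), scale = x$scales[si], .before = 1)
  }))
}

#' @rdname tidy.editnet_model
#' @export
tidy.editnet_ensemble <- function(x, ...) {
  purrr::list_rbind(purrr::imap(x$members, function(net, mi) {
    dplyr::mutate(tidy(net), member = mi, .before = 1)
  }))
}

#' @rdname tidy.editnet_model
#' @export
tidy.editnet_net <- function(x, ...) {
  tibble::tibble(
    input_flank = x$spec$input_flank,
    window_bp = 2L * x$spec$input_flank + 1L,
    hidden = paste(x$spec$hidden_sizes, collapse = "-"),
    n_params = sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0)),
    seed = x$seed
  )
}

#' @rdname tidy.editnet_model
#' @export
glance.editnet_model <- function(x, ...) {
  leaves <- tidy(x)
  tibble::tibble(
    n_components = 2L,
    n_modules = length(x$separate$modules) + length(x$pooled$modules),
    n_nets = nrow(leaves),
    scales = paste(sort(unique(x$scales), decreasing = TRUE), collapse = "/"),
    n_params = sum(leaves$n_params)
  )
}

#' @rdname tidy.editnet_model
#' @export
glance.editnet_component <- function(x, ...) {
  leaves <- tidy(x)
  tibble::tibble(
    n_modules = length(x$modules), n_nets = nrow(leaves),
    scales = paste(sort(unique(x$scales), decreasing = TRUE), collapse = "/"),
    n_params = sum(leaves$n_params)
  )
}

#' @rdname tidy.editnet_model
#' @export
glance.editnet_module <- function(x, ...) {
  leaves <- tidy(x)
  tibble::tibble(
    n_ensembles = length(x$ensembles), n_nets = nrow(leaves),
    scales = paste(sort(unique(x$scales), decreasing = TRUE), collapse = "/"),
    n_params = sum(leaves$n_params)
  )
}

#' @rdname tidy.editnet_model
#' @export
glance.editnet_ensemble <- function(x, ...) {
  leaves <- tidy(x)
  tibble::tibble(
    n_members = length(x$members),
    input_flank = x$input_flank,
    n_params = sum(leaves$n_params)
  )
}

#' Score-distribution plot
#'
#' Density of the editing probability, optionally split by true class.
#'
#' @param scored Tibble with a `p_editing` column.
#' @param label Optional column name holding class labels.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(scored, label = NULL) {
  p <- if (!is.null(label) && label %in% names(scored)) {
    ggplot2::ggplot(scored, ggplot2::aes(x = .data$p_editing,
                                         fill = .data[[label]])) +
      ggplot2::geom_density(alpha = 0.5)
  } else {
    ggplot2::ggplot(scored, ggplot2::aes(x = .data$p_editing)) +
      ggplot2::geom_density(fill = "steelblue", alpha = 0.7)
  }
  p + ggplot2::labs(x = "P(editing)", y = "density") + ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
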