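#' Specification of an individual network
#'
#' An individual net is a feed-forward network that maps the flattened
#' one-hot window (dimension `(2 * input_flank + 1) * 4`) through fully
#' connected hidden layers to a 3-unit softmax over EDITING / SNP / OTHER.
#' The defaults follow the optimised architecture: two hidden layers of
#' 1000 and 100 units.
#'
#' @param input_flank Flank of the input window (50 for the 101-bp scale,
#'   20 for the 41-bp scale).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param activation Hidden activation; only `"relu"` is implemented.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `editnet_net_spec`.
#' @export
net_spec <- function(input_flank = 50, hidden_sizes = c(1000, 100),
                     activation = "relu", seed = 1L) {
  if (!is_count(input_flank)) stop_("input_flank must be a nonnegative integer")
  if (length(hidden_sizes) < 1 || any(hidden_sizes < 1)) {
    stop_("hidden_sizes must be positive integers")
  }
  if (!identical(activation, "relu")) stop_("only 'relu' activation is implemented")
  structure(
    list(input_flank = as.integer(input_flank),
         hidden_sizes = as.integer(hidden_sizes),
         n_outputs = 3L, activation = activation, seed = as.integer(seed)),
    class = "editnet_net_spec"
  )
}

#' Training configuration
#'
#' Optimisation hyperparameters shared by every net in the hierarchy, plus
#' the cross-validation fold count and the calling cutoff. Optimiser,
#' epochs and learning rate are deliberate configuration (not architecture):
#' minibatch Adam with a fixed epoch budget and no early stopping.
#'
#' @param k_folds Folds for stratified cross-validation (>= 2).
#' @param epochs Full passes over the (bootstrap-balanced) training set.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param cutoff Probability threshold used by [call_editing_sites()].
#' @return An object of class `editnet_train_config`.
#' @export
train_config <- function(k_folds = 5L, epochs = 30L, batch_size = 128L,
                         learning_rate = 1e-3, optimizer = c("adam", "sgd"),
                         cutoff = 0.5) {
  optimizer <- match.arg(optimizer)
  if (k_folds < 2) stop_("k_folds must be >= 2")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0) {
    stop_("epochs, batch_size must be >= 1 and learning_rate > 0")
  }
  structure(
    list(k_folds = as.integer(k_folds), epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = optimizer,
         cutoff = cutoff),
    class = "editnet_train_config"
  )
}

# He-normal initialisation of all layer weights; biases start at zero.
mlp_init <- function(d_in, hidden, d_out, seed) {
  dims <- c(d_in, hidden, d_out)
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      list(W = matrix(stats::rnorm(fan_in * dims[l + 1L], sd = sqrt(2 / fan_in)),
                      nrow = fan_in),
           b = rep(0, dims[l + 1L]))
    })
  })
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; returns class probabilities, optionally with layer
# activations cached for backprop.
mlp_forward <- function(layers, X, cache = FALSE) {
  acts <- vector("list", length(layers))
  a <- X
  n_l <- length(layers)
  for (l in seq_len(n_l)) {
    z <- a %*% layers[[l]]$W
    z <- sweep(z, 2L, layers[[l]]$b, `+`)
    if (l < n_l) {
      a <- pmax(z, 0)  # ReLU
      if (cache) acts[[l]] <- a
    } else {
      a <- softmax_rows(z)
    }
  }
  if (cache) list(probs = a, acts = acts) else a
}

# One Adam/SGD training run on (X, y); y is an integer class index 1..3.
# Deterministic given `seed` (controls shuffling; init comes from spec seed).
mlp_train <- function(X, y, spec, config, seed) {
  n <- nrow(X)
  if (n == 0) stop_("empty training set")
  d_in <- ncol(X)
  layers <- mlp_init(d_in, spec$hidden_sizes, spec$n_outputs, spec$seed)
  n_l <- length(layers)
  lr <- config$learning_rate
  adam <- config$optimizer == "adam"
  if (adam) {
    mom <- lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                           mb = l$b * 0, vb = l$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  }
  Y <- matrix(0, n, spec$n_outputs)
  Y[cbind(seq_len(n), y)] <- 1
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- X[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        m <- length(idx)
        fw <- mlp_forward(layers, xb, cache = TRUE)
        delta <- (fw$probs - yb) / m  # softmax + cross-entropy gradient
        for (l in rev(seq_len(n_l))) {
          a_prev <- if (l == 1L) xb else fw$acts[[l - 1L]]
          gW <- crossprod(a_prev, delta)
          gb <- colSums(delta)
          if (l > 1L) {
            delta <- (delta %*% t(layers[[l]]$W)) * (fw$acts[[l - 1L]] > 0)
          }
          if (adam) {
            if (l == n_l) t <- t + 1
            mo <- mom[[l]]
            mo$mW <- b1 * mo$mW + (1 - b1) * gW
            mo$vW <- b2 * mo$vW + (1 - b2) * gW^2
            mo$mb <- b1 * mo$mb + (1 - b1) * gb
            mo$vb <- b2 * mo$vb + (1 - b2) * gb^2
            mom[[l]] <- mo
            c1 <- 1 - b1^t; c2 <- 1 - b2^t
            layers[[l]]$W <- layers[[l]]$W -
              lr * (mo$mW / c1) / (sqrt(mo$vW / c2) + eps)
            layers[[l]]$b <- layers[[l]]$b -
              lr * (mo$mb / c1) / (sqrt(mo$vb / c2) + eps)
          } else {
            layers[[l]]$W <- layers[[l]]$W - lr * gW
            layers[[l]]$b <- layers[[l]]$b - lr * gb
          }
        }
      }
    }
  })
  layers
}
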