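# Internal helpers shared across modules.

BASES <- c("A", "T", "C", "G")

# Fixed class order; argmax ties (never expected in float practice) resolve
# in this order: EDITING < SNP < OTHER.
CLASS_LEVELS <- c("EDITING", "SNP", "OTHER")

#' Class labels used by the three-way classifier
#'
#' @return Character vector `c("EDITING", "SNP", "OTHER")`, in the fixed
#'   order used for probability columns and argmax tie-breaking.
#' @export
class_levels <- function() CLASS_LEVELS

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Deterministic seed derivation: every source of randomness in the hierarchy
# flows from one master seed plus a path of small integers
# (level, module index, member index, ...). Kept strictly below 2^31.
derive_seed <- function(master, ...) {
  path <- c(...)
  h <- as.double(master) %% 2147483647
  for (p in path) {
    h <- (h * 69069 + as.double(p) * 48271 + 1) %% 2147483647
  }
  as.integer(h)
}

# FNV-1a 32-bit hash of an R object's canonical serialization; used to
# fingerprint model specs for load-time verification.
spec_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
}
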