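## Internal helpers shared across modules.

MODULUS31 <- 2147483647  # 2^31 - 1, Mersenne prime

## Exact (a * b) mod (2^31 - 1) in double arithmetic.
## Splits b into 16-bit halves so every intermediate product stays below
## 2^47 < 2^53 and is representable exactly.
mulmod31 <- function(a, b) {
  a <- a %% MODULUS31
  b <- b %% MODULUS31
  hi <- floor(b / 65536)
  lo <- b - hi * 65536
  (((a * hi) %% MODULUS31) * 65536 + a * lo) %% MODULUS31
}

#' Derive a reproducible child seed from a master seed and stream labels
#'
#' Splitmix-style multiplicative mixing over the field GF(2^31 - 1): each
#' component is folded in with a large odd multiplier and an avalanche
#' round, so streams indexed by `(seed, ...)` tuples are decorrelated and
#' independent of generation order.
#'
#' @param seed master integer seed.
#' @param ... further integer stream labels (e.g. group, subject index).
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' mix_seed(42, 1, 17)
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  stopifnot(all(is.finite(parts)))
  h <- 1442695040888963 %% MODULUS31
  for (p in parts) {
    h <- mulmod31(h + (p %% MODULUS31) + 1, 2654435761)
    h <- mulmod31(h, h + 12345)  # avalanche round
  }
  as.integer(h %% (MODULUS31 - 2) + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != round(x))
    stop_invalid("'%s' must be a single integer >= %d (got %s)",
                 name, min, paste(format(x), collapse = ","))
  as.integer(x)
}

check_square_finite <- function(m, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_invalid("'%s' must be a square matrix", name)
  if (!all(is.finite(m)))
    stop_invalid("'%s' contains non-finite entries", name)
  m
}

is_symmetric_tol <- function(m, tol = 1e-12) {
  max(abs(m - t(m))) < tol
}

default_region_labels <- function(n) {
  if (n == 90L) aal90_labels()$name else sprintf("Region_%03d", seq_len(n))
}
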