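# Internal helpers shared across the package.

#' @useDynLib scbridge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median mad rnorm runif sd var cor quantile p.adjust wilcox.test
#'   t.test plogis setNames
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483646L))
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483629)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

sigmoid <- function(x) plogis(x)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-broadcast addition of a vector to a matrix.
add_bias <- function(X, b) sweep(X, 2L, b, "+")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Sinusoidal time encoding
#'
#' Transformer-style positional features for a scalar time: `dim/2` sine and
#' `dim/2` cosine components at geometrically spaced frequencies
#' `1 / 10000^(2i/dim)`. Used to condition the encoder, decoder, drift and
#' kill-rate networks on (possibly fractional) time.
#'
#' @param t scalar time (any real; integers and doubles give identical output).
#' @param dim even integer, total number of features.
#' @return numeric vector of length `dim`: sines first, then cosines.
#' @examples
#' sinusoidal_encode(0, 8)   # sines all 0, cosines all 1
#' @export
sinusoidal_encode <- function(t, dim) {
  if (length(dim) != 1L || dim < 2L || dim %% 2L != 0L)
    stopf("`dim` must be an even integer >= 2, got %s", paste(dim, collapse = ","))
  t <- as.double(t)
  half <- dim / 2
  freq <- 1 / (10000^((2 * (seq_len(half) - 1)) / dim))
  c(sin(t * freq), cos(t * freq))
}
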