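#' @useDynLib fmricontrast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor dgamma convolve t.test p.adjust
#'   quantile poly setNames binomial
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministically mix a base seed with small integer tags, staying within
# the 32-bit range R's set.seed() accepts.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) {
    h <- (h * 69069 + as.double(t) * 40503 + 12345) %% 2147483647
  }
  as.integer(h)
}

# round() halves away from zero for nonnegative x; used for seconds -> frames.
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

stop_fc <- function(...) stop(..., call. = FALSE)
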