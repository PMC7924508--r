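#' @importFrom rlang abort warn .data
#' @importFrom stats plogis qnorm rbinom rnorm runif sd uniroot prcomp cmdscale
#'   hclust dist cutree quantile var
#' @importFrom utils head
NULL

# Deterministic derivation of stage seeds from one global seed.
# Mixes the integer ids with an LCG so that (seed, fold, config, ...) tuples
# map to well-spread 31-bit seeds; pure function of its arguments.
derive_seed <- function(seed, ...) {
  ids <- as.numeric(c(seed, ...))
  stopifnot(all(is.finite(ids)))
  x <- 104729
  for (i in ids) {
    x <- (x * 69069 + (i %% 2147483647) * 12345 + 1) %% 2147483647
  }
  as.integer(x)
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  all(x %in% c(0, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
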