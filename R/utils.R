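#' @importFrom rlang abort warn %||% .data
#' @importFrom stats rnorm rnbinom runif rbinom cor sd qnorm pnorm phyper
#'   hclust cutree as.dist lm.fit model.matrix wilcox.test fisher.test
#'   cor.test var quantile median setNames
#' @importFrom utils combn head
NULL

# Single place for seed handling: every generator takes an integer seed and
# restores the caller's RNG state on exit, so generators are pure functions
# of their arguments.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation for stage-scoped substreams. Keeps the
# result in [0, 2^31 - 2] so it is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  acc <- 0
  for (p in parts) acc <- (acc * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(acc)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s", name,
      if (open) "(" else "[", lo, hi, if (open) ")" else "]"
    ))
  }
  invisible(x)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

is_autosome_or_x <- function(chrom) {
  grepl("^(chr)?([0-9]+|X)$", as.character(chrom))
}
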