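#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats median rnorm runif sd
#' @importFrom utils head read.csv write.csv
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All seeded entry points funnel through here so the
# determinism contract (same seed => bit-identical output) holds regardless of
# surrounding RNG use.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Stable per-stage seed derivation: a global seed fans out to independent
# stage seeds so stages can be rerun in isolation yet reproducibly.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435.0 + h) %% 2147483647)
}

assertImage2D <- function(x, minDim = 1L, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (Image2D)", arg), call. = FALSE)
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  if (nrow(x) < minDim || ncol(x) < minDim)
    stop(sprintf("'%s' must be at least %dx%d", arg, minDim, minDim), call. = FALSE)
  invisible(x)
}

assertBinaryMask <- function(m, arg = "mask") {
  if (!is.matrix(m))
    stop(sprintf("'%s' must be a matrix (MaskImage)", arg), call. = FALSE)
  if (!all(m %in% c(0, 1)))
    stop(sprintf("'%s' must be binary (0/1)", arg), call. = FALSE)
  invisible(m)
}
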