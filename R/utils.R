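#' @importFrom stats quantile rnorm runif rpois rlnorm lm coef
#' @importFrom utils read.csv write.csv
NULL

# Run `expr` under a locally seeded RNG, restoring global RNG state afterwards.
# `seed = NULL` leaves the current RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Area-equivalent diameter (um) of a pixel mask of `n_px` pixels.
equiv_diameter_um <- function(n_px, pixel_size_um) {
  2 * sqrt(n_px * pixel_size_um^2 / pi)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}
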