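#' Percentage of a count
#'
#' \code{pct(15, 55)} is 27; \code{pct(94, 119, digits = 2)} is 78.99.
#' Composition tables use whole percentages, proportions of assigned
#' samples two decimals; raw counts are always reported alongside so the
#' rounding is non-destructive.
#'
#' @param n count
#' @param total denominator, > 0
#' @param digits decimal places (default 0)
#' @return numeric percentage on the 0-100 scale.
#' @export
pct <- function(n, total, digits = 0) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
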