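# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Printed parameter tables round half away from zero (so 2.175 -> 2.18),
#' unlike [round()]'s round-half-to-even. Used only when formatting values
#' for comparison with printed tables; internal arithmetic is never rounded.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(2.175, 2) # 2.18
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  # fuzz guards against binary representation error (2.175*100 = 217.49999...)
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(sprintf("`%s` must be a single positive finite number", name))
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_domain(sprintf("`%s` must be a single non-negative finite number", name))
  invisible(x)
}
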