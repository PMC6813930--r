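#' Hill response functions
#'
#' The three saturating response functions used throughout the acute
#' inflammatory response (AIR) model. `hill_up_sat()` is an upregulating
#' response that saturates at `n^h` as `x` grows (`x^h / (1 + (x/n)^h)`),
#' `hill_up()` is the standard Hill sigmoid bounded by 1
#' (`x^h / (x^h + n^h)`), and `hill_down()` is the complementary
#' downregulating response (`1 / (1 + (x/n)^h)`). For any valid input,
#' `hill_up(x, n, h) + hill_down(x, n, h) == 1`.
#'
#' @param x Non-negative stimulus (arbitrary concentration units).
#' @param n Positive half-saturation constant, same units as `x`.
#' @param h Positive Hill exponent (steepness).
#' @return Numeric vector of responses, recycled over `x`.
#' @examples
#' hill_up(1, 1, 2)        # 0.5 at the midpoint
#' hill_down(3, 1, 1)      # 0.25
#' hill_up_sat(10, 1, 1)   # 10/11
#' @export
hill_up_sat <- function(x, n, h) {
  check_hill_args(x, n, h)
  x^h / (1 + (x / n)^h)
}

#' @rdname hill_up_sat
#' @export
hill_up <- function(x, n, h) {
  check_hill_args(x, n, h)
  xh <- x^h
  xh / (xh + n^h)
}

#' @rdname hill_up_sat
#' @export
hill_down <- function(x, n, h) {
  check_hill_args(x, n, h)
  1 / (1 + (x / n)^h)
}

check_hill_args <- function(x, n, h) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("hill functions require finite non-negative 'x'", call. = FALSE)
  if (any(n <= 0) || any(h <= 0))
    stop("hill functions require positive 'n' and 'h'", call. = FALSE)
  invisible(NULL)
}
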