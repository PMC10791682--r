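#' Round half away from zero
#'
#' Decimal rounding with the half-up rule used for all printed-table display
#' (base [round()] rounds half to even). A small absolute guard absorbs binary
#' representation error so that e.g. 0.15 rounds to 0.2 at one digit.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' round_half_up(0.5, 0)  # 1
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-8) / scale
}

# format to fixed decimals with half-up rounding (display strings)
fmt_num <- function(x, digits = 2) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

fmt_pct <- function(p, digits = 1) {
  paste0(fmt_num(100 * p, digits), "%")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wbi <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "wbi_error")))
}
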