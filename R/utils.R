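## small internal helpers shared across modules

#' @noRd
stop_caflow <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "caflow_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_caflow(sprintf("`%s` must be a single finite number", name),
                "caflow_parameter_error")
  }
  if (positive && x <= 0) {
    stop_caflow(sprintf("`%s` must be > 0 (got %g)", name, x),
                "caflow_parameter_error")
  }
  if (nonneg && x < 0) {
    stop_caflow(sprintf("`%s` must be >= 0 (got %g)", name, x),
                "caflow_parameter_error")
  }
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## centered moving average with shrinking windows at the edges; width in
## frames is forced to an odd number so the window is symmetric
#' @noRd
moving_average <- function(y, width) {
  n <- length(y)
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || n < 3L) return(y)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## significance stars matching the usual figure annotation convention
#' @param p numeric vector of p-values
#' @return character vector: "ns", "*", "**", "***" or "****"
#' @noRd
p_stars <- function(p) {
  cut(p,
      breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"),
      right = FALSE) |> as.character()
}
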