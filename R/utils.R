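#' Wrap an angle onto the orientation half-circle
#'
#' Maps angles in degrees onto the 180-degree orientation cycle, using the
#' half-open interval \code{[-90, 90)}. The boundary +90 maps to -90 so that
#' every orientation has a unique representative.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in \code{[-90, 90)}.
#' @export
#' @examples
#' wrap_orientation(c(90, -95, 175))
wrap_orientation <- function(x) {
  ((x + 90) %% 180) - 90
}

# stop() with a sprintf-style message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# mean of several equal-length numeric vectors (trial averaging)
average_traces <- function(traces) {
  lens <- vapply(traces, length, integer(1))
  if (length(unique(lens)) != 1L)
    abort("traces to average have unequal lengths (%s)",
          paste(unique(lens), collapse = ", "))
  Reduce(`+`, traces) / length(traces)
}
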