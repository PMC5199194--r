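#' Build a tuning curve from per-direction response magnitudes
#'
#' @param directions drift directions in degrees (must be exactly the
#'   protocol's direction set, in any order).
#' @param magnitudes response magnitudes, one per direction (mV or pA).
#' @param protocol a \code{\link{stim_protocol}}.
#' @param baseline a \code{bm_baseline} (or NULL).
#' @param eye \code{"contra"} or \code{"ipsi"}.
#' @param input_type \code{"total"}, \code{"thalamic"} or \code{"cortical"}.
#' @param clamp_mode recording mode the magnitudes came from.
#' @param units \code{"mV"} or \code{"pA"}.
#' @param n_cycles_used per-direction cycle counts (2 or 3), optional.
#' @return object of class \code{tuning_curve}, directions sorted ascending.
#' @export
build_tuning_curve <- function(directions, magnitudes, protocol,
                               baseline = NULL,
                               eye = c("contra", "ipsi"),
                               input_type = c("total", "thalamic", "cortical"),
                               clamp_mode = c("voltage_clamp", "current_clamp"),
                               units = if (clamp_mode[1] == "current_clamp") "mV" else "pA",
                               n_cycles_used = NULL) {
  eye <- match.arg(eye)
  input_type <- match.arg(input_type)
  clamp_mode <- match.arg(clamp_mode)
  want <- protocol_directions(protocol)
  if (anyDuplicated(directions))
    abort("duplicate direction(s): %s",
          paste(unique(directions[duplicated(directions)]), collapse = ", "))
  miss <- setdiff(want, directions)
  if (length(miss))
    abort("missing direction(s): %s", paste(miss, collapse = ", "))
  extra <- setdiff(directions, want)
  if (length(extra))
    abort("direction(s) outside the protocol set: %s",
          paste(extra, collapse = ", "))
  if (length(magnitudes) != length(directions))
    abort("magnitudes and directions differ in length")
  if (any(!is.finite(magnitudes))) abort("non-finite response magnitude")
  ord <- order(directions)
  structure(list(directions = directions[ord],
                 magnitudes = as.numeric(magnitudes)[ord],
                 baseline = baseline, eye = eye, input_type = input_type,
                 clamp_mode = clamp_mode, units = units,
                 n_cycles_used = if (is.null(n_cycles_used)) NULL
                                 else n_cycles_used[ord]),
            class = "tuning_curve")
}

#' Vector-sum orientation statistics
#'
#' Computes the normalized orientation vector
#' \eqn{\sum_\theta R(\theta) e^{i 2\theta} / \sum_\theta R(\theta)} over the
#' tuning curve (angles in the doubled orientation space). Its modulus is
#' the global orientation selectivity index (gOSI); half its phase, shifted
#' by -90 degrees and wrapped into \code{[-90, 90)}, is the preferred
#' orientation. Negative (baseline-subtracted) magnitudes are clipped to 0
#' before the sum; the clipped fraction is reported.
#'
#' The preferred orientation is undefined (NA) when all clipped magnitudes
#' are zero or the resultant vanishes (e.g. a perfectly untuned curve).
#'
#' @param curve a \code{\link{tuning_curve}}.
#' @return list of class \code{orientation_stats} with \code{gOSI},
#'   \code{pref_O} (degrees in \code{[-90, 90)} or NA), \code{resultant}
#'   (complex) and \code{frac_clipped}.
#' @export
orientation_vector <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  R <- curve$magnitudes
  clipped <- R < 0
  R <- pmax(R, 0)
  S <- sum(R)
  if (S <= 0) {
    return(structure(list(gOSI = NA_real_, pref_O = NA_real_,
                          resultant = NA_complex_,
                          frac_clipped = mean(clipped)),
                     class = "orientation_stats"))
  }
  theta <- curve$directions * pi / 180
  resultant <- sum(R * exp(2i * theta)) / S
  gOSI <- Mod(resultant)
  pref <- if (gOSI < 1e-12) NA_real_ else
    wrap_orientation(Arg(resultant) / 2 * 180 / pi - 90)
  structure(list(gOSI = gOSI, pref_O = pref, resultant = resultant,
                 frac_clipped = mean(clipped)),
            class = "orientation_stats")
}

#' Circular difference between two preferred orientations
#'
#' The absolute difference along the 180-degree orientation cycle:
#' \code{min(d, 180 - d)} with \code{d = |a - b| mod 180}, always in
#' \code{[0, 90]}. NA inputs propagate (cells with undefined preference are
#' excluded from difference statistics).
#'
#' @param pref_a,pref_b preferred orientations in degrees (vectorized).
#' @return difference(s) in degrees, in \code{[0, 90]}.
#' @export
#' @examples
#' delta_orientation(-85, 85)  # 10, across the wrap-around
delta_orientation <- function(pref_a, pref_b) {
  d <- abs(pref_a - pref_b) %% 180
  pmin(d, 180 - d)
}

#' @export
print.orientation_stats <- function(x, ...) {
  cat(sprintf("gOSI = %s, pref_O = %s deg%s\n",
              format(x$gOSI, digits = 4),
              if (is.na(x$pref_O)) "undefined" else format(x$pref_O, digits = 4),
              if (x$frac_clipped > 0)
                sprintf(" (%.0f%% of directions clipped at 0)",
                        100 * x$frac_clipped) else ""))
  invisible(x)
}

#' @export
print.tuning_curve <- function(x, ...) {
  os <- orientation_vector(x)
  cat(sprintf("<tuning_curve> %s / %s (%s, %s)\n",
              x$eye, x$input_type, x$clamp_mode, x$units))
  m <- rbind(direction = x$directions, magnitude = signif(x$magnitudes, 4))
  print(m)
  print(os)
  invisible(x)
}

#' Plot a tuning curve
#'
#' Response magnitude against drift direction, with the preferred
#' orientation annotated.
#'
#' @param x a \code{\link{tuning_curve}}.
#' @param ... passed to \code{plot}.
#' @export
plot.tuning_curve <- function(x, ...) {
  os <- orientation_vector(x)
  plot(x$directions, x$magnitudes, type = "b", pch = 16,
       xlab = "drift direction (deg)",
       ylab = sprintf("response (%s)", x$units),
       main = sprintf("%s %s  gOSI=%.2f  pref_O=%s",
                      x$eye, x$input_type, os$gOSI,
                      if (is.na(os$pref_O)) "NA"
                      else sprintf("%.1f deg", os$pref_O)), ...)
  abline(h = 0, lty = 3)
  invisible(x)
}
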