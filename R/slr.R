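#' Sea-level rise trajectory
#'
#' Quadratic cumulative sea-level curves E(t) = a t + b t^2 over a 2010-2110
#' simulation epoch (t in years since 2010), in the style of the National
#' Research Council scenario curves as extrapolated by US Army Corps of
#' Engineers guidance: anchored to a present-day linear trend `a` with the
#' acceleration `b` solved so that E(100) equals the prescribed century total.
#' The stock "low" and "high" curves total 0.52 m and 1.65 m per century.
#'
#' @param label `"low"`, `"high"`, or a custom label (then `century_total`
#'   must be given).
#' @param century_total Total rise at t = 100, in meters. Defaults to 0.52
#'   for `"low"` and 1.65 for `"high"`.
#' @param initial_rate Present-day linear rate in m/yr (default 0.002,
#'   approximately the Golden Gate trend).
#' @return An `slr_curve` object.
#' @export
#' @examples
#' slr_elevation(slr_curve("high"), 50)
slr_curve <- function(label = c("low", "high"), century_total = NULL,
                      initial_rate = 0.002) {
  if (is.null(century_total)) {
    label <- match.arg(label)
    century_total <- switch(label, low = 0.52, high = 1.65)
  }
  stopifnot(is.numeric(century_total), century_total >= 0, initial_rate >= 0)
  b <- (century_total - initial_rate * 100) / 100^2
  if (b < 0) {
    stop("century_total smaller than the linear trend alone; ",
         "curve would decelerate", call. = FALSE)
  }
  structure(
    list(label = label[1], initial_rate = initial_rate, quad_coeff = b,
         century_total = century_total),
    class = "slr_curve"
  )
}

#' Cumulative sea-level rise at time t
#'
#' @param curve An [slr_curve()].
#' @param t Years since the 2010 epoch, in `[0, 100]` (vectorized).
#' @return Cumulative rise in meters.
#' @export
slr_elevation <- function(curve, t) {
  stopifnot(inherits(curve, "slr_curve"))
  if (any(t < 0 | t > 100)) {
    stop("`t` must lie within [0, 100] years of the simulation epoch",
         call. = FALSE)
  }
  curve$initial_rate * t + curve$quad_coeff * t^2
}

#' Sea-level rise between two times
#'
#' The per-interval offset consumed by the accretion simulator; additive over
#' adjacent intervals by construction.
#'
#' @param curve An [slr_curve()].
#' @param t0,t1 Interval endpoints in years, `0 <= t0 <= t1 <= 100`.
#' @return Rise over the interval in meters.
#' @export
slr_increment <- function(curve, t0, t1) {
  if (any(t1 < t0)) stop("`t1` must be >= `t0`", call. = FALSE)
  slr_elevation(curve, t1) - slr_elevation(curve, t0)
}

#' @export
print.slr_curve <- function(x, ...) {
  cat(sprintf("<slr_curve> %s: E(t) = %.4g t + %.4g t^2, E(100) = %.3f m\n",
              x$label, x$initial_rate, x$quad_coeff, x$century_total))
  invisible(x)
}

#' Tabulate an SLR trajectory
#'
#' @param x An [slr_curve()].
#' @param ... Unused.
#' @return Tibble with `year` (0-100) and `slr_m`.
#' @export
tidy.slr_curve <- function(x, ...) {
  tibble::tibble(year = 0:100, slr_m = slr_elevation(x, 0:100))
}

#' @export
autoplot.slr_curve <- function(object, ...) {
  ggplot2::ggplot(tidy.slr_curve(object),
                  ggplot2::aes(x = .data$year, y = .data$slr_m)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Years since 2010", y = "Cumulative SLR (m)",
                  title = paste0("Sea-level rise trajectory (", object$label, ")")) +
    ggplot2::theme_minimal()
}
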