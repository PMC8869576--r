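# Cross-device G-value scaling: activity recorded on a different sensor is
# mapped into the range the staging thresholds assume by a ratio of device
# extrema (range, maximum, or minimum ratio; the minimum ratio performed
# best on the wearable-vs-PSG benchmark and is the default).

#' Scaling specification
#'
#' @param method `"min_ratio"` (default; scale = Gmin/Gdmin), `"max_ratio"`
#'   (Gmax/Gdmax) or `"range_ratio"` ((Gmax-Gmin)/(Gdmax-Gdmin)), where
#'   G* are the reference device's extrema and Gd* the source device's.
#' @param g_max,g_min Reference-device G-value extrema (`g_max > g_min >= 0`).
#' @param gd_max,gd_min Source-device G-value extrema; must be positive where
#'   the chosen method divides by them.
#' @return A `scaling_spec` list.
#' @export
scaling_spec <- function(method = c("min_ratio", "max_ratio", "range_ratio"),
                         g_max, g_min, gd_max, gd_min) {
  method <- match.arg(method)
  for (v in list(g_max, g_min, gd_max, gd_min))
    if (length(v) != 1L || is.na(v) || !is.finite(v))
      abort_invalid("extrema must be single finite numbers")
  if (!(g_max > g_min) || g_min < 0)
    abort_invalid("reference extrema must satisfy g_max > g_min >= 0")
  if (method == "range_ratio" && gd_max <= gd_min)
    abort_invalid("range_ratio requires gd_max > gd_min")
  if (method == "max_ratio" && gd_max <= 0)
    abort_invalid("max_ratio requires gd_max > 0")
  if (method == "min_ratio" && gd_min <= 0)
    abort_invalid("min_ratio requires gd_min > 0")
  structure(list(method = method, g_max = g_max, g_min = g_min,
                 gd_max = gd_max, gd_min = gd_min), class = "scaling_spec")
}

#' Fit a cross-device scale factor
#'
#' @param spec A [scaling_spec()].
#' @return The scalar multiplier mapping source G-values onto the reference
#'   device's range under the chosen method.
#' @export
fit_scale <- function(spec) {
  switch(spec$method,
         range_ratio = (spec$g_max - spec$g_min) / (spec$gd_max - spec$gd_min),
         max_ratio = spec$g_max / spec$gd_max,
         min_ratio = spec$g_min / spec$gd_min)
}

#' Apply a scale factor to an epoch series
#'
#' Multiplies every G-value by `scale`; heart rate is untouched. Linear and
#' order-preserving, so a `min_ratio` fit maps the source minimum exactly
#' onto the reference minimum.
#'
#' @param epochs An [epoch_series()].
#' @param scale Positive scalar from [fit_scale()].
#' @return The rescaled [epoch_series()].
#' @export
apply_scale <- function(epochs, scale) {
  if (length(scale) != 1L || is.na(scale) || scale <= 0)
    abort_invalid("scale must be a single positive number")
  epoch_series(epochs$g_value * scale, epochs$heart_rate_bpm,
               attr(epochs, "epoch_seconds") %||% 30)
}

#' G-value extrema of a recording
#'
#' Extrema are computed over one subject-night (the smallest self-contained
#' unit) unless you pool series yourself before calling.
#'
#' @param epochs An [epoch_series()].
#' @return `list(g_min, g_max)`.
#' @export
device_extrema <- function(epochs) {
  if (nrow(epochs) == 0L) abort_invalid("empty epoch series")
  list(g_min = min(epochs$g_value), g_max = max(epochs$g_value))
}
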