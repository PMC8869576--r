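# Signal ingestion: reduce raw accelerometer / RR-interval streams to the
# aligned 30-s epoch representation (G-value + heart rate) that every
# downstream stage consumes, plus the epoch-table CSV dialect.

#' Sleep stage labels
#'
#' The four-label stage set used throughout the package. Coarser views
#' (NREM = LIGHT + DEEP, SLEEP = everything but WAKE) are derived on the fly
#' by [confusion()] and [sleep_summary()], never stored.
#'
#' @return Character vector `c("WAKE", "LIGHT", "DEEP", "REM")`.
#' @export
stage_levels <- function() c("WAKE", "LIGHT", "DEEP", "REM")

#' Raw tri-axial accelerometer trace
#'
#' Container for a raw wrist-accelerometer recording. Timestamps are seconds
#' from record start and must be monotone non-decreasing; axis values are in
#' units of g (1 g = 9.81 m/s^2, gravity included).
#'
#' @param time_s Numeric, sample timestamps in seconds, monotone non-decreasing.
#' @param ax_g,ay_g,az_g Numeric, per-sample acceleration per axis in g.
#' @param nominal_rate Nominal sampling rate in samples/second (default 250,
#'   the smartwatch accelerometer rate the pipeline was designed around).
#' @return A `raw_accel_trace`: data frame with the four signal columns and a
#'   `nominal_rate` attribute.
#' @export
raw_accel_trace <- function(time_s, ax_g, ay_g, az_g, nominal_rate = 250) {
  n <- length(time_s)
  if (n == 0L) abort_invalid("accelerometer trace is empty")
  if (length(ax_g) != n || length(ay_g) != n || length(az_g) != n)
    abort_invalid("axis series must all have the same length as time_s")
  if (!is.numeric(nominal_rate) || length(nominal_rate) != 1L || nominal_rate <= 0)
    abort_invalid("nominal_rate must be a single positive number")
  if (anyNA(time_s) || any(!is.finite(time_s)))
    abort_malformed("non-finite timestamps in accelerometer trace")
  if (is.unsorted(time_s))
    abort_malformed("accelerometer timestamps are not monotone non-decreasing")
  out <- data.frame(time_s = as.numeric(time_s), ax_g = as.numeric(ax_g),
                    ay_g = as.numeric(ay_g), az_g = as.numeric(az_g))
  attr(out, "nominal_rate") <- nominal_rate
  class(out) <- c("raw_accel_trace", "data.frame")
  out
}

#' Beat-to-beat (RR) interval series
#'
#' PPG-derived inter-beat intervals. Intervals outside the physiological
#' window (200, 4000) ms are discarded on construction (motion artifacts and
#' missed beats); the kept fraction is recorded in the `kept` attribute.
#'
#' @param beat_times Numeric, beat timestamps in seconds, strictly increasing.
#' @param rr_ms Numeric, beat-to-beat intervals in milliseconds, positive.
#' @return An `rr_series` data frame with columns `beat_times`, `rr_ms`.
#' @export
rr_series <- function(beat_times, rr_ms) {
  if (length(beat_times) != length(rr_ms))
    abort_invalid("beat_times and rr_ms must have the same length")
  if (length(beat_times) == 0L) abort_invalid("empty RR series")
  if (anyNA(beat_times) || is.unsorted(beat_times, strictly = TRUE))
    abort_malformed("beat_times must be strictly increasing")
  if (anyNA(rr_ms) || any(rr_ms <= 0))
    abort_malformed("rr_ms must be positive")
  keep <- rr_ms > 200 & rr_ms < 4000
  out <- data.frame(beat_times = as.numeric(beat_times[keep]),
                    rr_ms = as.numeric(rr_ms[keep]))
  if (nrow(out) == 0L) abort_invalid("empty RR series after artifact cleaning")
  attr(out, "kept") <- mean(keep)
  class(out) <- c("rr_series", "data.frame")
  out
}

#' Per-epoch series of activity and heart rate
#'
#' The central container: one row per consecutive 30-s epoch, holding the
#' epoch G-value (non-negative activity magnitude, device activity units) and
#' mean heart rate in beats/minute (possibly `NA` before gap filling).
#'
#' @param g_value Numeric, non-negative activity per epoch.
#' @param heart_rate_bpm Optional numeric, heart rate per epoch in (20, 250)
#'   where present; `NA` allowed.
#' @param epoch_seconds Epoch duration in seconds (fixed at 30 for the
#'   staging constants to apply).
#' @return An `epoch_series` data frame with columns `epoch_index`
#'   (0-based, gap-free), `g_value`, `heart_rate_bpm`.
#' @export
epoch_series <- function(g_value, heart_rate_bpm = NULL, epoch_seconds = 30) {
  if (anyNA(g_value) || any(!is.finite(g_value)))
    abort_invalid("g_value must be finite")
  if (any(g_value < 0)) abort_invalid("g_value must be non-negative")
  n <- length(g_value)
  if (is.null(heart_rate_bpm)) heart_rate_bpm <- rep(NA_real_, n)
  if (length(heart_rate_bpm) != n)
    abort_invalid("heart_rate_bpm must match g_value length")
  hr <- as.numeric(heart_rate_bpm)
  bad <- !is.na(hr) & (hr <= 20 | hr >= 250)
  if (any(bad))
    abort_invalid(sprintf("heart_rate_bpm outside (20, 250) at epoch %d",
                          which(bad)[1] - 1L))
  out <- data.frame(epoch_index = seq_len(n) - 1L,
                    g_value = as.numeric(g_value), heart_rate_bpm = hr)
  attr(out, "epoch_seconds") <- epoch_seconds
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Hypnogram: per-epoch sleep-stage labels
#'
#' A character vector of stage labels (one per epoch, aligned with an
#' [epoch_series()]) restricted to [stage_levels()], tagged with its
#' provenance (algorithm output vs. reference scoring).
#'
#' @param stage Character vector of labels in [stage_levels()].
#' @param provenance `"predicted"` or `"reference"`.
#' @return A `hypnogram` (classed character vector).
#' @export
hypnogram <- function(stage, provenance = c("predicted", "reference")) {
  provenance <- match.arg(provenance)
  stage <- as.character(stage)
  if (anyNA(stage)) abort_invalid("hypnogram stages must not be missing")
  bad <- setdiff(unique(stage), stage_levels())
  if (length(bad))
    abort_invalid(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  structure(stage, class = "hypnogram", provenance = provenance)
}

#' @export
`[.hypnogram` <- function(x, i) {
  structure(unclass(x)[i], class = "hypnogram",
            provenance = attr(x, "provenance"))
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = stage_levels()))
  cat(sprintf("<hypnogram: %d epochs (%.1f h), %s>\n", length(x),
              length(x) / 120, attr(x, "provenance") %||% "predicted"))
  print(tab)
  invisible(x)
}

#' Epoch activity (G-value) from a raw accelerometer trace
#'
#' Reduces a raw tri-axial trace to one activity value per full non-overlapping
#' epoch window. The per-sample dynamic acceleration is the deviation of the
#' vector magnitude from 1 g (the static gravity component), expressed in
#' milli-g; the epoch G-value is its maximum over the window (aggregator
#' configurable for device calibration). Epochs start at the first sample's
#' timestamp; a trailing partial window is dropped.
#'
#' @param trace A [raw_accel_trace()].
#' @param epoch_seconds Window length in seconds (default 30).
#' @param aggregate How to collapse per-sample dynamic acceleration within a
#'   window: `"max"` (default), `"mean"` or `"sum"`.
#' @return An [epoch_series()] with `g_value` only.
#' @export
epoch_activity <- function(trace, epoch_seconds = 30,
                           aggregate = c("max", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(trace, "raw_accel_trace"))
    trace <- raw_accel_trace(trace$time_s, trace$ax_g, trace$ay_g, trace$az_g)
  if (epoch_seconds <= 0) abort_invalid("epoch_seconds must be positive")
  t0 <- trace$time_s[1]
  dur <- trace$time_s[nrow(trace)] - t0
  n_ep <- floor(dur / epoch_seconds)
  if (n_ep < 1)
    return(epoch_series(numeric(0), epoch_seconds = epoch_seconds))
  dyn <- 1000 * abs(sqrt(trace$ax_g^2 + trace$ay_g^2 + trace$az_g^2) - 1)
  idx <- floor((trace$time_s - t0) / epoch_seconds)
  keep <- idx < n_ep
  f <- factor(idx[keep], levels = 0:(n_ep - 1L))
  agg <- switch(aggregate, max = max, mean = mean, sum = sum)
  g <- vapply(split(dyn[keep], f),
              function(v) if (length(v)) agg(v) else 0, numeric(1))
  epoch_series(unname(g), epoch_seconds = epoch_seconds)
}

#' Per-epoch heart rate from an RR-interval series
#'
#' For each epoch window, heart rate is 60000 divided by the mean RR interval
#' (ms) of the beats falling in the window. Epochs with no beats are filled
#' with the value of the nearest epoch that has beats (ties broken toward the
#' earlier epoch), since the REM clustering step cannot accept missing values;
#' filled positions are reported in the `filled` attribute.
#'
#' @param rr An [rr_series()].
#' @param n_epochs Number of epochs to produce (align with the activity series).
#' @param epoch_seconds Epoch duration in seconds (default 30).
#' @param t0 Time of the first epoch's start, seconds (default 0).
#' @return Numeric vector of length `n_epochs` (bpm), attribute `filled`.
#' @export
epoch_heart_rate <- function(rr, n_epochs, epoch_seconds = 30, t0 = 0) {
  if (!inherits(rr, "rr_series")) rr <- rr_series(rr$beat_times, rr$rr_ms)
  if (length(n_epochs) != 1L || is.na(n_epochs) || n_epochs <= 0)
    abort_invalid("n_epochs must be a positive count")
  idx <- floor((rr$beat_times - t0) / epoch_seconds)
  keep <- idx >= 0 & idx < n_epochs
  if (!any(keep)) abort_invalid("no beats fall inside the epoch grid")
  f <- factor(idx[keep], levels = 0:(n_epochs - 1L))
  mean_rr <- vapply(split(rr$rr_ms[keep], f),
                    function(v) if (length(v)) mean(v) else NA_real_, numeric(1))
  hr <- unname(60000 / mean_rr)
  missing <- unname(which(is.na(hr)))
  if (length(missing)) {
    present <- which(!is.na(hr))
    for (i in missing) {
      # nearest observed epoch; tie -> earlier epoch
      d <- abs(present - i)
      hr[i] <- hr[present[which.min(d)]]
    }
  }
  attr(hr, "filled") <- missing - 1L   # 0-based epoch indices
  hr
}

# ---- epoch-table CSV dialect ------------------------------------------
# header: epoch_index,g_value,heart_rate_bpm[,stage]; UTF-8, "." decimal.

#' Map external sleep-stage labels onto the four-label set
#'
#' Accepts the numeric and string label dialects of polysomnography exports
#' (PhysioNet-style): 0/W -> WAKE; 1/2/N1/N2 -> LIGHT; 3/4/N3 -> DEEP;
#' 5/R/REM -> REM. Canonical labels pass through. Unknown labels are an
#' error.
#'
#' @param x Character (or numeric) vector of stage labels.
#' @return Character vector of labels in [stage_levels()].
#' @export
map_stage_labels <- function(x) {
  m <- c("0" = "WAKE", "W" = "WAKE", "WAKE" = "WAKE",
         "1" = "LIGHT", "2" = "LIGHT", "N1" = "LIGHT", "N2" = "LIGHT",
         "LIGHT" = "LIGHT",
         "3" = "DEEP", "4" = "DEEP", "N3" = "DEEP", "DEEP" = "DEEP",
         "5" = "REM", "R" = "REM", "REM" = "REM")
  key <- toupper(trimws(as.character(x)))
  out <- m[key]
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    abort_malformed(paste0("unknown stage label(s): ", paste(bad, collapse = ", ")))
  }
  unname(out)
}

#' Read an epoch table
#'
#' Reads the CSV dialect `epoch_index,g_value,heart_rate_bpm[,stage]`.
#' Numeric columns must parse; `epoch_index` must be 0-based, consecutive and
#' duplicate-free. A `stage` column, if present, is mapped through
#' [map_stage_labels()] and returned as a reference/predicted hypnogram.
#'
#' @param path File path.
#' @param provenance Provenance recorded on the returned hypnogram.
#' @return `list(epochs = epoch_series, hypnogram = hypnogram or NULL)`.
#' @export
read_epoch_table <- function(path, provenance = "reference") {
  if (!file.exists(path)) abort_invalid(paste0("file not found: ", path))
  df <- read.csv(path, colClasses = "character", check.names = TRUE)
  req <- c("epoch_index", "g_value", "heart_rate_bpm")
  miss <- setdiff(req, names(df))
  if (length(miss))
    abort_malformed(paste0(path, ": missing required column(s): ",
                           paste(miss, collapse = ", ")))
  num <- function(col) {
    raw <- trimws(df[[col]])
    raw[is.na(raw)] <- "NA"    # read.csv maps the literal string to NA
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(raw %in% c("", "NA")))
    if (length(bad))
      abort_malformed(sprintf("%s: non-numeric '%s' in column %s at line %d",
                              path, raw[bad[1]], col, bad[1] + 1L))
    v
  }
  ei <- num("epoch_index")
  if (anyDuplicated(ei))
    abort_malformed(sprintf("%s: duplicate epoch_index at line %d",
                            path, anyDuplicated(ei) + 1L))
  o <- order(ei)
  ei <- ei[o]
  if (length(ei) && !identical(as.integer(ei), seq_along(ei) - 1L))
    abort_malformed(paste0(path, ": epoch_index must be 0-based and gap-free"))
  g <- num("g_value")[o]
  hr <- num("heart_rate_bpm")[o]
  ep <- epoch_series(g, hr)
  hyp <- NULL
  if ("stage" %in% names(df))
    hyp <- hypnogram(map_stage_labels(df$stage[o]), provenance)
  list(epochs = ep, hypnogram = hyp)
}

#' Write an epoch table
#'
#' Inverse of [read_epoch_table()]; numeric values are written with 17
#' significant digits so finite values round-trip exactly.
#'
#' @param epochs An [epoch_series()].
#' @param path Output file path.
#' @param hyp Optional [hypnogram()] to store in a `stage` column.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(epochs, path, hyp = NULL) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(epoch_index = epochs$epoch_index,
                    g_value = fmt(epochs$g_value),
                    heart_rate_bpm = fmt(epochs$heart_rate_bpm))
  if (!is.null(hyp)) {
    if (length(hyp) != nrow(epochs))
      abort_invalid("hypnogram length does not match epoch series")
    out$stage <- as.character(hyp)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a raw accelerometer CSV (`time_s,ax_g,ay_g,az_g`)
#' @param path File path.
#' @param nominal_rate Nominal sampling rate, samples/second.
#' @return A [raw_accel_trace()].
#' @export
read_raw_accel <- function(path, nominal_rate = 250) {
  if (!file.exists(path)) abort_invalid(paste0("file not found: ", path))
  df <- read.csv(path)
  req <- c("time_s", "ax_g", "ay_g", "az_g")
  miss <- setdiff(req, names(df))
  if (length(miss))
    abort_malformed(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
  raw_accel_trace(df$time_s, df$ax_g, df$ay_g, df$az_g, nominal_rate)
}

#' Read an RR-interval CSV (`time_s,rr_ms`)
#' @param path File path.
#' @return An [rr_series()].
#' @export
read_rr <- function(path) {
  if (!file.exists(path)) abort_invalid(paste0("file not found: ", path))
  df <- read.csv(path)
  miss <- setdiff(c("time_s", "rr_ms"), names(df))
  if (length(miss))
    abort_malformed(paste0(path, ": missing column(s): ", paste(miss, collapse = ", ")))
  rr_series(df$time_s, df$rr_ms)
}
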