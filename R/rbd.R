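# Abnormal-REM quantification: the percentage of REM minutes whose G-value
# exceeds a threshold (the RBD screening index), and the Mann-Whitney sweep
# that selects the threshold as the one best separating control from PD.

#' Abnormal-REM percentage
#'
#' The index is `100 * n / T`, where T is the total number of REM minutes of
#' the night and n the number of those minutes whose G-value exceeds the
#' threshold. Minutes are built from pairs of consecutive 30-s REM epochs
#' within each REM segment (a trailing odd epoch counts as one minute) and
#' aggregated by the maximum (or mean) G-value of their epochs.
#'
#' @param epochs An [epoch_series()].
#' @param hyp The aligned [hypnogram()].
#' @param threshold Positive G-value cut-off (default 1500, the value
#'   selected by the published threshold sweep).
#' @param minute_aggregate `"max"` (default) or `"mean"`.
#' @return An `abnormal_rem` list: `n_abnormal_min`, `total_rem_min`,
#'   `percent`, `threshold`, `no_rem` (TRUE when the night has no REM, in
#'   which case `percent` is defined as 0), and `g_abnormal` (the G-values
#'   of the suprathreshold minutes).
#' @export
abnormal_rem_percent <- function(epochs, hyp, threshold = 1500,
                                 minute_aggregate = c("max", "mean")) {
  minute_aggregate <- match.arg(minute_aggregate)
  if (length(hyp) != nrow(epochs))
    abort_invalid("hypnogram length does not match epoch series")
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0)
    abort_invalid("threshold must be a single positive number")
  agg <- switch(minute_aggregate, max = max, mean = mean)
  st <- as.character(hyp)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_ab <- 0L
  t_min <- 0L
  g_ab <- numeric(0)
  for (i in which(r$values == "REM")) {
    idx <- starts[i]:ends[i]
    minute_id <- (seq_along(idx) + 1L) %/% 2L
    g_min <- vapply(split(epochs$g_value[idx], minute_id), agg, numeric(1))
    t_min <- t_min + length(g_min)
    n_ab <- n_ab + sum(g_min > threshold)
    g_ab <- c(g_ab, g_min[g_min > threshold])
  }
  structure(list(n_abnormal_min = n_ab, total_rem_min = t_min,
                 percent = if (t_min == 0L) 0 else 100 * n_ab / t_min,
                 threshold = threshold, no_rem = t_min == 0L,
                 g_abnormal = g_ab),
            class = "abnormal_rem")
}

#' @export
print.abnormal_rem <- function(x, ...) {
  cat(sprintf("abnormal REM: %.2f%% (%d of %d REM minutes above G = %g)%s\n",
              x$percent, x$n_abnormal_min, x$total_rem_min, x$threshold,
              if (x$no_rem) " [no REM detected]" else ""))
  invisible(x)
}

#' Mann-Whitney U test (exact permutation null for small samples)
#'
#' Two-sample rank test reporting `U` (the Mann-Whitney statistic of `x`),
#' `T` (the rank sum of `y`), and the p-value. For combined sample sizes up
#' to `exact_max_n` the p-value is exact: the null distribution of U is
#' enumerated over all assignments of the pooled observations (midranks, so
#' ties are handled exactly). Larger samples use the normal approximation
#' with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (x is the first/control group by convention).
#' @param alternative `"two.sided"` (default), `"greater"` (x tends larger)
#'   or `"less"`.
#' @param exact_max_n Largest combined n for the exact null (default 20).
#' @return List `U`, `T`, `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "greater", "less"),
                         exact_max_n = 20) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) abort_invalid("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) abort_invalid("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  R1 <- sum(r[seq_len(n1)])
  U <- R1 - n1 * (n1 + 1) / 2
  Ty <- sum(r[n1 + seq_len(n2)])
  eps <- 1e-9
  if (N <= exact_max_n) {
    idx <- combn(N, n1)
    Us <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    p_le <- mean(Us <= U + eps)
    p_ge <- mean(Us >= U - eps)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    method <- "exact permutation"
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sigma <- sqrt((n1 * n2 / 12) * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1))))
    if (sigma == 0)   # every observation tied: no evidence against the null
      return(list(U = U, T = Ty, p_value = 1,
                  method = "normal approximation with tie correction"))
    z_num <- U - mu
    cc <- switch(alternative,   # continuity correction
                 two.sided = sign(z_num) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z_num - cc) / sigma
    p <- switch(alternative,
                two.sided = min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, T = Ty, p_value = p, method = method)
}

#' Per-subject abnormal-REM summaries for a cohort
#'
#' @param nights List of nights, each `list(epochs = epoch_series,
#'   hypnogram = hypnogram)`.
#' @param threshold G-value cut-off.
#' @param statistic Per-subject summary: `"percent"` (default; the
#'   abnormal-REM percentage, which normalises for between-subject
#'   differences in total REM time), `"abnormal_minutes"` (the raw count of
#'   suprathreshold REM minutes), or `"g_median"` (the median G-value of the
#'   suprathreshold REM minutes, 0 when there are none).
#' @param minute_aggregate Passed to [abnormal_rem_percent()].
#' @return Numeric vector, one value per night.
#' @export
cohort_abnormal_rem <- function(nights, threshold,
                                statistic = c("percent", "abnormal_minutes",
                                              "g_median"),
                                minute_aggregate = "max") {
  statistic <- match.arg(statistic)
  vapply(nights, function(nt) {
    a <- abnormal_rem_percent(nt$epochs, nt$hypnogram, threshold,
                              minute_aggregate)
    switch(statistic, abnormal_minutes = as.numeric(a$n_abnormal_min),
           percent = a$percent,
           g_median = if (length(a$g_abnormal)) median(a$g_abnormal) else 0)
  }, numeric(1))
}

#' G-value threshold sweep
#'
#' For each candidate threshold, each subject's abnormal-REM summary is
#' computed and the control and PD groups are compared with a two-sided
#' Mann-Whitney U test; the chosen threshold is the one with the smallest
#' p-value (ties broken toward the smaller threshold).
#'
#' @param control,pd Lists of nights (`list(epochs, hypnogram)` each), at
#'   least 2 subjects per group.
#' @param thresholds Candidate G-value thresholds (default 1200 to 4500 in
#'   steps of 300).
#' @param statistic,minute_aggregate Passed to [cohort_abnormal_rem()].
#' @return A `sweep_result`: `table` (data frame with per-threshold `U`,
#'   `T`, `p_value` and group medians) and `chosen`.
#' @export
threshold_sweep <- function(control, pd, thresholds = seq(1200, 4500, by = 300),
                            statistic = c("percent", "abnormal_minutes",
                                          "g_median"),
                            minute_aggregate = "max") {
  statistic <- match.arg(statistic)
  if (length(control) < 2L || length(pd) < 2L)
    abort_invalid("both groups need at least 2 subjects")
  if (length(thresholds) < 1L) abort_invalid("no thresholds supplied")
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(thr) {
    v_c <- cohort_abnormal_rem(control, thr, statistic, minute_aggregate)
    v_p <- cohort_abnormal_rem(pd, thr, statistic, minute_aggregate)
    mw <- mann_whitney(v_c, v_p)
    data.frame(threshold = thr, U = mw$U, T = mw$T, p_value = mw$p_value,
               median_control = median(v_c), median_pd = median(v_p))
  })
  tab <- do.call(rbind, rows)
  chosen <- tab$threshold[which.min(tab$p_value)]  # thresholds ascending: ties -> smallest
  structure(list(table = tab, chosen = chosen, statistic = statistic),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("G-value threshold sweep (%s), chosen threshold = %g\n",
              x$statistic, x$chosen))
  print(x$table, row.names = FALSE)
  invisible(x)
}
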