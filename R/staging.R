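# The three-stage classifier: Cole-Kripke sleep/awake scoring, cumulative
# G-value scoring for light/deep, per-night 1-D k-means on heart rate to pull
# REM out of deep sleep, and the three-rule hypnogram cleanup.

#' Staging configuration
#'
#' Every constant of the staging pipeline, with the published defaults.
#'
#' @param ck_weights Cole-Kripke weights for epoch offsets -4..+2 relative to
#'   the scored epoch. Default `c(50, 30, 14, 28, 121, 8, 50)`.
#' @param ck_scale_P Scale factor applied to the weighted activity sum;
#'   device-specific (it was fitted to the original device's activity units).
#'   Default 0.01076. See [sim_staging_config()] for the synthetic device's
#'   calibration.
#' @param score_bins Data frame `g_low`, `g_high`, `increment` partitioning
#'   `[0, Inf)`: the score increment applied for an epoch whose G-value falls
#'   in `[g_low, g_high)`. Defaults: +1 below 40; -2, -3, -5, -10, -20 for
#'   40-50, 50-80, 80-200, 200-400, 400-600; -20 extended above 600.
#' @param deep_score_threshold Epoch labelled DEEP iff its post-update
#'   cumulative score exceeds this (default 0).
#' @param kmeans_K Number of clusters; fixed at 2 (deep vs REM heart rate).
#' @param kmeans_max_iter Hard iteration cap for the clustering (default 300).
#' @param kmeans_stable_iters Terminate once cluster memberships have been
#'   unchanged for this many consecutive iterations (default 100).
#' @param kmeans_restarts Independent seeded initialisations; the lowest
#'   within-cluster sum of squares wins (default 10).
#' @param rem_onset_lockout_min REM within this many minutes after sleep
#'   onset is demoted (rule 1; default 45).
#' @param rem_min_segment_min REM segments shorter than this are demoted
#'   (rule 2; default 5).
#' @param rem_gap_merge_min Non-REM gaps of at most this length flanked by
#'   REM are promoted to REM (rule 3; default 3).
#' @param rem_gap_include_wake Should rule 3 also promote WAKE gaps? Default
#'   TRUE: the rule overrides the sleep/awake classifier, which is what lets
#'   brief high-activity arousals inside REM (the abnormal-REM signal) stay
#'   in REM. Set FALSE to preserve WAKE gaps.
#' @param cluster_on Cluster heart rate in `"bpm"` (default) or the
#'   equivalent mean RR interval in `"rr"` milliseconds; the two are monotone
#'   transforms of each other but cluster memberships can differ.
#' @param rng_seed Seed for the k-means initialisation draws (default 1).
#' @return A `staging_config` list.
#' @export
staging_config <- function(ck_weights = c(50, 30, 14, 28, 121, 8, 50),
                           ck_scale_P = 0.01076,
                           score_bins = NULL,
                           deep_score_threshold = 0,
                           kmeans_K = 2,
                           kmeans_max_iter = 300,
                           kmeans_stable_iters = 100,
                           kmeans_restarts = 10,
                           rem_onset_lockout_min = 45,
                           rem_min_segment_min = 5,
                           rem_gap_merge_min = 3,
                           rem_gap_include_wake = TRUE,
                           cluster_on = c("bpm", "rr"),
                           rng_seed = 1L) {
  if (is.null(score_bins)) {
    score_bins <- data.frame(
      g_low = c(0, 40, 50, 80, 200, 400, 600),
      g_high = c(40, 50, 80, 200, 400, 600, Inf),
      increment = c(1, -2, -3, -5, -10, -20, -20))
  }
  if (length(ck_weights) != 7L || anyNA(ck_weights))
    abort_invalid("ck_weights must be 7 values (offsets -4..+2)")
  if (ck_scale_P <= 0) abort_invalid("ck_scale_P must be positive")
  with(score_bins, {
    if (g_low[1] != 0 || any(g_high[-nrow(score_bins)] != g_low[-1]) ||
        !is.infinite(g_high[nrow(score_bins)]))
      abort_invalid("score_bins must partition [0, Inf) without gaps or overlap")
  })
  if (kmeans_K != 2) abort_invalid("kmeans_K is fixed at 2")
  for (d in c(kmeans_max_iter, kmeans_stable_iters, kmeans_restarts,
              rem_onset_lockout_min, rem_min_segment_min, rem_gap_merge_min))
    if (length(d) != 1L || is.na(d) || d <= 0)
      abort_invalid("durations and iteration counts must be positive")
  structure(list(ck_weights = as.numeric(ck_weights), ck_scale_P = ck_scale_P,
                 score_bins = score_bins,
                 deep_score_threshold = deep_score_threshold,
                 kmeans_K = 2L, kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_stable_iters = as.integer(kmeans_stable_iters),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 rem_onset_lockout_min = rem_onset_lockout_min,
                 rem_min_segment_min = rem_min_segment_min,
                 rem_gap_merge_min = rem_gap_merge_min,
                 rem_gap_include_wake = isTRUE(rem_gap_include_wake),
                 cluster_on = match.arg(cluster_on),
                 rng_seed = as.integer(rng_seed)),
            class = "staging_config")
}

#' Cole-Kripke sleep/awake detection
#'
#' Computes the weighted moving-window score
#' `D_t = P * sum_k W_k * A_{t+k}` for offsets k = -4..+2, where A is the
#' epoch G-value and neighbour epochs outside the record contribute zero
#' activity. An epoch is WAKE iff `D >= 1` (evaluated with a 1e-9 tolerance
#' so exact-boundary arithmetic lands on the wake side), SLEEP otherwise.
#'
#' @param epochs An [epoch_series()].
#' @param config A [staging_config()].
#' @return `list(D = numeric, wake = logical)`.
#' @export
cole_kripke <- function(epochs, config = staging_config()) {
  A <- epochs$g_value
  n <- length(A)
  if (n == 0L) abort_invalid("empty epoch series")
  offs <- -4:2
  D <- numeric(n)
  for (j in seq_along(offs)) {
    k <- offs[j]
    src <- seq_len(n) + k
    ok <- src >= 1 & src <= n
    D[ok] <- D[ok] + config$ck_weights[j] * A[src[ok]]
  }
  D <- config$ck_scale_P * D
  list(D = D, wake = D >= 1 - 1e-9)
}

#' Light/deep classification by cumulative G-value score
#'
#' Over the sleep epochs in time order, a running score starts at 0 and
#' accumulates the increment of the bin containing each epoch's G-value,
#' clamped below at 0. An epoch is DEEP iff its post-update score exceeds
#' `deep_score_threshold`; wake epochs are untouched (score `NA`).
#'
#' @param epochs An [epoch_series()].
#' @param sleep_mask Logical vector marking the epochs classified SLEEP.
#' @param config A [staging_config()].
#' @return `list(score = numeric, stage = character)` with `"LIGHT"`/`"DEEP"`
#'   at sleep positions and `NA` elsewhere.
#' @export
light_deep_score <- function(epochs, sleep_mask, config = staging_config()) {
  n <- nrow(epochs)
  if (length(sleep_mask) != n)
    abort_invalid("sleep_mask length does not match epoch series")
  bins <- config$score_bins
  bin_idx <- findInterval(epochs$g_value, bins$g_low)
  inc <- bins$increment[bin_idx]
  score <- rep(NA_real_, n)
  stage <- rep(NA_character_, n)
  s <- 0
  for (i in which(sleep_mask)) {
    s <- max(0, s + inc[i])
    score[i] <- s
    stage[i] <- if (s > config$deep_score_threshold) "DEEP" else "LIGHT"
  }
  list(score = score, stage = stage)
}

#' One-dimensional two-cluster k-means
#'
#' Lloyd iteration with the termination scheme used for the REM split:
#' centroids are initialised by a seeded draw of two distinct observed
#' values, each point is assigned to its nearer centroid (ties to the
#' lower-valued centroid), centroids are updated to subset means, and the
#' algorithm stops when memberships have been unchanged for
#' `kmeans_stable_iters` consecutive iterations or at `kmeans_max_iter`.
#' `kmeans_restarts` independent initialisations are run and the solution
#' with the lowest within-cluster sum of squares is kept.
#'
#' @param values Numeric vector with at least two distinct values.
#' @param config A [staging_config()].
#' @return A `cluster_model`: list with `centroids` (ascending), `assignment`
#'   (1 = lower cluster, 2 = higher), `iterations_run`, `converged`, `wss`.
#' @export
kmeans_1d <- function(values, config = staging_config()) {
  x <- as.numeric(values)
  if (length(x) < 2L) abort_invalid("need at least 2 values to cluster")
  if (anyNA(x)) abort_invalid("values must not contain NA")
  ux <- unique(x)
  if (length(ux) < 2L)
    abort_degenerate("all values identical; no two-cluster structure")
  run_once <- function(cent) {
    assign_prev <- NULL
    stable <- 0L
    iter <- 0L
    assign <- NULL
    while (iter < config$kmeans_max_iter && stable < config$kmeans_stable_iters) {
      iter <- iter + 1L
      cent <- sort(cent)
      d1 <- abs(x - cent[1])
      d2 <- abs(x - cent[2])
      assign <- ifelse(d1 <= d2, 1L, 2L)   # tie -> lower-valued centroid
      if (identical(assign, assign_prev)) stable <- stable + 1L else stable <- 0L
      assign_prev <- assign
      for (c in 1:2) if (any(assign == c)) cent[c] <- mean(x[assign == c])
    }
    wss <- sum((x - cent[assign])^2)
    list(centroids = cent, assignment = assign, iterations_run = iter,
         converged = stable >= config$kmeans_stable_iters, wss = wss)
  }
  best <- NULL
  with_rng_seed(config$rng_seed, {
    for (r in seq_len(config$kmeans_restarts)) {
      init <- sample(ux, 2L)
      fit <- run_once(init)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  structure(best, class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: centroids %.2f / %.2f, n = %d/%d, %s after %d iterations>\n",
              x$centroids[1], x$centroids[2], sum(x$assignment == 1),
              sum(x$assignment == 2),
              if (x$converged) "converged" else "iteration cap hit",
              x$iterations_run))
  invisible(x)
}

#' REM detection by heart-rate clustering of deep-sleep epochs
#'
#' Clusters the heart rates of the epochs currently labelled DEEP into two
#' groups ([kmeans_1d()], trained per subject-night) and relabels the
#' higher-centroid cluster REM: heart rate is elevated in REM relative to
#' slow-wave sleep. If the deep-sleep heart rates are degenerate (fewer than
#' two distinct values) the split is skipped, all DEEP labels are retained,
#' and the returned hypnogram carries attribute `rem_degenerate = TRUE` with
#' a warning.
#'
#' @param epochs An [epoch_series()] with heart rate present for DEEP epochs.
#' @param hyp A [hypnogram()] containing only WAKE/LIGHT/DEEP labels.
#' @param config A [staging_config()].
#' @return The hypnogram with REM labels added.
#' @export
rem_from_deep <- function(epochs, hyp, config = staging_config()) {
  if (length(hyp) != nrow(epochs))
    abort_invalid("hypnogram length does not match epoch series")
  if (any(unclass(hyp) == "REM"))
    abort_invalid("hypnogram already contains REM labels")
  deep <- which(unclass(hyp) == "DEEP")
  if (length(deep) == 0L) return(hyp)
  hr <- epochs$heart_rate_bpm[deep]
  if (anyNA(hr))
    abort_invalid("missing heart rate among DEEP epochs; fill with epoch_heart_rate() first")
  vals <- if (config$cluster_on == "rr") 60000 / hr else hr
  if (length(unique(vals)) < 2L || length(vals) < 2L) {
    warning("degenerate heart rate among DEEP epochs; REM split skipped",
            call. = FALSE)
    attr(hyp, "rem_degenerate") <- TRUE
    return(hyp)
  }
  km <- kmeans_1d(vals, config)
  # higher heart rate = REM; on the RR scale the mapping flips
  high <- if (config$cluster_on == "rr") 1L else 2L
  st <- unclass(hyp)
  st[deep[km$assignment == high]] <- "REM"
  out <- hypnogram(st, attr(hyp, "provenance") %||% "predicted")
  attr(out, "rem_cluster") <- km
  out
}

#' Rule-based REM cleanup
#'
#' Applies, once each and in order, the three correction rules:
#' \enumerate{
#'   \item REM within the first `rem_onset_lockout_min` minutes after sleep
#'     onset (the first non-WAKE epoch) is demoted to DEEP;
#'   \item separated REM shorter than `rem_min_segment_min` minutes is
#'     demoted to DEEP. "Separated" is read structurally: REM segments lying
#'     within the rule-3 merge distance of one another form one REM period,
#'     and a period is demoted only if its whole span (first to last REM
#'     epoch) is below the minimum. A short fragment next to more REM is not
#'     separated REM, so brief mid-REM interruptions do not erase the
#'     surrounding REM;
#'   \item non-REM gaps of at most `rem_gap_merge_min` minutes between two
#'     REM segments are promoted to REM, overruling the upstream classifiers
#'     (WAKE inside a gap is included unless `rem_gap_include_wake` is
#'     FALSE, in which case gaps containing WAKE are preserved).
#' }
#' Demoted REM becomes DEEP (it was DEEP before the heart-rate split). The
#' composed operator is idempotent.
#'
#' @param hyp A four-label [hypnogram()].
#' @param config A [staging_config()].
#' @return The cleaned hypnogram.
#' @export
rem_postprocess <- function(hyp, config = staging_config()) {
  st <- as.character(hyp)
  n <- length(st)
  if (n == 0L) return(hyp)
  ep_min <- 2L  # epochs per minute at 30-s epochs
  gap_max <- config$rem_gap_merge_min * ep_min
  seg_min <- config$rem_min_segment_min * ep_min
  # rule 1: onset lockout
  onset <- match(TRUE, st != "WAKE")
  if (!is.na(onset)) {
    lock <- onset:min(n, onset + config$rem_onset_lockout_min * ep_min - 1L)
    st[lock][st[lock] == "REM"] <- "DEEP"
  }
  # REM segment table: start/end of each maximal REM run
  segments <- function(st) {
    r <- rle(st)
    ends <- cumsum(r$lengths)
    i <- which(r$values == "REM")
    cbind(start = ends[i] - r$lengths[i] + 1L, end = ends[i])
  }
  # is the gap between consecutive segments bridgeable by rule 3?
  bridgeable <- function(st, gap_from, gap_to) {
    len <- gap_to - gap_from + 1L
    len <= gap_max &&
      (config$rem_gap_include_wake || !any(st[gap_from:gap_to] == "WAKE"))
  }
  # rule 2: group segments into REM periods (consecutive segments whose gaps
  # are bridgeable); demote every segment of a period whose span < minimum
  seg <- segments(st)
  if (nrow(seg)) {
    m <- nrow(seg)
    period <- cumsum(c(1L, vapply(seq_len(m - 1L), function(i) {
      as.integer(!bridgeable(st, seg[i, "end"] + 1L, seg[i + 1L, "start"] - 1L))
    }, integer(1))[seq_len(max(0L, m - 1L))]))
    for (p in unique(period)) {
      idx <- which(period == p)
      span <- seg[idx[length(idx)], "end"] - seg[idx[1L], "start"] + 1L
      if (span < seg_min)
        for (i in idx) st[seg[i, "start"]:seg[i, "end"]] <- "DEEP"
    }
  }
  # rule 3: promote bridgeable gaps between surviving segments
  seg <- segments(st)
  if (nrow(seg) >= 2L) {
    for (i in seq_len(nrow(seg) - 1L)) {
      from <- seg[i, "end"] + 1L
      to <- seg[i + 1L, "start"] - 1L
      if (bridgeable(st, from, to)) st[from:to] <- "REM"
    }
  }
  out <- hypnogram(st, attr(hyp, "provenance") %||% "predicted")
  attr(out, "rem_degenerate") <- attr(hyp, "rem_degenerate")
  out
}

#' Stage a full night
#'
#' The complete classifier: [cole_kripke()] sleep/awake detection, then
#' [light_deep_score()] over the sleep epochs, then [rem_from_deep()] and
#' [rem_postprocess()]. Deterministic given `config$rng_seed`.
#'
#' @param epochs An [epoch_series()] with G-values and heart rate.
#' @param config A [staging_config()].
#' @return A predicted [hypnogram()]; attributes `D` (Cole-Kripke scores) and
#'   `score` (light/deep cumulative score) are attached for inspection.
#' @export
stage_night <- function(epochs, config = staging_config()) {
  ck <- cole_kripke(epochs, config)
  st <- rep(NA_character_, nrow(epochs))
  st[ck$wake] <- "WAKE"
  lds <- light_deep_score(epochs, !ck$wake, config)
  st[!ck$wake] <- lds$stage[!ck$wake]
  hyp <- hypnogram(st, "predicted")
  hyp <- rem_from_deep(epochs, hyp, config)
  hyp <- rem_postprocess(hyp, config)
  attr(hyp, "D") <- ck$D
  attr(hyp, "score") <- lds$score
  hyp
}
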