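# Validation against reference hypnograms (confusion matrices at three
# stage resolutions), per-night sleep summaries, cohort rank statistics and
# device-vs-reference agreement metrics.

#' Build a confusion matrix from counts
#'
#' @param counts Square numeric matrix of epoch counts, rows = reference,
#'   columns = predicted, with matching dimnames.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    abort_invalid("counts must be a square matrix")
  if (any(counts < 0)) abort_invalid("counts must be non-negative")
  labs <- rownames(counts) %||% colnames(counts) %||%
    paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(reference = labs, predicted = labs)
  structure(list(labels = labs, counts = counts, total = sum(counts)),
            class = "confusion_matrix")
}

#' Classification accuracy of a confusion matrix
#'
#' The fraction of epochs on the diagonal: for the two-class case this is
#' (TP + TN) / total.
#'
#' @param cm A [confusion_matrix()].
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  sum(diag(cm$counts)) / cm$total
}

#' Epoch-level confusion of predicted vs reference hypnograms
#'
#' Three stage resolutions are supported:
#' \describe{
#'   \item{`sleep_wake`}{WAKE vs SLEEP over all epochs;}
#'   \item{`nrem_rem`}{NREM (LIGHT + DEEP) vs REM, over the epochs both
#'     hypnograms score as sleep;}
#'   \item{`light_deep_rem`}{the full three-way sleep split, same epochs.}
#' }
#'
#' @param reference,predicted Aligned [hypnogram()]s of equal length.
#' @param scheme The coarsening scheme.
#' @return A [confusion_matrix()] (rows = reference, columns = predicted).
#' @export
confusion <- function(reference, predicted,
                      scheme = c("sleep_wake", "nrem_rem", "light_deep_rem")) {
  scheme <- match.arg(scheme)
  if (length(reference) != length(predicted))
    abort_invalid("hypnograms must have equal length")
  ref <- unclass(reference); prd <- unclass(predicted)
  if (scheme == "sleep_wake") {
    labs <- c("WAKE", "SLEEP")
    ref2 <- ifelse(ref == "WAKE", "WAKE", "SLEEP")
    prd2 <- ifelse(prd == "WAKE", "WAKE", "SLEEP")
  } else {
    keep <- ref != "WAKE" & prd != "WAKE"
    ref <- ref[keep]; prd <- prd[keep]
    if (scheme == "nrem_rem") {
      labs <- c("NREM", "REM")
      ref2 <- ifelse(ref == "REM", "REM", "NREM")
      prd2 <- ifelse(prd == "REM", "REM", "NREM")
    } else {
      labs <- c("LIGHT", "DEEP", "REM")
      ref2 <- ref; prd2 <- prd
    }
  }
  tab <- table(factor(ref2, levels = labs), factor(prd2, levels = labs))
  confusion_matrix(unclass(tab))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  cat(sprintf("accuracy: %.2f%% (%d epochs)\n", 100 * accuracy(x), x$total))
  invisible(x)
}

#' Per-night sleep summary
#'
#' Total sleep time (0.5 min per non-WAKE epoch), time in bed (0.5 min per
#' epoch), sleep efficiency (sleep time / time in bed, as a percentage) and
#' stage percentages relative to the sleep epochs. A night with no sleep
#' epochs gets `NA` stage percentages and `all_wake = TRUE`.
#'
#' @param hyp A [hypnogram()].
#' @return List with `total_sleep_min`, `time_in_bed_min`,
#'   `sleep_efficiency_pct`, `light_pct`, `deep_pct`, `rem_pct`, `all_wake`.
#' @export
sleep_summary <- function(hyp) {
  n <- length(hyp)
  if (n == 0L) abort_invalid("empty hypnogram")
  st <- unclass(hyp)
  n_sleep <- sum(st != "WAKE")
  pct <- function(lab) if (n_sleep == 0L) NA_real_ else 100 * sum(st == lab) / n_sleep
  list(total_sleep_min = 0.5 * n_sleep,
       time_in_bed_min = 0.5 * n,
       sleep_efficiency_pct = 100 * n_sleep / n,
       light_pct = pct("LIGHT"), deep_pct = pct("DEEP"), rem_pct = pct("REM"),
       all_wake = n_sleep == 0L)
}

#' Assemble a cohort table
#'
#' @param group Character vector of group labels, one per subject.
#' @param ... Named numeric per-subject metric vectors of matching length.
#' @return A data frame with a `group` column plus the metrics.
#' @export
cohort_table <- function(group, ...) {
  metrics <- list(...)
  if (!length(metrics)) abort_invalid("supply at least one metric")
  for (m in metrics) if (length(m) != length(group))
    abort_invalid("metric lengths must match the group vector")
  data.frame(group = as.character(group), metrics, check.names = TRUE)
}

#' Group comparison of cohort metrics
#'
#' Two-group designs use the two-sample rank-sum (Mann-Whitney) test
#' ([mann_whitney()]; exact for small samples, tie-corrected normal
#' approximation otherwise); three-group designs use the Kruskal-Wallis test
#' with tie correction. All p-values are two-sided.
#'
#' @param cohort A data frame with a `group` column and numeric metric
#'   columns (see [cohort_table()]).
#' @param design `"two_group"` or `"three_group"`.
#' @param metrics Metric columns to test (default: all numeric columns).
#' @return Data frame with one row per metric: `metric`, `statistic`,
#'   `p_value`, `test`.
#' @export
group_compare <- function(cohort, design = c("two_group", "three_group"),
                          metrics = NULL) {
  design <- match.arg(design)
  if (!"group" %in% names(cohort)) abort_invalid("cohort needs a 'group' column")
  g <- as.character(cohort$group)
  lv <- unique(g)
  need <- if (design == "two_group") 2L else 3L
  if (length(lv) != need)
    abort_invalid(sprintf("%s design requires exactly %d groups (found %d)",
                          design, need, length(lv)))
  if (any(table(g) < 2)) abort_invalid("every group needs at least 2 subjects")
  if (is.null(metrics))
    metrics <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
  rows <- lapply(metrics, function(m) {
    v <- cohort[[m]]
    if (design == "two_group") {
      mw <- mann_whitney(v[g == lv[1]], v[g == lv[2]])
      data.frame(metric = m, statistic = mw$U, p_value = mw$p_value,
                 test = "rank-sum (Mann-Whitney U)")
    } else {
      kt <- kruskal.test(v, factor(g))
      data.frame(metric = m, statistic = unname(kt$statistic),
                 p_value = kt$p.value, test = "Kruskal-Wallis")
    }
  })
  do.call(rbind, rows)
}

#' Agreement between device-derived and reference metrics
#'
#' Mean absolute error, mean absolute percentage error (relative to the
#' reference), root mean square error, and Spearman's rank correlation with
#' its p-value (exact for n of at most 9 without ties, t-approximation
#' otherwise, as in [stats::cor.test()]).
#'
#' @param device,reference Paired numeric vectors, length at least 3.
#' @return List `mae`, `mape_pct`, `rmse`, `rho`, `p_value`.
#' @export
agreement <- function(device, reference) {
  if (length(device) != length(reference)) abort_invalid("paired vectors required")
  n <- length(device)
  if (n < 3L) abort_invalid("need at least 3 pairs")
  if (anyNA(device) || anyNA(reference)) abort_invalid("missing values not allowed")
  d <- device - reference
  mape <- if (any(reference == 0)) NA_real_ else 100 * mean(abs(d / reference))
  ties <- anyDuplicated(device) || anyDuplicated(reference)
  ct <- suppressWarnings(cor.test(device, reference, method = "spearman",
                                  exact = n <= 9 && !ties))
  list(mae = mean(abs(d)), mape_pct = mape, rmse = sqrt(mean(d^2)),
       rho = unname(ct$estimate), p_value = ct$p.value)
}
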