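# Independent oracles and fixture builders. These deliberately use different
# algorithms from the package code paths they check.

# Exhaustive optimal 1-D 2-means: in one dimension an optimal 2-partition is
# a contiguous split of the sorted values, so enumerate all n-1 splits and
# keep the minimisers of the within-cluster sum of squares.
oracle_split_1d <- function(x) {
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  wss <- vapply(seq_len(n - 1L), function(k) {
    a <- xs[1:k]; b <- xs[(k + 1L):n]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  best <- which(wss <= min(wss) + 1e-9)
  assigns <- lapply(best, function(k) {
    a <- integer(n)
    a[o[1:k]] <- 1L
    a[o[(k + 1L):n]] <- 2L
    a
  })
  list(min_wss = min(wss), assignments = assigns)
}

# Brute-force Mann-Whitney p-value: enumerate every assignment of the pooled
# observations to group 1, computing U by direct pairwise comparison
# (#{x > y} + 0.5 #{x == y}), not via ranks.
oracle_mw_p <- function(x, y, alternative = "two.sided") {
  v <- c(x, y)
  n1 <- length(x)
  N <- length(v)
  ustat <- function(sel) {
    xs <- v[sel]; ys <- v[-sel]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- ustat(seq_len(n1))
  Us <- apply(utils::combn(N, n1), 2, ustat)
  eps <- 1e-9
  p_le <- mean(Us <= u_obs + eps)
  p_ge <- mean(Us >= u_obs - eps)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Random four-label hypnogram with realistic run structure (runs of
# geometric length), for property tests of the cleanup rules.
random_hypnogram <- function(n = 240, mean_run = 6) {
  st <- character(0)
  while (length(st) < n) {
    lab <- sample(stage_levels(), 1L, prob = c(0.15, 0.35, 0.30, 0.20))
    st <- c(st, rep(lab, 1L + stats::rgeom(1L, 1 / mean_run)))
  }
  hypnogram(st[seq_len(n)])
}

# A flat trace: watch at rest, z axis carrying gravity.
resting_trace <- function(seconds, rate = 10) {
  t <- seq(0, seconds, by = 1 / rate)
  raw_accel_trace(t, rep(0, length(t)), rep(0, length(t)), rep(1, length(t)),
                  nominal_rate = rate)
}

# Sharply separated simulation profile used for the staging-recovery
# regression: tight stage distributions, few arousals, no bursts.
separated_profile <- function(...) {
  stages <- stage_levels()
  tr <- matrix(c(
    0.950, 0.050, 0.000, 0.000,
    0.004, 0.926, 0.040, 0.030,
    0.002, 0.028, 0.970, 0.000,
    0.004, 0.026, 0.000, 0.970),
    nrow = 4, byrow = TRUE, dimnames = list(stages, stages))
  sim_profile("control", transition = tr,
              hr_mean = c(WAKE = 72, LIGHT = 62, DEEP = 50, REM = 75),
              hr_sd = c(WAKE = 3, LIGHT = 2, DEEP = 1.5, REM = 2),
              g_meanlog = log(c(WAKE = 10000, LIGHT = 250, DEEP = 5, REM = 5)),
              g_sdlog = c(WAKE = 0.3, LIGHT = 0.3, DEEP = 0.5, REM = 0.5),
              abnormal_rem_burst_prob = 0, ...)
}
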