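# The three-stage classifier and its parts.

test_that("Cole-Kripke scores match the closed forms of the printed constants", {
  cfg <- staging_config()
  # zero activity scores zero everywhere: all sleep
  ck0 <- cole_kripke(epoch_series(rep(0, 20)), cfg)
  expect_equal(ck0$D, rep(0, 20))
  expect_false(any(ck0$wake))
  # constant unit activity: interior D = P * sum(W) = 0.01076 * 301
  ck1 <- cole_kripke(epoch_series(rep(1, 20)), cfg)
  expect_equal(ck1$D[10], 3.23876, tolerance = 1e-12)
  expect_true(all(ck1$wake[5:16]))
  # the exact boundary: an isolated epoch with A = 1/(P * W0) gives D = 1, wake
  a0 <- 1 / (0.01076 * 121)
  g <- rep(0, 9); g[5] <- a0
  ckb <- cole_kripke(epoch_series(g), cfg)
  expect_equal(ckb$D[5], 1, tolerance = 1e-12)
  expect_true(ckb$wake[5])
})

test_that("Cole-Kripke wake calls are monotone in activity", {
  set.seed(7)
  for (rep in 1:25) {
    g <- rlnorm(40, log(0.3), 1)
    cfg <- staging_config()
    before <- cole_kripke(epoch_series(g), cfg)$wake
    i <- sample(40, 1)
    g[i] <- g[i] + rlnorm(1, 0, 1)
    after <- cole_kripke(epoch_series(g), cfg)$wake
    expect_true(all(after[before]),
                info = "raising one epoch's activity never flips WAKE to SLEEP")
  }
})

test_that("the cumulative score classifies light and deep per the G-value bins", {
  cfg <- staging_config()
  ep <- epoch_series(c(10, 10, 10))
  out <- light_deep_score(ep, rep(TRUE, 3), cfg)
  expect_equal(out$score, c(1, 2, 3))
  expect_equal(out$stage, rep("DEEP", 3))
  # a 450 G-value epoch drains the score (clamped at zero) and scores LIGHT
  out2 <- light_deep_score(epoch_series(c(10, 450)), c(TRUE, TRUE), cfg)
  expect_equal(out2$score, c(1, 0))
  expect_equal(out2$stage, c("DEEP", "LIGHT"))
  # wake epochs are untouched
  out3 <- light_deep_score(epoch_series(c(10, 10)), c(FALSE, FALSE), cfg)
  expect_true(all(is.na(out3$score)) && all(is.na(out3$stage)))
  expect_error(light_deep_score(epoch_series(c(1, 2)), TRUE, cfg),
               class = "somnograph_invalid_input")
})

test_that("two-cluster k-means recovers point masses and the optimal contiguous split", {
  cfg <- staging_config()
  km <- kmeans_1d(c(50, 50, 90, 90), cfg)
  expect_equal(km$centroids, c(50, 90))
  expect_equal(km$assignment, c(1L, 1L, 2L, 2L))
  expect_true(km$converged)
  km2 <- kmeans_1d(c(55, 58, 60, 72, 75), cfg)
  expect_equal(km2$assignment, c(1L, 1L, 1L, 2L, 2L))
  expect_error(kmeans_1d(c(60, 60, 60), cfg), class = "somnograph_degenerate_input")
  expect_error(kmeans_1d(60, cfg), class = "somnograph_invalid_input")
})

test_that("REM is pulled from deep sleep as the high-heart-rate cluster", {
  hr <- c(55, 56, 54, 80, 82)
  ep <- epoch_series(rep(5, 5), hr)
  hyp <- hypnogram(rep("DEEP", 5))
  out <- rem_from_deep(ep, hyp, staging_config())
  expect_equal(as.character(out), c("DEEP", "DEEP", "DEEP", "REM", "REM"))
  # relabelled epochs all have heart rate at least that of every retained DEEP
  rem_hr <- hr[as.character(out) == "REM"]
  deep_hr <- hr[as.character(out) == "DEEP"]
  expect_true(min(rem_hr) >= max(deep_hr))
})

test_that("REM split leaves hypnograms without deep sleep untouched and flags degenerate heart rate", {
  ep <- epoch_series(rep(5, 4), c(60, 61, 62, 63))
  hyp <- hypnogram(c("WAKE", "LIGHT", "LIGHT", "WAKE"))
  expect_identical(as.character(rem_from_deep(ep, hyp, staging_config())),
                   as.character(hyp))
  ep2 <- epoch_series(rep(5, 4), rep(60, 4))
  hyp2 <- hypnogram(rep("DEEP", 4))
  expect_warning(out <- rem_from_deep(ep2, hyp2, staging_config()),
                 "degenerate")
  expect_equal(as.character(out), rep("DEEP", 4))
  expect_true(attr(out, "rem_degenerate"))
})

test_that("cleanup rule 1 demotes REM inside the 45-minute onset lockout", {
  # onset at epoch 1; REM at minutes 10-20 is inside the lockout
  st <- rep("LIGHT", 240)
  st[20:40] <- "REM"
  out <- rem_postprocess(hypnogram(st), staging_config())
  expect_false(any(as.character(out) == "REM"))
  expect_equal(as.character(out)[20:40], rep("DEEP", 21))
  # REM starting after the lockout survives
  st2 <- rep("LIGHT", 480)
  st2[200:230] <- "REM"
  out2 <- rem_postprocess(hypnogram(st2), staging_config())
  expect_equal(which(as.character(out2) == "REM"), 200:230)
})

test_that("cleanup rule 2 demotes separated REM shorter than 5 minutes but keeps clustered fragments", {
  # an isolated 4-minute segment far from onset is removed
  st <- rep("LIGHT", 480)
  st[200:207] <- "REM"
  out <- rem_postprocess(hypnogram(st), staging_config())
  expect_false(any(as.character(out) == "REM"))
  expect_equal(as.character(out)[200:207], rep("DEEP", 8))
  # two 4-minute fragments separated by a 1-minute gap form one 9-minute
  # period: kept, and the gap is merged by rule 3
  st2 <- rep("LIGHT", 480)
  st2[200:207] <- "REM"; st2[210:217] <- "REM"
  out2 <- rem_postprocess(hypnogram(st2), staging_config())
  expect_equal(which(as.character(out2) == "REM"), 200:217)
})

test_that("cleanup rule 3 merges short non-REM gaps between REM periods", {
  # REM(10 min) + DEEP(2 min) + REM(10 min): the gap becomes REM
  st <- c(rep("LIGHT", 200), rep("REM", 20), rep("DEEP", 4), rep("REM", 20),
          rep("LIGHT", 100))
  out <- rem_postprocess(hypnogram(st), staging_config())
  expect_equal(as.character(out)[221:224], rep("REM", 4))
  # a WAKE gap is merged by default (the rule overrules the classifier) ...
  st2 <- c(rep("LIGHT", 200), rep("REM", 20), rep("WAKE", 2), rep("REM", 20),
           rep("LIGHT", 100))
  out2 <- rem_postprocess(hypnogram(st2), staging_config())
  expect_equal(as.character(out2)[221:222], rep("REM", 2))
  # ... but preserved when configured off
  cfg_nw <- staging_config(rem_gap_include_wake = FALSE)
  out3 <- rem_postprocess(hypnogram(st2), cfg_nw)
  expect_equal(as.character(out3)[221:222], rep("WAKE", 2))
  # gaps longer than 3 minutes are never merged
  st4 <- c(rep("LIGHT", 200), rep("REM", 20), rep("DEEP", 8), rep("REM", 20),
           rep("LIGHT", 100))
  out4 <- rem_postprocess(hypnogram(st4), staging_config())
  expect_equal(as.character(out4)[221:228], rep("DEEP", 8))
})

test_that("the composed cleanup is idempotent on random hypnograms", {
  set.seed(11)
  cfg <- staging_config()
  cfg_nw <- staging_config(rem_gap_include_wake = FALSE)
  for (i in 1:50) {
    h <- random_hypnogram(240)
    for (config in list(cfg, cfg_nw)) {
      once <- rem_postprocess(h, config)
      twice <- rem_postprocess(once, config)
      expect_identical(as.character(twice), as.character(once))
    }
  }
})

test_that("stage_night composes the parts deterministically and stays in the label set", {
  prof <- separated_profile()
  cfg <- sim_staging_config(prof, rng_seed = 5)
  nt <- simulate_night(prof, 99)
  h1 <- stage_night(nt$epochs, cfg)
  h2 <- stage_night(nt$epochs, cfg)
  expect_identical(as.character(h1), as.character(h2))
  expect_equal(length(h1), nrow(nt$epochs))
  expect_true(all(as.character(h1) %in% stage_levels()))
  # constant very high activity is all wake under the published constants
  ep_wake <- epoch_series(rep(1000, 40), rep(60, 40))
  expect_equal(as.character(stage_night(ep_wake, staging_config())),
               rep("WAKE", 40))
})

test_that("with zero activity and bimodal heart rate, REM is exactly the surviving high-rate cluster", {
  # 300 epochs of sleep; high heart rate in two late blocks
  n <- 300
  hr <- rep(56, n)
  hr <- hr + rep(c(0, 0.3), length.out = n)  # break degeneracy
  hi <- c(151:190, 221:260)
  hr[hi] <- 75 + rep(c(0, 0.3), length.out = length(hi))
  ep <- epoch_series(rep(0, n), hr)
  out <- stage_night(ep, staging_config(rng_seed = 2))
  expect_false(any(as.character(out) == "WAKE"))
  expect_equal(which(as.character(out) == "REM"), c(151:190, 221:260))
})
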