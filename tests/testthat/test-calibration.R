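test_that("cuff readings pair with their overlapping PAT window", {
  cuff <- data.frame(t_start = 0, t_end = 30, sbp = 120, dbp = 80)
  win <- data.frame(t_start = 0, t_end = 30, pat_bar = 0.25,
                    n_beats = 30)
  p <- pair_cuff_with_pat(cuff, win)
  expect_identical(nrow(p), 1L)
  expect_equal(p$pat, 0.25)

  far <- data.frame(t_start = 40, t_end = 70, pat_bar = 0.25,
                    n_beats = 30)
  expect_message(p <- pair_cuff_with_pat(cuff, far), "unpaired")
  expect_identical(nrow(p), 0L)
  expect_identical(attr(p, "n_unpaired"), 1L)
})

test_that("aligned simulations pair every reading with the right mean", {
  prof <- list(sbp0 = 120, dbp0 = 80, pat0 = 0.25, gamma = 0.031,
               heart_rate_rest = 70, heart_rate_peak = 90,
               pat_drop_exercise = 0.04, decay_tau = 180,
               pat_jitter_sd = 0, generating_model = "dMK-BH")
  traj <- simulate_pat_trajectory(prof, duration = 900)
  gen <- generating_params(prof)
  bp <- derive_true_bp(traj, gen)
  cuff <- simulate_cuff_readings(bp, device_sd = 0)
  series <- data.frame(beat_time = traj$beat_time, pat = traj$pat_true)
  win <- average_pat_windows(series, cuff[c("t_start", "t_end")])
  p <- pair_cuff_with_pat(cuff, win)
  expect_identical(nrow(p), 30L)
  manual <- vapply(seq_len(nrow(cuff)), function(i) {
    sel <- traj$beat_time >= cuff$t_start[i] &
      traj$beat_time < cuff$t_end[i]
    mean(traj$pat_true[sel])
  }, numeric(1))
  expect_lt(max(abs(p$pat - manual)), 0.001)
})

test_that("identical pairs collapse PTP averaging to that pair", {
  pairs <- data.frame(pat = rep(0.25, 16), sbp = 120, dbp = 80,
                      round = rep(1:4, each = 4))
  fit <- ptp_calibrate("dMK-BH", pairs)
  expect_identical(fit$baseline$sbp0, 120)
  expect_identical(fit$baseline$dbp0, 80)
  expect_identical(fit$baseline$pat0, 0.25)
  expect_identical(fit$audit$n_used, 16L)
})

test_that("exact-curve rounds agree across all six two-point subsets", {
  pats <- c(0.20, 0.23, 0.26, 0.29)
  ex <- exact_pairs("MK-EE", rep(pats, 4))
  pairs <- cbind(ex$pairs, round = rep(1:4, each = 4))
  fit <- ptp_calibrate("MK-EE", pairs)
  expect_identical(fit$audit$n_used, 24L)  # 4 rounds x C(4,2)
  sub <- fit$audit$subset_params
  expect_lt(max(apply(sub, 2, function(col) diff(range(col)))), 1e-9)
  expect_equal(coef(fit), ex$truth, tolerance = 1e-9)
})

test_that("degenerate duplicate-PAT subsets are skipped and logged", {
  block <- data.frame(pat = c(0.25, 0.25, 0.28, 0.31),
                      sbp = c(120, 121, 126, 131),
                      dbp = c(80, 81, 84, 87), round = 1L)
  fit <- ptp_calibrate("L-MK", block)
  expect_identical(fit$audit$n_skipped, 1L)
  expect_match(fit$audit$skips$reason, "degenerate")
  expect_identical(fit$audit$n_used, 5L)
})

test_that("M-M subsets with no real solution are skipped with a reason", {
  pats <- c(0.20, 0.24, 0.28, 0.32)
  ex <- exact_pairs("M-M", pats)
  pairs <- ex$pairs
  # perturb one point so some subset forces a negative radicand
  pairs$sbp[2] <- pairs$sbp[2] + 40
  pairs$round <- 1L
  fit <- tryCatch(ptp_calibrate("M-M", pairs), error = function(e) e)
  if (inherits(fit, "error")) {
    expect_match(conditionMessage(fit), "no real solution|no usable")
  } else {
    expect_gt(fit$audit$n_skipped, 0L)
    expect_match(paste(fit$audit$skips$reason, collapse = " "),
                 "no real solution")
  }
})

test_that("PTP calibration fails loudly when every subset is unusable", {
  pairs <- data.frame(pat = rep(0.25, 8), sbp = 120, dbp = 80,
                      round = rep(1:2, each = 4))
  expect_error(ptp_calibrate("MK-EE", pairs), "no usable subset")
})

test_that("pair order within a round does not change the result", {
  pats <- c(0.20, 0.23, 0.26, 0.29)
  for (model in c("MK-EE", "L-MK", "M-M", "dMK-BH")) {
    ex <- exact_pairs(model, pats)
    pairs <- cbind(ex$pairs, round = 1L)
    f1 <- ptp_calibrate(model, pairs)
    f2 <- ptp_calibrate(model, pairs[c(3, 1, 4, 2), ])
    expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  }
})

test_that("noiseless exact-curve data identify every model's parameters", {
  pats4 <- function(r) 0.20 + 0.03 * (0:3) + 0.002 * r
  for (model in bp_model_ids()) {
    rounds <- lapply(1:4, function(r) {
      if (model %in% c("MK-BH", "dMK-BH"))
        ex <- exact_pairs(model, rep(0.24, 4))
      else
        ex <- exact_pairs(model, pats4(r))
      cbind(ex$pairs, round = r)
    })
    truth <- if (model %in% c("MK-BH", "dMK-BH"))
      exact_pairs(model, 0.24)$truth else exact_pairs(model, 0.25)$truth
    fit <- ptp_calibrate(model, do.call(rbind, rounds))
    expect_lt(max(abs(coef(fit) - truth) / pmax(abs(truth), 1e-12)),
              1e-6)
  }
})

test_that("more calibration rounds do not hurt parameter accuracy", {
  # Monte-Carlo: RMSE of recovered L-MK slope vs truth, 1 vs 4 rounds
  set.seed(77)
  rmse <- function(n_rounds) {
    errs <- replicate(40, {
      pairs <- do.call(rbind, lapply(seq_len(n_rounds), function(r) {
        # well-spread PATs, as drifting 30-s windows deliver in practice
        pats <- sort(runif(4, 0.20, 0.32))
        pats <- 0.20 + 0.12 * (rank(pats) - 1) / 3 +
          runif(4, -0.01, 0.01)
        data.frame(pat = pats, sbp = 195 - 300 * pats + rnorm(4, 0, 2),
                   dbp = 140 - 250 * pats + rnorm(4, 0, 2), round = r)
      }))
      fit <- ptp_calibrate("L-MK", pairs)
      coef(fit)[["sbp.b"]] - (-300)
    })
    sqrt(mean(errs^2))
  }
  expect_lte(rmse(4), rmse(1) * 1.10)  # within Monte-Carlo slack
})
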