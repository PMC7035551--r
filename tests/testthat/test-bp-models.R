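test_that("each model needs its documented number of calibration points", {
  expect_identical(required_calibration_points("MK-EE"), 2L)
  expect_identical(required_calibration_points("L-MK"), 2L)
  expect_identical(required_calibration_points("MK-BH"), 1L)
  expect_identical(required_calibration_points("dMK-BH"), 1L)
  expect_identical(required_calibration_points("M-M"), 3L)
  expect_error(required_calibration_points("XYZ"), "unknown model")
})

test_that("baseline identities hold: PP0 and MBP0 derive from the anchors", {
  bl <- baseline_state(120, 80, 0.25, gamma = 0.031)
  expect_equal(bl$pp0, 40)
  expect_equal(bl$mbp0, 120 / 3 + 2 * 80 / 3)
  expect_error(baseline_state(80, 120, 0.25), "sbp0 > dbp0")
})

test_that("forward evaluation matches hand-substituted values", {
  bl_pairs <- data.frame(pat = 0.25, sbp = 120, dbp = 80)
  dmk <- calibrate_bp_model("dMK-BH", bl_pairs, gamma = 0.031)
  est <- estimate_bp(dmk, 0.20)
  expect_equal(est$sbp, 149.3964, tolerance = 1e-6)
  expect_equal(est$dbp, 86.8964, tolerance = 1e-6)

  mkbh <- calibrate_bp_model("MK-BH", bl_pairs, gamma = 0.031)
  est <- estimate_bp(mkbh, 0.20, warn_crossed = FALSE)
  expect_equal(est$sbp, 132.9032, tolerance = 1e-6)
  expect_equal(est$dbp, 70.4032, tolerance = 1e-6)

  mm <- new_model_for_test("M-M", sbp = c(a = 60, b = 2000, c = 100),
                           dbp = c(a = 40, b = 1500, c = 80))
  expect_equal(estimate_bp(mm, 0.25)$sbp, 60 + sqrt(3600))
})

test_that("MK-BH and dMK-BH return the baseline exactly at PAT = PAT0", {
  for (m in c("MK-BH", "dMK-BH")) {
    obj <- calibrate_bp_model(m, data.frame(pat = 0.25, sbp = 120,
                                            dbp = 80), gamma = 0.031)
    est <- estimate_bp(obj, 0.25)
    expect_identical(est$sbp, 120)
    expect_identical(est$dbp, 80)
  }
})

test_that("dMK-BH pulse pressure follows PP0 (PAT0/PAT)^2 identically", {
  obj <- calibrate_bp_model("dMK-BH", data.frame(pat = 0.25, sbp = 120,
                                                 dbp = 80))
  pat <- seq(0.15, 0.45, length.out = 1000)
  est <- estimate_bp(obj, pat, warn_crossed = FALSE)
  expect_lt(max(abs((est$sbp - est$dbp) - 40 * (0.25 / pat)^2)), 1e-10)
})

test_that("M-M with positive c is decreasing in PAT and bounded below", {
  mm <- new_model_for_test("M-M", sbp = c(a = 60, b = 2000, c = 100),
                           dbp = c(a = 40, b = 1500, c = 80))
  pat <- seq(0.15, 5, length.out = 500)
  est <- estimate_bp(mm, pat, warn_crossed = FALSE)
  expect_true(all(diff(est$sbp) < 0))
  expect_true(all(est$sbp > 60 + sqrt(2000)))
  expect_lt(estimate_bp(mm, 1e3, warn_crossed = FALSE)$sbp -
              (60 + sqrt(2000)), 1e-3)
})

test_that("M-M errors out of its real domain instead of going complex", {
  mm <- new_model_for_test("M-M", sbp = c(a = 60, b = -2000, c = 10),
                           dbp = c(a = 40, b = -2000, c = 10))
  expect_error(estimate_bp(mm, 0.5), "no real solution")
})

test_that("two-point closed forms match hand calculation", {
  pairs <- data.frame(pat = c(0.25, 0.20), sbp = c(120, 135),
                      dbp = c(80, 88))
  ee <- calibrate_bp_model("MK-EE", pairs)
  expect_equal(unname(coef(ee)[c("sbp.a", "sbp.b")]),
               c(-67.2213, 26.8115), tolerance = 1e-4)
  lmk <- calibrate_bp_model("L-MK", pairs)
  expect_equal(unname(coef(lmk)[c("sbp.a", "sbp.b")]), c(195, -300))
})

test_that("M-M three-point calibration recovers its generating parameters", {
  ex <- exact_pairs("M-M", c(0.20, 0.25, 0.30))
  fit <- calibrate_bp_model("M-M", ex$pairs)
  expect_equal(coef(fit), ex$truth, tolerance = 1e-6)
})

test_that("dMK-BH one-point calibration applies the baseline identities", {
  fit <- calibrate_bp_model("dMK-BH",
                            data.frame(pat = 0.25, sbp = 120, dbp = 80),
                            gamma = 0.031)
  expect_equal(unname(coef(fit)[["pp0"]]), 40)
  expect_equal(unname(coef(fit)[["mbp0"]]), 93.33333, tolerance = 1e-6)
})

test_that("calibration round trip reproduces every calibration point", {
  set.seed(42)
  for (model in bp_model_ids()) {
    k <- required_calibration_points(model)
    for (rep in 1:50) {
      pairs <- random_pairs(model, k)
      fit <- tryCatch(calibrate_bp_model(model, pairs),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        expect_match(conditionMessage(fit), "no real solution")
        next
      }
      est <- estimate_bp(fit, pairs$pat, warn_crossed = FALSE)
      expect_lt(max(abs(est$sbp - pairs$sbp) / abs(pairs$sbp)), 1e-9)
      expect_lt(max(abs(est$dbp - pairs$dbp) / abs(pairs$dbp)), 1e-9)
    }
  }
})

test_that("duplicate PAT values are rejected as degenerate", {
  pairs <- data.frame(pat = c(0.25, 0.25), sbp = c(120, 135),
                      dbp = c(80, 88))
  expect_error(calibrate_bp_model("MK-EE", pairs), "degenerate")
  expect_error(calibrate_bp_model("L-MK", pairs), "degenerate")
  expect_error(
    calibrate_bp_model("M-M", data.frame(pat = c(0.2, 0.2, 0.3),
                                         sbp = c(120, 125, 130),
                                         dbp = c(80, 82, 84))),
    "degenerate")
})

test_that("MK-BH and dMK-BH are invariant to joint PAT rescaling", {
  for (m in c("MK-BH", "dMK-BH")) {
    a <- calibrate_bp_model(m, data.frame(pat = 0.25, sbp = 121,
                                          dbp = 79), gamma = 0.031)
    b <- calibrate_bp_model(m, data.frame(pat = 250, sbp = 121,
                                          dbp = 79), gamma = 0.031)
    pat <- c(0.20, 0.23, 0.28)
    ea <- estimate_bp(a, pat, warn_crossed = FALSE)
    eb <- estimate_bp(b, pat * 1000, warn_crossed = FALSE)
    expect_equal(ea$sbp, eb$sbp)
    expect_equal(ea$dbp, eb$dbp)
  }
})

test_that("model parameters survive a JSON round trip bit-exactly", {
  pairs <- data.frame(pat = c(0.25, 0.20), sbp = c(120, 135),
                      dbp = c(80, 88))
  for (fit in list(calibrate_bp_model("MK-EE", pairs),
                   calibrate_bp_model("dMK-BH", pairs[1, ]))) {
    path <- withr_local_tempfile()
    write_model_json(fit, path)
    back <- read_model_json(path)
    expect_identical(coef(back), coef(fit))
    expect_identical(back$model, fit$model)
  }
})

test_that("estimates crossing sbp <= dbp are flagged, not hidden", {
  crossed <- new_model_for_test("L-MK", sbp = c(a = 100, b = 100),
                                dbp = c(a = 120, b = -100))
  expect_warning(estimate_bp(crossed, 0.05), "sbp <= dbp")
  expect_silent(estimate_bp(crossed, 0.50))
})
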