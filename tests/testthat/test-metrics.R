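test_that("normalization divides by the last pre-treatment sample", {
  s <- ci_series(c(23.9, 24.1), c(2.0, 1.8), t_treat = 24)
  n <- normalize_ci(s)
  expect_equal(n$ci, c(1.0, 0.9))
  # constant series normalizes to 1 everywhere; renormalizing is the identity
  cs <- ci_series(0:10, rep(2, 11), t_treat = 5)
  ncs <- normalize_ci(cs)
  expect_equal(ncs$ci, rep(1, 11))
  expect_equal(normalize_ci(ncs)$ci, ncs$ci)
  expect_error(normalize_ci(ci_series(c(23.9, 24.1), c(0, 1.8), t_treat = 24)),
               "positive")
  expect_error(normalize_ci(ci_series(c(25, 26), c(1, 1), t_treat = 24)),
               "no sample")
})

test_that("percent cytolysis identities hold", {
  tt <- seq(20, 40, by = 0.5)
  no_eff <- ci_series(tt, 1 + 0.05 * (tt - 20), t_treat = 24)
  same <- ci_series(tt, no_eff$ci, condition = "effector", et_ratio = 1,
                    t_treat = 24)
  cv <- percent_cytolysis(no_eff, same)
  expect_true(all(cv$cytolysis == 0))

  dead <- ci_series(tt, ifelse(tt <= 24, no_eff$ci, 0),
                    condition = "effector", et_ratio = 1, t_treat = 24)
  cvd <- percent_cytolysis(no_eff, dead, normalized = FALSE)
  expect_true(all(cvd$cytolysis == 100))

  # formula arithmetic on raw values: 2.0 vs 0.5 -> 75%
  a <- ci_series(c(24, 25), c(2, 2), t_treat = 24)
  b <- ci_series(c(24, 25), c(2, 0.5), condition = "effector", et_ratio = 1,
                 t_treat = 24)
  expect_equal(percent_cytolysis(a, b, normalized = FALSE)$cytolysis, 75)

  # overgrowth in the effector well gives negative values, unclamped
  over <- ci_series(tt, no_eff$ci * 1.2, condition = "effector", et_ratio = 1,
                    t_treat = 24)
  expect_true(all(percent_cytolysis(no_eff, over,
                                    normalized = FALSE)$cytolysis < 0))

  zero_ctrl <- ci_series(c(24, 25), c(1, 0), t_treat = 24)
  expect_error(percent_cytolysis(zero_ctrl, b, normalized = FALSE), "zero")
})

test_that("mismatched grids are interpolated onto the control grid", {
  t1 <- seq(20, 40, by = 1)
  t2 <- seq(20.5, 38.5, by = 1)
  no_eff <- ci_series(t1, rep(2, length(t1)), t_treat = 24)
  eff <- ci_series(t2, rep(1, length(t2)), condition = "effector",
                   et_ratio = 1, t_treat = 24)
  cv <- percent_cytolysis(no_eff, eff, normalized = FALSE)
  expect_true(all(cv$cytolysis == 50))
  expect_true(max(cv$times) <= 38.5 - 24 + 1e-9)  # overlap only
})

test_that("killing time interpolates the first threshold crossing", {
  ramp <- cytolysis_curve(seq(0, 10, by = 0.5), seq(0, 100, by = 5),
                          et_ratio = 1)
  expect_equal(killing_time(ramp, 50)$kt, 5)
  samp <- cytolysis_curve(c(0, 2, 4, 6), c(0, 30, 40, 80), et_ratio = 1)
  expect_equal(killing_time(samp, 50)$kt, 4.5)
  plateau <- cytolysis_curve(seq(0, 48, by = 1),
                             55 * (1 - exp(-seq(0, 48, by = 1) / 5)),
                             et_ratio = 1)
  kt80 <- killing_time(plateau, 80)
  expect_false(kt80$detected)
  expect_true(is.na(kt80$kt))
  expect_error(killing_time(samp, 0), "threshold")
})

test_that("killing time is monotone in the threshold on a monotone curve", {
  set.seed(9)
  for (i in 1:10) {
    vals <- cumsum(runif(30, 0, 6))
    vals <- vals / max(vals) * runif(1, 40, 100)
    cv <- cytolysis_curve(seq_along(vals), vals)
    kts <- lapply(c(10, 30, 50, 70, 90), function(p) killing_time(cv, p))
    det <- vapply(kts, function(k) k$detected, TRUE)
    # once undetected, all higher thresholds are undetected
    expect_true(all(diff(det) <= 0))
    finite <- vapply(kts[det], function(k) k$kt, 1.0)
    expect_true(all(diff(finite) >= 0))
  }
})

test_that("the killing-time table preserves ND entries and ratio ordering", {
  truth <- killing_truth_m1(h = 3, l = 1)
  pan <- generate_killing_panel(truth, experiment_design(sampling_min = 15),
                                noise_off(), seed = 3)$panel
  kt <- killing_time_table(pan, thresholds = c(20, 50))
  expect_named(kt, c("et_ratio", "threshold_pct", "kt_h", "detected"))
  expect_equal(nrow(kt), 6)
  # stronger effector pressure kills faster
  kt50 <- kt[kt$threshold_pct == 50, ]
  expect_lt(kt50$kt_h[kt50$et_ratio == 2], kt50$kt_h[kt50$et_ratio == 0.5])
  # monotone in threshold within one ratio
  expect_true(all(kt$kt_h[kt$threshold_pct == 20] <=
                    kt$kt_h[kt$threshold_pct == 50]))

  # a panel whose effector wells equal the control is ND everywhere
  ctrl <- pan[[1]]
  clone <- ci_series(ctrl$times, ctrl$ci, condition = "effector",
                     et_ratio = 1, t_treat = ctrl$t_treat)
  kt_nd <- killing_time_table(list(ctrl, clone), thresholds = c(20, 50, 80))
  expect_true(all(!kt_nd$detected))

  expect_error(killing_time_table(list(clone, clone)), "no-effector")
})
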