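test_that("least squares matches hand-computed residuals", {
  # model trace identically zero (explicit ci0 = 0) against data (1, 2)
  p <- growth_truth_m1()
  s <- ci_series(c(0, 1), c(1, 2), ci0 = 0)
  expect_equal(least_squares(p, s), 5)

  # M = 2 frozen state y = (0.3, 0.7) vs datum 1.2 -> (1.0 - 1.2)^2
  p2 <- model_parameters(r = c(0, 0), d = c(0, 0), a = c(1, 1), K = 2,
                         h = c(0, 0), l = c(0, 0), b_A = .5, b_E = .5,
                         r_A = 0, d_E = 0, C = 1)
  s2 <- ci_series(c(0, 3), c(1, 1.2), ci0 = 1)
  expect_equal(least_squares(p2, s2, fractions = c(0.3, 0.7)),
               (1 - 1)^2 + (1 - 1.2)^2, tolerance = 1e-10)

  # noise-free self-consistency at the generating truth
  g <- generate_growth_series(growth_truth_m1(), coarse_design(),
                              noise_off(), seed = 2)
  expect_lt(least_squares(growth_truth_m1(), g$series), 1e-8)
  pan <- generate_killing_panel(killing_truth_m1(), coarse_design(),
                                noise_off(), seed = 2)
  expect_lt(least_squares(killing_truth_m1(), pan$panel), 1e-8)
})

test_that("initial populations are uniform within bounds and reproducible", {
  free <- rtcafit:::free_spec_growth(1, default_parameter_ranges())
  cfg <- ma_config(N = 1000, tau_max = 0, seed = 5)
  set.seed(5); pop1 <- init_population(free, cfg)
  set.seed(5); pop2 <- init_population(free, cfg)
  expect_identical(pop1, pop2)
  for (j in seq_len(nrow(free))) {
    expect_true(all(pop1[, j] >= free$lo[j] & pop1[, j] <= free$hi[j]))
  }
  # uniform-mean sanity for the [0, 50] components
  se <- 3 * (50 / sqrt(12)) / sqrt(1000)
  expect_lt(abs(mean(pop1[, "r_1"]) - 25), se)
  expect_lt(abs(mean(pop1[, "d_1"]) - 25), se)
})

test_that("perturbed copies stay within 2 percent of their parent before clamping", {
  free <- rtcafit:::free_spec_growth(1, default_parameter_ranges())
  parents <- matrix(c(10, 20, 0.5, 30), 1, 4,
                    dimnames = list(NULL, free$name))
  set.seed(11)
  for (i in 1:50) {
    child <- rtcafit:::perturb_vectors(parents, free, 0.02)
    expect_true(all(abs(child / parents - 1) <= 0.02 + 1e-12))
  }
  # components at a boundary are clamped back into the box
  edge <- matrix(c(50, 50, 1, 100), 1, 4, dimnames = list(NULL, free$name))
  set.seed(12)
  kids <- do.call(rbind, replicate(50, rtcafit:::perturb_vectors(edge, free, 0.02),
                                   simplify = FALSE))
  expect_true(all(kids[, 1] <= 50 & kids[, 3] <= 1 & kids[, 4] <= 100))
})

test_that("a generation is composed of elites, perturbed copies and fresh draws", {
  free <- rtcafit:::free_spec_growth(1, default_parameter_ranges())
  cfg <- ma_config(N = 8, tau_max = 1, seed = 3)
  set.seed(3)
  pop <- init_population(free, cfg)
  ls <- c(5, 1, 7, 3, 9, 2, 8, 6)
  nxt <- evolve_generation(pop, ls, free, cfg)
  expect_equal(nrow(nxt$pop), 8)
  # 2 elites (scores 1 and 2) carried unchanged with their scores
  expect_identical(nxt$pop[1, ], pop[2, ])
  expect_identical(nxt$pop[2, ], pop[6, ])
  expect_equal(nxt$ls[1:2], c(1, 2))
  expect_true(all(is.na(nxt$ls[3:8])))
  # 2 perturbed copies of the elites, within 2 percent
  expect_true(all(abs(nxt$pop[3, ] / pop[2, ] - 1) <= 0.02 + 1e-12))
  expect_true(all(abs(nxt$pop[4, ] / pop[6, ] - 1) <= 0.02 + 1e-12))
})

test_that("the fit is elitist, reproducible and respects bounds", {
  g <- generate_growth_series(growth_truth_m1(), coarse_design(),
                              noise_model(cv = 0.02, sd_add = 0, spike_rel = 0),
                              seed = 8)
  free <- rtcafit:::free_spec_growth(1, default_parameter_ranges())
  template <- growth_truth_m1()
  cfg <- ma_config(N = 40, tau_max = 40, top_k = 10, seed = 21)
  fit1 <- run_ma(g$series, free, template, cfg, stage = "growth")
  fit2 <- run_ma(g$series, free, template, cfg, stage = "growth")
  expect_identical(fit1, fit2)
  expect_true(all(diff(fit1$history) <= 0))
  expect_equal(fit1$best_ls, min(attr(fit1$top_k, "ls")))
  for (j in seq_len(nrow(free)))
    expect_true(all(fit1$top_k[, j] >= free$lo[j] &
                      fit1$top_k[, j] <= free$hi[j]))
  # tau_max = 0 returns the best of the initial random population
  fit0 <- run_ma(g$series, free, template, ma_config(N = 40, tau_max = 0,
                                                     top_k = 10, seed = 21))
  expect_equal(length(fit0$history), 1)
  expect_equal(fit0$best_ls, fit1$history[1])
})

test_that("the growth stage recovers a single-population growth curve", {
  truth <- growth_truth_m1()
  g <- generate_growth_series(truth, coarse_design(), noise_off(), seed = 31)
  fit <- fit_growth_stage(g$series, M = 1,
                          config = ma_config(N = 200, tau_max = 500,
                                             top_k = 50, seed = 31))
  expect_lt(fit$best_ls, 1e-3)
  b <- fit$best
  # the identifiable combinations: net growth rate and logistic curvature
  expect_equal(b$r - b$d, truth$r - truth$d, tolerance = 0.05)
  expect_equal(unname(b$r * b$a / b$K), truth$r * truth$a / truth$K,
               tolerance = 0.05)
  # fitted trajectory reproduces the data
  ci_fit <- observable_ci(simulate_growth(b, g$series$ci[1],
                                          t1 = max(g$series$times)),
                          g$series$times)
  expect_lt(sqrt(mean((ci_fit - g$series$ci)^2)), 1e-2)
})

test_that("stage functions validate their inputs and carry reference defaults", {
  eff <- ci_series(c(0, 1), c(1, 1), condition = "effector", et_ratio = 1,
                   t_treat = 0.5)
  expect_error(fit_growth_stage(eff), "effector-free")
  no_treat <- ci_series(c(0, 1), c(1, 1), condition = "effector", et_ratio = 1)
  expect_error(fit_interaction_stage(list(no_treat), growth_truth_m1()),
               "treatment time")
  expect_error(fit_interaction_stage(list(ci_series(c(0, 1), c(1, 1))),
                                     growth_truth_m1()), "no effector")
  # reference budgets: tau = 1e4 (growth), tau = 1e3 (interaction), top-250
  expect_equal(eval(formals(fit_growth_stage)$config)$tau_max, 10000L)
  expect_equal(eval(formals(fit_interaction_stage)$config)$tau_max, 1000L)
  expect_equal(ma_config()$N, 1000L)
  expect_equal(ma_config()$top_k, 250L)
  expect_equal(formals(fit_growth_stage)$M, 3L)
  cfg <- ma_config()
  expect_equal(cfg$elite_frac + cfg$perturb_frac + cfg$random_frac, 1)
})

test_that("integration failure makes a vector maximally unfit rather than erroring", {
  p <- growth_truth_m1()
  s <- ci_series(c(0, 24), c(0.1, 0.5))
  bad <- integrator_settings(rtol = 1e-14, atol = 1e-16, h_min = 0.05)
  expect_identical(least_squares(p, s, settings = bad), Inf)
})
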