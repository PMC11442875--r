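test_that("integration matches the closed-form logistic solution", {
  p <- model_parameters(r = 1, d = 0, a = 1, K = 2, h = 0, l = 0,
                        b_A = .5, b_E = .5, r_A = 0, d_E = 0, C = 1)
  tr <- simulate_growth(p, 0.1, t1 = 72)
  tt <- seq(0, 72, by = 5 / 60)
  exact <- logistic_exact(tt, 1, 2, 0.1)
  expect_lt(max(abs(observable_ci(tr, tt) - exact) / exact), 1e-6)
  # the spec point value y(5)
  expect_equal(observable_ci(tr, 5), logistic_exact(5, 1, 2, 0.1),
               tolerance = 1e-6)
})

test_that("integration matches closed-form exponential decay", {
  p <- model_parameters(r = 0, d = 1, a = 1, K = 2, h = 0, l = 0,
                        b_A = .5, b_E = .5, r_A = 0, d_E = 0, C = 1)
  tr <- simulate_growth(p, 1, t1 = 72)
  tt <- seq(0, 72, by = 5 / 60)
  exact <- exp(-tt)
  y <- observable_ci(tr, tt)
  # relative error where the analytic value is resolvable above the
  # integrator's absolute tolerance and state floor
  sel <- exact > 1e-10
  expect_lt(max(abs(y[sel] - exact[sel]) / exact[sel]), 1e-6)
  # beyond that the solution tracks the decay into the floored equilibrium
  expect_lt(max(abs(y[!sel] - exact[!sel])), 1e-10)
  expect_true(all(y[exact < 1e-13] == 0))
  expect_equal(observable_ci(tr, 2), exp(-2), tolerance = 1e-6)
})

test_that("zero initial state stays identically zero", {
  tr <- integrate_model(coupled_params(), c(0, 0, 0), 0, 10)
  expect_true(all(tr$segments[[1]]$states == 0))
})

test_that("repeated integration is bit-identical", {
  p <- hap1_reference_parameters("parental")
  a <- integrate_model(p, c(0.2, 0.2, 0.2, 0.5, 0), 0, 48)
  b <- integrate_model(p, c(0.2, 0.2, 0.2, 0.5, 0), 0, 48)
  expect_identical(a, b)
})

test_that("halving the tolerance changes the solution by less than the larger tolerance", {
  p <- coupled_params()
  s0 <- c(0.5, 0.3, 0)
  y1 <- trajectory_states(integrate_model(p, s0, 0, 24,
                                          integrator_settings(rtol = 1e-6)), 24)
  y2 <- trajectory_states(integrate_model(p, s0, 0, 24,
                                          integrator_settings(rtol = 5e-7)), 24)
  expect_lt(max(abs(y1 - y2)), 1e-6)
})

test_that("states remain nonnegative and logistic-bounded for random parameters", {
  set.seed(421)
  for (i in 1:20) {
    p <- random_params(M = 2)
    s0 <- c(runif(2, 0, 1), runif(1, 0, 1), 0)
    tr <- tryCatch(integrate_model(p, s0, 0, 24),
                   error = function(e) NULL)  # pathological draws may underflow
    if (is.null(tr)) next
    st <- tr$segments[[1]]$states
    expect_true(all(st >= 0))
    V <- st[, 1:2, drop = FALSE] %*% p$a
    expect_true(all(V <= max(V[1], p$K) * (1 + 1e-6)))
  }
})

test_that("T-cell logistic load is bounded by its carrying capacity when l = 0", {
  set.seed(77)
  for (i in 1:10) {
    p <- random_params(M = 1)
    p$l <- 0  # no exhaustion drain
    s0 <- c(0.5, runif(1, 0, 2), runif(1, 0, 1))
    tr <- tryCatch(integrate_model(p, s0, 0, 24), error = function(e) NULL)
    if (is.null(tr)) next
    st <- tr$segments[[1]]$states
    W <- p$b_A * st[, 2] + p$b_E * st[, 3]
    expect_true(all(W <= max(W[1], p$C) * (1 + 1e-6)))
  }
})

test_that("exhausted T cells satisfy their integral balance", {
  p <- hap1_reference_parameters("parental")
  tr <- simulate_coculture(p, ci0 = 0.3, t_treat = 24, t_end = 96, et_ratio = 1)
  tt <- seq(24, 96, length.out = 4001)
  st <- trajectory_states(tr, tt)
  production <- st[, "x_A"] * (st[, 1:3] %*% p$l)
  integrand <- production - p$d_E * st[, "x_E"]
  lhs <- st[nrow(st), "x_E"] - st[1, "x_E"]
  rhs <- simpson(tt, as.numeric(integrand))
  # relative to the total exhaustion production (lhs itself can be ~0 when
  # the cancer is extinct and all exhausted cells have decayed)
  expect_lt(abs(lhs - rhs) / simpson(tt, as.numeric(production)), 1e-4)
})

test_that("solution agrees with an independent stiff solver", {
  skip_if_not_installed("deSolve")
  p <- hap1_reference_parameters("fasn_ko")
  s0 <- c(0.2, 0.2, 0.2, 0.4, 0)
  f <- function(t, y, parms) {
    S <- sum(p$a * y[1:3]); L <- sum(p$l * y[1:3])
    dy <- p$r * y[1:3] * (1 - S / p$K) - p$d * y[1:3] - p$h * y[1:3] * y[4]
    dxA <- p$r_A * y[4] * (1 - (p$b_A * y[4] + p$b_E * y[5]) / p$C) - y[4] * L
    dxE <- y[4] * L - p$d_E * y[5]
    list(c(dy, dxA, dxE))
  }
  ref <- deSolve::ode(s0, seq(0, 24, by = 1), f, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  mine <- trajectory_states(integrate_model(p, s0, 0, 24), seq(0, 24, by = 1))
  expect_lt(max(abs(mine - ref[, -1]) / (1 + abs(ref[, -1]))), 1e-5)
})

test_that("trajectory evaluation matches stored states and rejects out-of-span times", {
  p <- coupled_params()
  tr <- integrate_model(p, c(0.5, 0.3, 0), 0, 12)
  seg <- tr$segments[[1]]
  mid <- seq(1, length(seg$times), by = 7)
  expect_equal(trajectory_states(tr, seg$times[mid]),
               seg$states[mid, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(trajectory_states(tr, 13), "span")
  expect_error(observable_ci(tr, -1), "span")
})

test_that("step-size underflow is reported with the failure time", {
  p <- coupled_params()
  expect_error(
    integrate_model(p, c(0.5, 0.3, 0), 0, 24,
                    integrator_settings(rtol = 1e-14, atol = 1e-16,
                                        h_min = 0.05, h_max = 0.5)),
    "failed at t")
})
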