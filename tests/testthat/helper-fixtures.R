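# Shared fixtures: small parameter sets, designs and numerical helpers.

# Single-population logistic-only truth (no T-cell interaction).
growth_truth_m1 <- function() {
  model_parameters(r = 2.7, d = 2.1, a = 0.8, K = 1.8, h = 0, l = 0,
                   b_A = 0.5, b_E = 0.5, r_A = 0, d_E = 0, C = 1)
}

# Co-culture truth with known interaction rates.
killing_truth_m1 <- function(h = 2, l = 1) {
  model_parameters(r = 2.7, d = 2.1, a = 0.8, K = 1.8, h = h, l = l,
                   b_A = 0.5, b_E = 0.5, r_A = 1, d_E = 1, C = 5)
}

# Generic fully-coupled parameter set used where all terms must be active.
coupled_params <- function() {
  model_parameters(r = 2, d = 1, a = 1, K = 2, h = 0.8, l = 1,
                   b_A = 0.5, b_E = 0.5, r_A = 2, d_E = 1, C = 10)
}

noise_off <- function() noise_model(cv = 0, sd_add = 0, spike_rel = 0)

# Coarse, fast design for fitter tests.
coarse_design <- function(follow_h = 24) {
  experiment_design(sampling_min = 30, growth_h = 24, follow_h = follow_h)
}

# Composite Simpson quadrature on a uniform grid (odd number of points).
simpson <- function(x, y) {
  n <- length(x)
  if (n %% 2 == 0) { n <- n - 1; x <- x[1:n]; y <- y[1:n] }
  h <- (x[n] - x[1]) / (n - 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, by = 2)]) +
             2 * sum(y[seq(3, n - 2, by = 2)]))
}

# Analytic logistic solution y' = r y (1 - y/K), y(0) = y0 (a = 1).
logistic_exact <- function(t, r, K, y0) {
  K * y0 * exp(r * t) / (K + y0 * (exp(r * t) - 1))
}

# Draw one random parameter set uniformly inside the default search box.
random_params <- function(M = 2) {
  rg <- default_parameter_ranges()
  u <- function(key, n = 1) runif(n, rg[[key]][1], rg[[key]][2])
  model_parameters(r = u("r", M), d = u("d", M), a = u("a", M), K = u("K"),
                   h = u("h", M), l = u("l", M), b_A = u("b"), b_E = u("b"),
                   r_A = u("r_A"), d_E = u("d_E"), C = u("C"))
}
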