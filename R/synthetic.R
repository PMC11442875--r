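#' Design of a real-time cytotoxicity experiment
#'
#' Timing and layout of an impedance killing assay: cells attach and grow
#' for `growth_h` hours with impedance read every `sampling_min` minutes,
#' effector T cells are added at the treatment time at one or more E:T
#' ratios, and the plate is followed for `follow_h` more hours.
#'
#' @param sampling_min sampling interval in minutes (default 5).
#' @param growth_h attachment/growth phase duration before treatment
#'   (default 24 h).
#' @param follow_h post-treatment follow-up duration (default 72 h).
#' @param ratios E:T ratios of the effector wells (default 0.5, 1, 2).
#' @param ci0 initial cell index at seeding; the default truths reach the
#'   working range 0.5-1 CI by the treatment time.
#' @param t_treat treatment time in hours (default `growth_h`).
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(sampling_min = 5, growth_h = 24, follow_h = 72,
                              ratios = c(0.5, 1, 2), ci0 = 0.1,
                              t_treat = growth_h) {
  if (sampling_min <= 0 || growth_h <= 0 || follow_h <= 0)
    stop("durations and sampling interval must be positive")
  if (any(ratios < 0)) stop("E:T ratios must be nonnegative")
  if (ci0 <= 0) stop("ci0 must be positive")
  dt <- sampling_min / 60
  if (growth_h / dt < 2 || follow_h / dt < 2)
    stop("sampling interval too coarse: need at least 2 samples per phase")
  structure(list(sampling_min = sampling_min, growth_h = growth_h,
                 follow_h = follow_h, ratios = ratios, ci0 = ci0,
                 t_treat = t_treat),
            class = "experiment_design")
}

#' Measurement-noise model for synthetic cell-index data
#'
#' Observations are `ci_true * (1 + eps_m) + eps_a` with multiplicative
#' Gaussian noise `eps_m ~ N(0, cv)` and additive noise `eps_a ~ N(0,
#' sd_add)`; negative observations are floored at 0.  Optionally a single
#' positive spike is added on the first sample after the treatment time,
#' emulating the transient caused by removing the plate from the incubator
#' to add effector cells.
#'
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.02).
#' @param sd_add standard deviation of the additive noise in CI units
#'   (default 0.005).
#' @param spike_rel spike amplitude relative to the CI at treatment time
#'   (default 0.2; set 0 to disable).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.02, sd_add = 0.005, spike_rel = 0.2) {
  if (cv < 0 || sd_add < 0 || spike_rel < 0)
    stop("noise magnitudes must be nonnegative")
  structure(list(cv = cv, sd_add = sd_add, spike_rel = spike_rel),
            class = "noise_model")
}

# Deterministic per-well substream seed: adding a well never changes others.
well_seed <- function(seed, well) {
  (as.integer(seed) + 7919L * as.integer(well)) %% .Machine$integer.max
}

apply_noise <- function(ci_true, noise) {
  n <- length(ci_true)
  obs <- ci_true * (1 + stats::rnorm(n, 0, noise$cv)) +
    stats::rnorm(n, 0, noise$sd_add)
  pmax(obs, 0)
}

design_grid <- function(design) {
  dt <- design$sampling_min / 60
  seq(0, design$t_treat + design$follow_h, by = dt)
}

#' Generate a synthetic effector-free growth series
#'
#' Simulates cancer-only growth with [simulate_growth()], samples the
#' observable CI on the design grid and applies the measurement-noise model.
#' Deterministic under `seed`.
#'
#' @param params the generating [model_parameters()].
#' @param design an [experiment_design()].
#' @param noise a [noise_model()].
#' @param seed integer master seed.
#' @param fractions optional initial split of `ci0` across subpopulations.
#' @param settings an [integrator_settings()].
#' @return A list with elements `series` (a [ci_series()]) and `record` (a
#'   `ground_truth_record` sufficient to regenerate the series bit-exactly).
#' @export
generate_growth_series <- function(params, design = experiment_design(),
                                   noise = noise_model(), seed = 1L,
                                   fractions = NULL,
                                   settings = integrator_settings()) {
  grid <- design_grid(design)
  traj <- simulate_growth(params, design$ci0, t1 = max(grid),
                          fractions = fractions, settings = settings)
  ci_true <- observable_ci(traj, grid)
  obs <- with_well_rng(seed, 0L, apply_noise(ci_true, noise))
  series <- ci_series(grid, obs, condition = "no_effector", et_ratio = 0,
                      t_treat = design$t_treat)
  list(series = series,
       record = ground_truth_record(params, design, noise, seed,
                                    fractions = fractions, kind = "growth"))
}

with_well_rng <- function(seed, well, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(well_seed(seed, well))
  expr
}

ground_truth_record <- function(params, design, noise, seed, fractions, kind) {
  structure(list(params = params, design = design, noise = noise,
                 seed = as.integer(seed), fractions = fractions, kind = kind),
            class = "ground_truth_record")
}

#' Generate a synthetic killing panel
#'
#' One matched no-effector well plus one effector well per E:T ratio, all
#' generated from the same parameters.  Each effector well is a
#' [simulate_coculture()] run with `xA0 = ratio * CI(t_treat)` (noise-free
#' model CI).  Each well draws its noise from its own seed substream, so
#' adding a ratio never changes the other wells.  The optional spike
#' artifact is added to every well on the first sample after treatment.
#'
#' @inheritParams generate_growth_series
#' @return A list with elements `panel` (list of [ci_series()], the
#'   no-effector well first) and `record`.
#' @export
generate_killing_panel <- function(params, design = experiment_design(),
                                   noise = noise_model(), seed = 1L,
                                   fractions = NULL,
                                   settings = integrator_settings()) {
  if (length(design$ratios) < 1L) stop("design must contain at least one E:T ratio")
  grid <- design_grid(design)
  t_treat <- design$t_treat
  spike_at <- which(grid > t_treat)[1]

  growth <- simulate_growth(params, design$ci0, t1 = max(grid),
                            fractions = fractions, settings = settings)
  ci_treat <- observable_ci(growth, t_treat)
  spike <- noise$spike_rel * ci_treat

  make_well <- function(ci_true, condition, ratio, well_idx) {
    obs <- with_well_rng(seed, well_idx, apply_noise(ci_true, noise))
    if (!is.na(spike_at) && spike > 0) obs[spike_at] <- obs[spike_at] + spike
    ci_series(grid, obs, condition = condition, et_ratio = ratio,
              t_treat = t_treat)
  }

  panel <- vector("list", 1L + length(design$ratios))
  panel[[1]] <- make_well(observable_ci(growth, grid), "no_effector", 0, 0L)
  for (k in seq_along(design$ratios)) {
    ratio <- design$ratios[k]
    traj <- simulate_coculture(params, design$ci0, t_treat = t_treat,
                               t_end = max(grid), xA0 = ratio * ci_treat,
                               fractions = fractions, settings = settings)
    panel[[k + 1L]] <- make_well(observable_ci(traj, grid), "effector",
                                 ratio, k)
  }
  list(panel = panel,
       record = ground_truth_record(params, design, noise, seed,
                                    fractions = fractions, kind = "killing_panel"))
}

#' Regenerate a dataset from its ground-truth record
#'
#' @param record a `ground_truth_record` produced by the generators.
#' @param settings an [integrator_settings()].
#' @return The same structure the original generator returned.
#' @export
regenerate <- function(record, settings = integrator_settings()) {
  stopifnot(inherits(record, "ground_truth_record"))
  if (record$kind == "growth") {
    generate_growth_series(record$params, record$design, record$noise,
                           record$seed, fractions = record$fractions,
                           settings = settings)
  } else {
    generate_killing_panel(record$params, record$design, record$noise,
                           record$seed, fractions = record$fractions,
                           settings = settings)
  }
}

#' Built-in benchmark suite of synthetic datasets
#'
#' A fixed small collection of datasets with known ground truth covering the
#' regimes the pipeline must handle: (i) single-population growth; (ii)
#' three-population growth whose noise-free curve shows multiple growth
#' phases; (iii) co-culture panels for a "sensitive" truth (high cytolysis
#' rate; finite KT80) and a "resistant" truth (low cytolysis rate; KT80 not
#' detected at any default ratio), echoing the contrast between
#' FASN-knockout and parental cancer cells.
#'
#' @param seed integer master seed; the suite regenerates bit-exactly from it.
#' @param design an [experiment_design()] shared by all cases.
#' @return A named list of cases, each a generator result (with `record`).
#' @export
make_benchmark_suite <- function(seed = 1L, design = experiment_design()) {
  truth_m1 <- model_parameters(r = 2.7, d = 2.1, a = 0.8, K = 1.8,
                               h = 0, l = 0, b_A = 0.5, b_E = 0.5,
                               r_A = 0, d_E = 0, C = 1)
  # three subpopulations with staggered saturation levels K*(1 - d_i/r_i)
  truth_m3 <- model_parameters(
    r = c(6, 1.5, 0.4), d = c(3, 0.45, 0.04), a = c(1, 1, 1), K = 2,
    h = c(0, 0, 0), l = c(0, 0, 0), b_A = 0.5, b_E = 0.5,
    r_A = 0, d_E = 0, C = 1)
  truth_sensitive <- model_parameters(
    r = 2.7, d = 2.1, a = 0.8, K = 1.8, h = 4, l = 1,
    b_A = 0.5, b_E = 0.5, r_A = 1, d_E = 1, C = 5)
  truth_resistant <- model_parameters(
    r = 2.7, d = 2.1, a = 0.8, K = 1.8, h = 1, l = 3,
    b_A = 0.5, b_E = 0.5, r_A = 0.5, d_E = 1, C = 5)
  list(
    growth_m1 = generate_growth_series(truth_m1, design, seed = well_seed(seed, 11L)),
    growth_m3 = generate_growth_series(truth_m3, design, seed = well_seed(seed, 22L)),
    coculture_sensitive = generate_killing_panel(truth_sensitive, design,
                                                 seed = well_seed(seed, 33L)),
    coculture_resistant = generate_killing_panel(truth_resistant, design,
                                                 seed = well_seed(seed, 44L)))
}
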