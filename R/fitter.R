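#' Configuration of the macroevolutionary fitting algorithm
#'
#' Each generation the population of parameter vectors is ranked by its
#' least-squares distance to the data; the best 25% survive unchanged, a
#' further 25% are small multiplicative perturbations of the survivors
#' (`p' = p * (1 + beta)` with `beta ~ U(-beta_max, beta_max)` drawn
#' independently per component), and the remaining 50% are resampled
#' uniformly within the parameter ranges.  The reference configuration for
#' real 5-minute assay data is `N = 1000` with `tau_max = 1e4` for the
#' growth stage and `1e3` for the interaction stage, retaining the best 250
#' vectors.
#'
#' @param N population size (default 1000).
#' @param elite_frac fraction kept unchanged each generation (default 0.25).
#' @param perturb_frac fraction added as perturbed elite copies (default
#'   0.25); the remaining fraction is resampled uniformly.
#' @param beta_max half-width of the uniform perturbation (default 0.02).
#' @param tau_max number of generations to run.
#' @param top_k number of best vectors retained in the result (default 250,
#'   capped at N).
#' @param seed integer seed making the run reproducible.
#' @return A list of class `ma_config`.
#' @export
ma_config <- function(N = 1000L, elite_frac = 0.25, perturb_frac = 0.25,
                      beta_max = 0.02, tau_max = 1000L, top_k = 250L,
                      seed = 1L) {
  N <- as.integer(N)
  if (N < 4L) stop("population size N must be at least 4")
  if (elite_frac < 0 || perturb_frac < 0 || elite_frac + perturb_frac > 1)
    stop("elite and perturbed fractions must be nonnegative and sum to <= 1")
  if (tau_max < 0) stop("tau_max must be >= 0")
  top_k <- min(as.integer(top_k), N)
  structure(list(N = N, elite_frac = elite_frac, perturb_frac = perturb_frac,
                 random_frac = 1 - elite_frac - perturb_frac,
                 beta_max = beta_max, tau_max = as.integer(tau_max),
                 top_k = top_k, seed = as.integer(seed)),
            class = "ma_config")
}

# ---- free-parameter encoding -------------------------------------------------

# A free spec is a data frame (name, lo, hi) describing the flat encoding of
# the stage's free components; decode() rebuilds full model parameters from a
# flat vector plus the stage's fixed template.
free_spec_growth <- function(M, ranges) {
  nm <- c(paste0("r_", seq_len(M)), paste0("d_", seq_len(M)),
          paste0("a_", seq_len(M)), "K")
  bounds <- t(vapply(nm, function(x) range_for(ranges, x), c(0, 0)))
  data.frame(name = nm, lo = bounds[, 1], hi = bounds[, 2])
}

free_spec_interaction <- function(M, ranges) {
  nm <- c(paste0("h_", seq_len(M)), paste0("l_", seq_len(M)),
          "b_A", "b_E", "r_A", "d_E", "C")
  bounds <- t(vapply(nm, function(x) range_for(ranges, x), c(0, 0)))
  data.frame(name = nm, lo = bounds[, 1], hi = bounds[, 2])
}

decode_vector <- function(vec, free, template) {
  p <- unclass(template)
  M <- p$M
  for (j in seq_along(free$name)) {
    nm <- free$name[j]
    if (grepl("_[0-9]+$", nm) && !nm %in% c("b_A", "b_E", "r_A", "d_E")) {
      base <- sub("_[0-9]+$", "", nm)
      i <- as.integer(sub("^.*_", "", nm))
      p[[base]][i] <- vec[j]
    } else {
      p[[nm]] <- vec[j]
    }
  }
  class(p) <- "model_parameters"
  p
}

encode_params <- function(params, free) {
  vapply(seq_along(free$name), function(j) {
    nm <- free$name[j]
    if (grepl("_[0-9]+$", nm) && !nm %in% c("b_A", "b_E", "r_A", "d_E")) {
      base <- sub("_[0-9]+$", "", nm)
      i <- as.integer(sub("^.*_", "", nm))
      params[[base]][i]
    } else params[[nm]]
  }, 1.0)
}

# ---- dataset preparation and least squares ----------------------------------

# Precompute per-series simulation inputs once: output grid, model initial CI,
# treatment time and absolute x_A(0) (= et_ratio x observed CI at the last
# sample at or before t_treat).
prepare_dataset <- function(dataset) {
  if (inherits(dataset, "ci_series")) dataset <- list(dataset)
  lapply(dataset, function(s) {
    stopifnot(inherits(s, "ci_series"))
    coculture <- s$et_ratio > 0
    if (coculture && !is.finite(s$t_treat))
      stop("effector series lacks a treatment time")
    ci0 <- if (!is.null(s$ci0)) s$ci0 else s$ci[1]
    xA0 <- 0
    t_treat <- NA_real_
    if (coculture) {
      t_treat <- s$t_treat
      idx <- which(s$times <= t_treat)
      if (length(idx) == 0L) stop("no sample at or before the treatment time")
      xA0 <- s$et_ratio * s$ci[max(idx)]
    }
    list(times = s$times, ci = s$ci, t0 = s$times[1], ci0 = ci0,
         t_treat = t_treat, xA0 = xA0)
  })
}

ls_prepared <- function(theta, M, prep, fractions, settings) {
  total <- 0
  for (d in prep) {
    y0 <- d$ci0 * fractions
    res <- cpp_ci_at(theta, y0, d$t0, d$t_treat, d$xA0, d$times,
                     settings$rtol, settings$atol, settings$h_init,
                     settings$h_min, settings$h_max, settings$safety,
                     settings$max_steps)
    if (!res$ok) return(Inf)
    total <- total + sum((res$ci - d$ci)^2)
  }
  total
}

#' Least-squares distance between model and data
#'
#' Simulates each series' condition (growth-only, or co-culture with the
#' active T-cell level jumping at the series' treatment time), evaluates the
#' observable CI at the data timestamps and returns the sum of squared
#' residuals over all series and timestamps (CI^2 units).  An integration
#' failure makes the vector maximally unfit (score `Inf`).
#'
#' @param params a [model_parameters()] object.
#' @param dataset a [ci_series()] or list of them.  Effector wells
#'   (`et_ratio > 0`) are simulated as co-cultures with
#'   `xA0 = et_ratio * CI` observed at the last sample at or before the
#'   treatment time; the model's initial CI is each series' first
#'   observation unless the series carries an explicit `ci0`.
#' @param fractions optional initial split across subpopulations (equal by
#'   default).
#' @param settings an [integrator_settings()].
#' @return The least-squares score (nonnegative scalar, possibly `Inf`).
#' @export
least_squares <- function(params, dataset, fractions = NULL,
                          settings = integrator_settings()) {
  stopifnot(inherits(params, "model_parameters"))
  prep <- prepare_dataset(dataset)
  if (is.null(fractions)) fractions <- rep(1 / params$M, params$M)
  ls_prepared(as_theta(params), params$M, prep, fractions, settings)
}

# ---- population mechanics ----------------------------------------------------

#' Draw the initial population of parameter vectors
#'
#' Each of the N vectors has every free component drawn independently and
#' uniformly within its search range.  Reproducible under the config seed
#' (call inside [run_ma()] or after `set.seed()`).
#'
#' @param free a free-component spec as built by the stage functions
#'   (data frame with columns `name`, `lo`, `hi`).
#' @param config an [ma_config()].
#' @return An N x P matrix with named columns, one row per vector.
#' @keywords internal
#' @export
init_population <- function(free, config) {
  P <- nrow(free)
  pop <- matrix(stats::runif(config$N * P), config$N, P)
  pop <- sweep(pop, 2, free$hi - free$lo, "*")
  pop <- sweep(pop, 2, free$lo, "+")
  colnames(pop) <- free$name
  pop
}

perturb_vectors <- function(mat, free, beta_max) {
  beta <- matrix(stats::runif(length(mat), -beta_max, beta_max),
                 nrow(mat), ncol(mat))
  out <- mat * (1 + beta)
  # clamp to the search box
  out <- pmin(pmax(out, matrix(free$lo, nrow(mat), ncol(mat), byrow = TRUE)),
              matrix(free$hi, nrow(mat), ncol(mat), byrow = TRUE))
  out
}

#' One generation of the macroevolutionary algorithm
#'
#' Given the current population and its scores (lowest score = highest
#' fitness), builds the next generation: `floor(N * elite_frac)` unchanged
#' elites, the same number of perturbed elite copies (components multiplied
#' by `1 + beta`, clamped to bounds), and uniform redraws for the rest.
#' Elite scores are carried forward (the score is deterministic); all other
#' scores are `NA` until evaluated.
#'
#' @param pop N x P population matrix.
#' @param ls numeric vector of N least-squares scores for `pop`.
#' @param free the free-component spec.
#' @param config an [ma_config()].
#' @return A list with the new `pop` matrix and its partially-known `ls`.
#' @keywords internal
#' @export
evolve_generation <- function(pop, ls, free, config) {
  N <- config$N
  n_elite <- floor(N * config$elite_frac)
  n_pert <- floor(N * config$perturb_frac)
  n_rand <- N - n_elite - n_pert
  ord <- order(ls)  # stable: ties keep insertion order
  elite_idx <- ord[seq_len(n_elite)]
  elites <- pop[elite_idx, , drop = FALSE]
  pert_src <- ((seq_len(n_pert) - 1L) %% n_elite) + 1L  # recycle if needed
  pert <- perturb_vectors(elites[pert_src, , drop = FALSE], free,
                          config$beta_max)
  fresh <- init_population(free, modifyList(config, list(N = n_rand)))
  new_pop <- rbind(elites, pert, fresh)
  colnames(new_pop) <- free$name
  new_ls <- c(ls[elite_idx], rep(NA_real_, n_pert + n_rand))
  list(pop = new_pop, ls = new_ls)
}

#' Run the macroevolutionary fit
#'
#' Minimises the least-squares distance between the simulated observable CI
#' and the data over the free components, holding the remaining model fields
#' at the values in `template`.  The best score never increases across
#' generations (elitism), and identical inputs and seed give identical
#' results.
#'
#' @param dataset a [ci_series()] or list of them (see [least_squares()]).
#' @param free free-component spec (data frame `name`, `lo`, `hi`).
#' @param template a [model_parameters()] object supplying the fixed
#'   components.
#' @param config an [ma_config()].
#' @param fractions optional initial CI split across subpopulations.
#' @param settings an [integrator_settings()].
#' @param stage label stored in the result.
#' @return An object of class `ma_fit`: `best` (decoded
#'   [model_parameters()]), `best_vector`, `best_ls`, `top_k` (matrix of the
#'   retained best vectors with attribute `ls`), `history` (best score per
#'   generation, length `tau_max + 1`, non-increasing), `free`, `config`,
#'   `stage`.
#' @export
run_ma <- function(dataset, free, template, config = ma_config(),
                   fractions = NULL, settings = integrator_settings(),
                   stage = "custom") {
  stopifnot(inherits(template, "model_parameters"))
  prep <- prepare_dataset(dataset)
  M <- template$M
  if (is.null(fractions)) fractions <- rep(1 / M, M)
  theta0 <- as_theta(template)
  # index of each free component inside the flat theta encoding
  theta_idx <- theta_index(free$name, M)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  eval_pop <- function(pop, ls) {
    todo <- which(is.na(ls))
    for (i in todo) {
      th <- theta0
      th[theta_idx] <- pop[i, ]
      ls[i] <- ls_prepared(th, M, prep, fractions, settings)
    }
    ls
  }

  pop <- init_population(free, config)
  ls <- eval_pop(pop, rep(NA_real_, config$N))
  history <- numeric(config$tau_max + 1L)
  history[1] <- min(ls)
  if (config$tau_max > 0) {
    for (g in seq_len(config$tau_max)) {
      nxt <- evolve_generation(pop, ls, free, config)
      pop <- nxt$pop
      ls <- eval_pop(pop, nxt$ls)
      history[g + 1L] <- min(ls)
    }
  }
  ord <- order(ls)
  top <- ord[seq_len(config$top_k)]
  best_vec <- pop[ord[1], ]
  fit <- structure(
    list(best = decode_vector(best_vec, free, template),
         best_vector = stats::setNames(best_vec, free$name),
         best_ls = ls[ord[1]],
         top_k = structure(pop[top, , drop = FALSE], ls = ls[top]),
         history = history, free = free, config = config,
         fractions = fractions, stage = stage),
    class = "ma_fit")
  fit
}

theta_index <- function(names, M) {
  # theta layout: [M, r(M), d(M), a(M), K, h(M), l(M), b_A, b_E, r_A, d_E, C]
  base_at <- c(r = 1, d = 1 + M, a = 1 + 2 * M)
  scalar_at <- c(K = 1 + 3 * M, b_A = 2 + 5 * M, b_E = 3 + 5 * M,
                 r_A = 4 + 5 * M, d_E = 5 + 5 * M, C = 6 + 5 * M)
  vec_at <- c(h = 2 + 3 * M, l = 2 + 4 * M)
  vapply(names, function(nm) {
    if (nm %in% names(scalar_at)) return(scalar_at[[nm]] + 1)  # +1: theta[1] = M
    base <- sub("_[0-9]+$", "", nm)
    i <- as.integer(sub("^.*_", "", nm))
    if (base %in% names(base_at)) return(base_at[[base]] + i)
    if (base %in% names(vec_at)) return(vec_at[[base]] + i)
    stop(sprintf("unknown free component '%s'", nm))
  }, 1.0)
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("Macroevolutionary fit (stage '%s'): N = %d, tau = %d, seed = %d\n",
              x$stage, x$config$N, x$config$tau_max, x$config$seed))
  cat(sprintf("  best LS = %.6g over %d free components; top-%d retained\n",
              x$best_ls, nrow(x$free), nrow(x$top_k)))
  invisible(x)
}

#' Ensemble spread of the retained top-k vectors
#'
#' Component-wise median and interquartile range over the retained best
#' vectors, a summary of how tightly the data pin each free component.
#'
#' @param fit an `ma_fit`.
#' @return A data frame with columns `name`, `median`, `q25`, `q75`.
#' @export
top_k_summary <- function(fit) {
  stopifnot(inherits(fit, "ma_fit"))
  q <- apply(fit$top_k, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE)
  data.frame(name = colnames(fit$top_k), median = q[2, ], q25 = q[1, ],
             q75 = q[3, ], row.names = NULL)
}

# ---- two-stage protocol ------------------------------------------------------

#' Stage 1: fit the intrinsic growth parameters
#'
#' Estimates `r_1..r_M`, `d_1..d_M`, `a_1..a_M` and `K` from effector-free
#' wells using the cancer-only model (no T-cell equations).  The carrying
#' capacity is fitted here and frozen in stage 2, since the growth model
#' cannot be simulated without it.  Reference budget for real data:
#' `tau_max = 1e4`.
#'
#' @param growth_series a [ci_series()] or list of them; all must be
#'   effector-free (`et_ratio == 0`).
#' @param ranges a [parameter_ranges()] object.
#' @param M number of cancer subpopulations (default 3, the minimum giving a
#'   good fit to multi-phase growth curves).
#' @param config an [ma_config()]; default `tau_max = 1e4`, `top_k = 250`.
#' @param fractions,settings see [run_ma()].
#' @return An `ma_fit` tagged `"growth"`.
#' @export
fit_growth_stage <- function(growth_series,
                             ranges = default_parameter_ranges(), M = 3L,
                             config = ma_config(tau_max = 1e4),
                             fractions = NULL,
                             settings = integrator_settings()) {
  if (inherits(growth_series, "ci_series")) growth_series <- list(growth_series)
  for (s in growth_series)
    if (s$et_ratio > 0)
      stop("fit_growth_stage() accepts only effector-free series (et_ratio == 0)")
  free <- free_spec_growth(M, ranges)
  template <- model_parameters(r = rep(1, M), d = rep(0, M), a = rep(1, M),
                               K = 1, h = rep(0, M), l = rep(0, M),
                               b_A = 0.5, b_E = 0.5, r_A = 0, d_E = 0, C = 1)
  run_ma(growth_series, free, template, config = config,
         fractions = fractions, settings = settings, stage = "growth")
}

#' Stage 2: fit the T-cell interaction parameters
#'
#' With the intrinsic growth parameters frozen at the stage-1 estimates,
#' fits `h_1..h_M`, `l_1..l_M`, `b_A`, `b_E`, `r_A`, `d_E` and `C` to
#' co-culture wells, jointly across all E:T ratios in the panel.  Reference
#' budget for real data: `tau_max = 1e3`.
#'
#' @param panel list of [ci_series()]: effector wells (each with a
#'   treatment time) and optionally the matched no-effector well, which is
#'   included in the objective.
#' @param intrinsic an `ma_fit` from [fit_growth_stage()] or a
#'   [model_parameters()] object supplying `r`, `d`, `a`, `K`.
#' @param ranges a [parameter_ranges()] object.
#' @param config an [ma_config()]; default `tau_max = 1e3`.
#' @param fractions,settings see [run_ma()].
#' @return An `ma_fit` tagged `"interaction"`.
#' @export
fit_interaction_stage <- function(panel, intrinsic,
                                  ranges = default_parameter_ranges(),
                                  config = ma_config(tau_max = 1e3),
                                  fractions = NULL,
                                  settings = integrator_settings()) {
  if (inherits(panel, "ci_series")) panel <- list(panel)
  if (inherits(intrinsic, "ma_fit")) intrinsic <- intrinsic$best
  stopifnot(inherits(intrinsic, "model_parameters"))
  eff <- Filter(function(s) s$et_ratio > 0, panel)
  if (length(eff) == 0L) stop("panel contains no effector series")
  for (s in eff)
    if (!is.finite(s$t_treat))
      stop("effector series lacks a treatment time in its metadata")
  M <- intrinsic$M
  free <- free_spec_interaction(M, ranges)
  template <- model_parameters(r = intrinsic$r, d = intrinsic$d,
                               a = intrinsic$a, K = intrinsic$K,
                               h = rep(0, M), l = rep(0, M),
                               b_A = 0.5, b_E = 0.5, r_A = 0, d_E = 0, C = 1)
  run_ma(panel, free, template, config = config, fractions = fractions,
         settings = settings, stage = "interaction")
}

#' Serialize a fit result to JSON
#'
#' Records the config, seed, stage, best vector and score, per-generation
#' best-score history and the retained top-k table.
#'
#' @param fit an `ma_fit`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "ma_fit"))
  obj <- list(stage = fit$stage,
              config = unclass(fit$config),
              best = unclass(fit$best),
              best_vector = as.list(fit$best_vector),
              best_ls = fit$best_ls,
              history = fit$history,
              top_k = apply(fit$top_k, 1, as.list),
              top_k_ls = as.numeric(attr(fit$top_k, "ls")))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
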