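#' Configuration for a full simulate/metrics/fit analysis
#'
#' Either `input` (a CSV readable by [read_series_csv()]) or `truth` (a
#' [model_parameters()] object from which a synthetic panel is generated)
#' must be supplied.  All stochastic stages derive their seeds from the
#' single master seed, and the merged effective configuration is written
#' next to the outputs, so every artifact is reproducible from the config
#' alone.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for every stochastic stage.
#' @param input optional path to an input series CSV.
#' @param truth optional generating [model_parameters()] for synthetic mode.
#' @param design an [experiment_design()].
#' @param noise a [noise_model()] (synthetic mode).
#' @param ranges a [parameter_ranges()] object.
#' @param M number of cancer subpopulations fitted in stage 1.
#' @param ma_growth,ma_interaction [ma_config()] objects for the two stages.
#' @param thresholds KT thresholds in percent.
#' @param settings an [integrator_settings()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, input = NULL, truth = NULL,
                       design = experiment_design(), noise = noise_model(),
                       ranges = default_parameter_ranges(), M = 3L,
                       ma_growth = ma_config(tau_max = 1e4),
                       ma_interaction = ma_config(tau_max = 1e3),
                       thresholds = c(20, 50, 60, 80),
                       settings = integrator_settings()) {
  if (is.null(input) && is.null(truth))
    stop("either an input CSV or a generating truth must be supplied")
  if (!is.null(input) && !file.exists(input))
    stop(sprintf("input file not found: %s", input))
  structure(list(out_dir = out_dir, seed = as.integer(seed), input = input,
                 truth = truth, design = design, noise = noise,
                 ranges = ranges, M = as.integer(M), ma_growth = ma_growth,
                 ma_interaction = ma_interaction, thresholds = thresholds,
                 settings = settings),
            class = "run_config")
}

# Order-sensitive checksum of the serialized effective config.  The output
# directory is excluded: the checksum identifies the analysis, not where its
# artifacts happen to be stored.
config_checksum <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                        auto_unbox = TRUE, digits = 10, force = TRUE)
  b <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(b * (seq_along(b) %% 97 + 1)) %% 2^31)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete workflow: obtain the cell-index panel (read
#' from CSV or generated from a known truth), compute the killing-time
#' table, fit the intrinsic growth parameters on the no-effector well
#' (stage 1), fit the interaction parameters on the effector wells with the
#' intrinsic set frozen (stage 2, skipped if there are no effector wells),
#' and write all artifacts to the output directory:
#' `effective_config.json`, `stage1_fit.json`, `stage2_fit.json`,
#' `kt_table.csv`, `history_growth.csv`, `history_interaction.csv`,
#' `panel.csv` and a plain-text `summary.txt`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the fits, the KT table and the paths of
#'   the written artifacts.
#' @export
run_full_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  checksum <- config_checksum(config)
  say("run checksum %s, master seed %d", checksum, config$seed)

  if (!is.null(config$input)) {
    panel <- read_series_csv(config$input, t_treat = config$design$t_treat)
    say("stage input: read %d series from %s", length(panel), config$input)
  } else {
    say("stage simulate: generating synthetic panel (seed %d)", config$seed)
    gen <- generate_killing_panel(config$truth, config$design, config$noise,
                                  seed = config$seed,
                                  settings = config$settings)
    panel <- gen$panel
  }
  paths <- list(config = file.path(config$out_dir, "effective_config.json"),
                panel = file.path(config$out_dir, "panel.csv"),
                kt = file.path(config$out_dir, "kt_table.csv"),
                stage1 = file.path(config$out_dir, "stage1_fit.json"),
                stage2 = file.path(config$out_dir, "stage2_fit.json"),
                hist1 = file.path(config$out_dir, "history_growth.csv"),
                hist2 = file.path(config$out_dir, "history_interaction.csv"),
                summary = file.path(config$out_dir, "summary.txt"))
  eff <- rapply(unclass(config), unclass, how = "replace")
  eff$checksum <- checksum
  writeLines(as.character(jsonlite::toJSON(eff, auto_unbox = TRUE,
                                           digits = 10, force = TRUE)),
             paths$config)
  write_series_csv(panel, paths$panel)

  growth <- Filter(function(s) s$et_ratio == 0, panel)
  effectors <- Filter(function(s) s$et_ratio > 0, panel)
  if (length(growth) == 0L) stop("stage metrics: no no-effector well in the panel")

  kt <- NULL
  if (length(effectors) > 0L) {
    say("stage metrics: killing-time table for %d effector well(s)",
        length(effectors))
    kt <- killing_time_table(panel, thresholds = config$thresholds)
    write_kt_table(kt, paths$kt)
  }

  say("stage fit-growth: M = %d, N = %d, tau = %d", config$M,
      config$ma_growth$N, config$ma_growth$tau_max)
  cfg1 <- config$ma_growth
  cfg1$seed <- config$seed
  fit1 <- fit_growth_stage(growth, ranges = config$ranges, M = config$M,
                           config = cfg1, settings = config$settings)
  fit_to_json(fit1, paths$stage1)
  utils::write.csv(data.frame(generation = seq_along(fit1$history) - 1L,
                              best_ls = fit1$history),
                   paths$hist1, row.names = FALSE)

  fit2 <- NULL
  if (length(effectors) > 0L) {
    say("stage fit-killing: N = %d, tau = %d", config$ma_interaction$N,
        config$ma_interaction$tau_max)
    cfg2 <- config$ma_interaction
    cfg2$seed <- config$seed + 1L
    fit2 <- fit_interaction_stage(panel, fit1, ranges = config$ranges,
                                  config = cfg2, settings = config$settings)
    fit_to_json(fit2, paths$stage2)
    utils::write.csv(data.frame(generation = seq_along(fit2$history) - 1L,
                                best_ls = fit2$history),
                     paths$hist2, row.names = FALSE)
  }

  writeLines(summary_lines(config, checksum, fit1, fit2, kt), paths$summary)
  say("done; artifacts in %s", config$out_dir)
  invisible(list(fit_growth = fit1, fit_interaction = fit2, kt_table = kt,
                 panel = panel, paths = paths, checksum = checksum))
}

summary_lines <- function(config, checksum, fit1, fit2, kt) {
  fmt_fit <- function(fit) {
    sm <- top_k_summary(fit)
    c(sprintf("  best LS: %.6g (seed %d, N = %d, tau = %d)", fit$best_ls,
              fit$config$seed, fit$config$N, fit$config$tau_max),
      sprintf("  top-%d ensemble spread:", nrow(fit$top_k)),
      sprintf("    %-6s median %10.4g  IQR [%.4g, %.4g]", sm$name, sm$median,
              sm$q25, sm$q75))
  }
  out <- c("Tumor/T-cell impedance analysis summary",
           sprintf("config checksum: %s   master seed: %d", checksum,
                   config$seed),
           "", "Stage 1 (intrinsic growth parameters):", fmt_fit(fit1))
  if (!is.null(fit2))
    out <- c(out, "", "Stage 2 (T-cell interaction parameters):",
             fmt_fit(fit2))
  if (!is.null(kt)) {
    out <- c(out, "", "Killing-time table (h since treatment; ND = not detected):",
             sprintf("  E:T %4g  KT%-3g: %s", kt$et_ratio, kt$threshold_pct,
                     ifelse(kt$detected, sprintf("%.2f h", kt$kt_h), "ND")))
  }
  out
}
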