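#' Default analysis configuration
#'
#' Configuration list for [run_pipeline()], overridable via YAML or named
#' arguments. With no data paths the pipeline analyses the synthetic
#' descriptive challenge.
#'
#' @param ... Named overrides of the defaults.
#' @return A configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    inputs_csv = NULL, observations_csv = NULL, # optional measured data
    challenge = list(),       # overrides for challenge_spec()
    input_noise_seed = NULL,  # NULL = noiseless synthetic traces
    obs_noise_seed = NULL,
    sweep_values = c(-0.05, 0, 0.05),
    avr = 0.25,
    baseline_window = c(0, 100),
    plateau_window = c(300, 400),
    regimes = c("supply", "demand"),
    target_sets = list(oxCCO = "oxCCO",
                       TOI_CBF = c("TOI", "dCBF_pct"),
                       all = c("oxCCO", "TOI", "dCBF_pct")),
    repeats = 20,
    ga = list(pop_size = 40, generations = 60),
    polish = TRUE,
    out_dir = NULL,           # NULL = no files written
    plots = TRUE
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  modifyList(cfg, overrides)
}

#' Run the full hypercapnia analysis pipeline
#'
#' Orchestrates the complete analysis on measured or synthetic data:
#' (1) data preparation, (2) the unoptimized forward simulation,
#' (3) supply/demand parameter sweeps, (4) the modified-Fick CMRO2
#' comparator, (5) repeated genetic-algorithm fits for both regimes crossed
#' with the three target sets, and (6) a summary report with a verdict on
#' which regime reconciles the oxCCO signal with the Fick CMRO2 estimate.
#' The supply regime "reconciles" if its all-signal fit matches the observed
#' oxCCO sign and its modelled CMRO2 change agrees in sign with the Fick
#' estimate; same rule for demand.
#'
#' @param config A [pipeline_config()] list, or the path of a YAML file with
#'   the same fields.
#' @return An object of class `bc_report`: the stage outputs (`inputs`,
#'   `observations`, `unoptimized`, `sweeps`, `fick`, `fits`), the `summary`
#'   table (one row per regime x target set), the `verdict` string and the
#'   written file `paths`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(
#'   repeats = 2, ga = list(pop_size = 12, generations = 6)))
#' rep$verdict
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  cfg <- pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  message("stage data: preparing input and observation traces")
  spec <- stage("data", do.call(challenge_spec, cfg$challenge))
  inputs <- stage("data", {
    if (!is.null(cfg$inputs_csv)) read_trace(cfg$inputs_csv, "inputs")
    else make_inputs(spec, seed = cfg$input_noise_seed)
  })
  observations <- stage("data", {
    if (!is.null(cfg$observations_csv)) {
      read_trace(cfg$observations_csv, "observations")
    } else {
      make_observations(inputs, mode = "descriptive", spec = spec,
                        seed = cfg$obs_noise_seed)
    }
  })

  message("stage unoptimized: forward simulation with default parameters")
  p0 <- bc_params()
  unopt <- stage("unoptimized", bc_simulate(inputs, p0))

  message("stage sweeps: supps and uf in {", paste(cfg$sweep_values, collapse = ", "), "}")
  sweeps <- stage("sweeps", purrr::map_dfr(c("supps", "uf"), function(gain) {
    purrr::map_dfr(cfg$sweep_values, function(v) {
      sim <- bc_simulate(inputs, do.call(bc_params, setNames(list(v), gain)))
      pc <- plateau_change(sim, c("oxCCO", "CMRO2", "Dp", "NADNADHrat",
                                  "dCBF_pct", "TOI"),
                           plateau = cfg$plateau_window,
                           baseline = cfg$baseline_window)
      dplyr::mutate(pc, gain = gain, value = v, .before = 1)
    })
  }))

  message("stage fick: modified-Fick CMRO2 from the observations")
  fick <- stage("fick", {
    d <- dplyr::inner_join(observations,
                           dplyr::select(inputs, "t", "SpO2"), by = "t")
    fick_cmro2(d, avr = cfg$avr, baseline_window = cfg$baseline_window)
  })
  fick_plateau <- plateau_change(fick, "dCMRO2_pct",
                                 plateau = cfg$plateau_window,
                                 baseline = cfg$baseline_window)$plateau

  ga <- do.call(ga_control, cfg$ga)
  combos <- tidyr::expand_grid(regime = cfg$regimes,
                               set_name = names(cfg$target_sets))
  message("stage fits: ", nrow(combos), " regime x target-set optimizations, ",
          cfg$repeats, " repeats each")
  fit_seed_base <- cfg$seed
  fits <- stage("fits", purrr::pmap(combos, function(regime, set_name) {
    i <- which(combos$regime == regime & combos$set_name == set_name)
    repeat_fits(observations, inputs, regime,
                target_set = cfg$target_sets[[set_name]],
                ga = ga, seed = fit_seed_base + 1000 * i,
                repeats = cfg$repeats, polish = cfg$polish)
  }))
  names(fits) <- paste(combos$regime, combos$set_name, sep = ".")

  summary <- purrr::map_dfr(seq_along(fits), function(i) {
    rf <- fits[[i]]
    g <- glance(rf$best)
    stats <- rf$stats
    tibble(
      regime = combos$regime[i], target_set = combos$set_name[i],
      cost = g$total_cost,
      gain_mean = stats$mean[1], gain_sd = stats$sd[1],
      oxCCO_plateau = g$oxCCO_plateau,
      dCMRO2_model_pct = g$dCMRO2_pct,
      dCMRO2_fick_pct = fick_plateau
    )
  })

  obs_oxcco <- plateau_change(observations, "oxCCO",
                              plateau = cfg$plateau_window,
                              baseline = cfg$baseline_window)$change
  reconciles <- function(regime) {
    row <- summary[summary$regime == regime & summary$target_set == "all", ]
    nrow(row) == 1 &&
      sign(row$oxCCO_plateau) == sign(obs_oxcco) &&
      sign(row$dCMRO2_model_pct) == sign(row$dCMRO2_fick_pct)
  }
  ok <- vapply(cfg$regimes, reconciles, logical(1))
  verdict <- if (any(ok)) paste(cfg$regimes[ok], collapse = "+") else "none"

  report <- structure(list(
    config = cfg, challenge = spec,
    inputs = inputs, observations = observations,
    unoptimized = unopt, sweeps = sweeps, fick = fick,
    fick_plateau = fick_plateau, fits = fits,
    summary = summary, verdict = verdict, paths = character(0)
  ), class = "bc_report")

  if (!is.null(cfg$out_dir)) {
    report$paths <- bc_write_report(report, cfg$out_dir, cfg$plots)
  }
  report
}

bc_write_report <- function(report, out_dir, plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    inputs = file.path(out_dir, "inputs.csv"),
    observations = file.path(out_dir, "observations.csv"),
    unoptimized = file.path(out_dir, "unoptimized.csv"),
    sweeps = file.path(out_dir, "sweeps.csv"),
    fick = file.path(out_dir, "fick.csv"),
    summary = file.path(out_dir, "summary.csv")
  )
  write_trace(report$inputs, paths["inputs"])
  write_trace(report$observations, paths["observations"])
  readr::write_csv(report$unoptimized, paths[["unoptimized"]], progress = FALSE)
  readr::write_csv(report$sweeps, paths[["sweeps"]], progress = FALSE)
  readr::write_csv(report$fick, paths[["fick"]], progress = FALSE)
  readr::write_csv(report$summary, paths[["summary"]], progress = FALSE)
  writeLines(report$verdict, file.path(out_dir, "verdict.txt"))
  paths <- c(paths, verdict = file.path(out_dir, "verdict.txt"))
  if (plots) {
    pu <- file.path(out_dir, "unoptimized.png")
    ggplot2::ggsave(pu, autoplot(report$unoptimized), width = 9, height = 6,
                    dpi = 120)
    paths <- c(paths, unoptimized_plot = pu)
    for (nm in names(report$fits)) {
      pf <- file.path(out_dir, paste0("fit_", nm, ".png"))
      ggplot2::ggsave(pf, autoplot(report$fits[[nm]]$best), width = 9,
                      height = 4, dpi = 120)
      paths <- c(paths, setNames(pf, paste0("fit_", nm, "_plot")))
    }
  }
  paths
}

#' @export
print.bc_report <- function(x, ...) {
  cat("<bc_report> hypercapnia analysis\n")
  cat(sprintf("  Fick dCMRO2 plateau: %+.2f %%\n", x$fick_plateau))
  print(x$summary)
  cat(sprintf("  verdict: %s regime reconciles oxCCO with Fick CMRO2\n",
              x$verdict))
  invisible(x)
}
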