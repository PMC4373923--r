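#' Options for the full simulation study
#'
#' Defaults reproduce the study design: all five scenarios over 100
#' years from 3673 initial thymic-naive cells, 50 agent-based replicates
#' per scenario, step 0.01 years for both simulators, and the default
#' synthetic activated-CD4+ table.
#'
#' @param scenarios Integer vector of scenario ids, subset of 1..5.
#' @param t_end Horizon, years.
#' @param n_runs ABM replicate count.
#' @param sd_dt,abm_dt Step sizes, years.
#' @param seed Base seed for every random draw in the study.
#' @param actives An \code{\link{active_table}}, or a CSV path, or NULL
#'   for the default synthetic table.
#' @param out_dir Output directory (created if missing); NULL disables
#'   file output.
#' @param level Significance level of the similarity verdict.
#' @return A \code{study_options} object.
#' @export
study_options <- function(scenarios = 1:5, t_end = 100, n_runs = 50,
                          sd_dt = 0.01, abm_dt = 0.01, seed = 1,
                          actives = NULL, out_dir = NULL, level = 0.05) {
  if (!all(scenarios %in% 1:5) || length(scenarios) == 0L)
    stop("scenarios must be a non-empty subset of 1..5", call. = FALSE)
  if (is.character(actives)) actives <- read_active_table(actives)
  if (is.null(actives)) actives <- synthetic_active_table()
  stopifnot(inherits(actives, "active_table"))
  structure(list(scenarios = as.integer(scenarios), t_end = t_end,
                 n_runs = as.integer(n_runs), sd_dt = sd_dt,
                 abm_dt = abm_dt, seed = as.integer(seed),
                 actives = actives, out_dir = out_dir, level = level),
            class = "study_options")
}

#' Read study options from a JSON config file
#'
#' Keys mirror the arguments of \code{\link{study_options}} (with
#' \code{actives} given as a CSV path).  Unknown keys are an error, never
#' silently replaced by defaults.
#'
#' @param path JSON file path.
#' @param overrides Named list of option overrides (highest precedence).
#' @return A \code{study_options} object.
#' @export
read_study_config <- function(path, overrides = list()) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(study_options))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  x[names(overrides)] <- overrides
  do.call(study_options, x)
}

.study_log <- function(...) message(sprintf(...))

#' Run one scenario end to end
#'
#' Runs the deterministic simulator and the agent-based ensemble for one
#' scenario, compares them, fits both TREC validation tables, and (when
#' \code{opts$out_dir} is set) writes: the SD trajectory CSV, per-run and
#' mean ABM CSVs, a comparison JSON and a TREC-fit JSON.  Seeds and
#' parameters are logged to stderr for reproducibility; re-running with
#' the same options reproduces every file byte for byte.
#'
#' @param id Scenario id in 1..5.
#' @param opts A \code{\link{study_options}} object.
#' @return A \code{scenario_report}: list with \code{sd}, \code{ensemble},
#'   \code{comparison}, \code{trec_fits} and \code{files}.
#' @export
run_scenario <- function(id, opts = study_options()) {
  stopifnot(inherits(opts, "study_options"))
  scenario <- scenario_parameters(id)   # validates id
  out_dir <- opts$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0L)
      stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  # per-scenario base seed, derived deterministically from the study seed
  sc_seed <- opts$seed + 1000L * scenario$id

  .study_log("scenario %d | SD | dt=%g | %g years", id, opts$sd_dt, opts$t_end)
  sd <- simulate_sd(scenario, opts$actives, t_end = opts$t_end,
                    dt = opts$sd_dt)
  .study_log("scenario %d | ABM | dt=%g | %d runs | base seed %d",
             id, opts$abm_dt, opts$n_runs, sc_seed)
  cfg <- abm_config(dt = opts$abm_dt, n_runs = opts$n_runs,
                    seed = sc_seed, t_end = opts$t_end)
  ens <- simulate_abm_ensemble(scenario, opts$actives, cfg)
  cmp <- compare_trajectories(sd, ens$mean, level = opts$level)
  # TREC validation needs the run to cover the data's age span
  trec_names <- c("murray_douek", "lorenzi")
  fits <- lapply(trec_names, function(nm) {
    trec <- load_trec_table(nm)
    if (max((trec$age_lo + trec$age_hi) / 2) > opts$t_end) {
      .study_log("scenario %d | TREC fit vs %s skipped (horizon %g y too short)",
                 id, nm, opts$t_end)
      NULL
    } else trec_goodness_of_fit(sd, trec)
  })
  names(fits) <- trec_names

  files <- character(0)
  if (!is.null(out_dir)) {
    f <- function(name) file.path(out_dir, name)
    write_trajectory_csv(sd, f(sprintf("scenario%d_sd.csv", id)))
    write_trajectory_csv(ens$mean, f(sprintf("scenario%d_abm_mean.csv", id)))
    run_df <- do.call(rbind, lapply(seq_along(ens$per_run), function(r) {
      df <- as.data.frame(ens$per_run[[r]])
      df$run <- r
      df
    }))
    utils::write.csv(run_df, f(sprintf("scenario%d_abm_runs.csv", id)),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(scenario = id,
           p_values = lapply(cmp$tests, function(t) t$p_value),
           headline_p = cmp$headline_p, verdict = cmp$verdict,
           seeds = ens$seeds),
      f(sprintf("scenario%d_comparison.json", id)),
      auto_unbox = TRUE, digits = NA)
    done <- !vapply(fits, is.null, logical(1L))
    if (any(done))
      jsonlite::write_json(
        lapply(fits[done], function(x) list(offset = x$offset, ssr = x$ssr,
                                            residuals = x$residuals)),
        f(sprintf("scenario%d_trec_fit.json", id)),
        auto_unbox = TRUE, digits = NA)
    files <- list.files(out_dir, pattern = sprintf("^scenario%d_", id),
                        full.names = TRUE)
  }
  structure(list(scenario = scenario, sd = sd, ensemble = ens,
                 comparison = cmp, trec_fits = fits, files = files),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  print(x$comparison)
  if (!is.null(x$trec_fits$murray_douek))
    cat(sprintf("  TREC SSR: murray_douek %.3f, lorenzi %.3f\n",
                x$trec_fits$murray_douek$ssr, x$trec_fits$lorenzi$ssr))
  invisible(x)
}

#' Run the full comparison study
#'
#' Runs every requested scenario through \code{\link{run_scenario}} and
#' collects a per-scenario summary of headline rank-sum p-values and
#' similarity verdicts; when an output directory is set, the summary is
#' also written as \code{summary.csv} (\code{scenario,p_value,verdict}).
#'
#' @param opts A \code{\link{study_options}} object.
#' @return A \code{study_summary}: list with \code{reports} (per
#'   scenario) and \code{summary} (data frame
#'   \code{scenario,p_value,verdict}).
#' @export
run_comparison_study <- function(opts = study_options()) {
  stopifnot(inherits(opts, "study_options"))
  reports <- lapply(opts$scenarios, run_scenario, opts = opts)
  summary <- data.frame(
    scenario = opts$scenarios,
    p_value = vapply(reports, function(r) r$comparison$headline_p,
                     numeric(1L)),
    verdict = vapply(reports, function(r) r$comparison$verdict,
                     character(1L)))
  if (!is.null(opts$out_dir))
    utils::write.csv(summary, file.path(opts$out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
  structure(list(reports = reports, summary = summary),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("SD vs ABM comparison study\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
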