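#' Convert a continuous rate to a per-step event probability
#'
#' Exponential-waiting-time discretisation: an event with continuous
#' rate r (year^-1) occurs within a step of length dt with probability
#' \code{1 - exp(-r * dt)}.
#'
#' @param rate Event rate, year^-1, non-negative (vectorised).
#' @param dt Step length, years, positive.
#' @return Probability in [0, 1).
#' @export
#' @examples
#' rate_to_probability(4.4, 0.01)   # 1 - exp(-0.044)
rate_to_probability <- function(rate, dt) {
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  1 - exp(-rate * dt)
}

#' State assigned to a newly created T-cell agent
#'
#' New agents enter the system from three sources and start in the state
#' that source produces: thymic export creates naive cells, peripheral
#' proliferation creates proliferation-origin naive cells, and reversion
#' of activated cells creates memory cells.
#'
#' @param source One of \code{"THYMUS"}, \code{"PERIPHERAL_PROLIFERATION"},
#'   \code{"ACTIVE_REVERSION"}.
#' @return The new agent's state: \code{"NAIVE"},
#'   \code{"NAIVE_FROM_PROLIFERATION"} or \code{"MEMORY"}.
#' @export
decide_new_agent_state <- function(source) {
  map <- c(THYMUS = "NAIVE",
           PERIPHERAL_PROLIFERATION = "NAIVE_FROM_PROLIFERATION",
           ACTIVE_REVERSION = "MEMORY")
  if (length(source) != 1L || !source %in% names(map))
    stop("unknown agent source '", source, "'", call. = FALSE)
  unname(map[[source]])
}

#' ABM configuration
#'
#' @param dt Step length, years, in (0, 0.1]; must divide one year evenly.
#' @param n_runs Number of replicate runs (the study design uses 50).
#' @param seed Base RNG seed; run r uses \code{seed + r}.
#' @param t_end Horizon, years (the study design uses 100).
#' @return An \code{abm_config} object.
#' @export
abm_config <- function(dt = 0.01, n_runs = 50, seed = 1, t_end = 100) {
  if (dt <= 0 || dt > 0.1) stop("need 0 < dt <= 0.1", call. = FALSE)
  if (abs(round(1 / dt) * dt - 1) > 1e-9)
    stop("dt must divide one year evenly", call. = FALSE)
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  structure(list(dt = dt, n_runs = as.integer(n_runs),
                 seed = as.integer(seed), t_end = t_end),
            class = "abm_config")
}

# one step of the competing-risks draw in aggregate (binomial) form:
# n agents, two competing exponential rates r1, r2 over dt.  A single
# combined draw removes order-of-evaluation bias; events are attributed
# to the two risks proportionally to their rates.
.competing_binomial <- function(n, r1, r2, dt) {
  if (n == 0L || (r1 == 0 && r2 == 0)) return(c(0L, 0L))
  p_any <- 1 - exp(-(r1 + r2) * dt)
  k <- stats::rbinom(1L, n, p_any)
  k1 <- stats::rbinom(1L, k, if (r1 + r2 > 0) r1 / (r1 + r2) else 0)
  c(k1, k - k1)
}

# per-agent form of the same competing draw: one uniform per agent
# against the combined probability, then proportional attribution.
.competing_per_agent <- function(n, r1, r2, dt) {
  if (n == 0L || (r1 == 0 && r2 == 0)) return(c(0L, 0L))
  u <- stats::runif(n)
  p_any <- 1 - exp(-(r1 + r2) * dt)
  hit <- u < p_any
  k <- sum(hit)
  if (k == 0L) return(c(0L, 0L))
  k1 <- sum(stats::runif(k) < r1 / (r1 + r2))
  c(k1, k - k1)
}

#' One stochastic agent-based simulation run
#'
#' Discrete-time agent-based counterpart of \code{\link{simulate_sd}}.
#' One agent represents one cell per mm^3 of peripheral blood; the run
#' starts with 3673 naive agents.  Per step of length dt, with modifier
#' functions evaluated on start-of-step counts:
#' \itemize{
#'   \item new naive agents arrive as Poisson(thymic output rate * dt);
#'   \item new memory agents arrive as Poisson(lambda_a * A(t) * dt);
#'   \item each naive agent faces competing death (rate mu_n * g) and
#'     conversion to the proliferating pool (rate lambda_n);
#'   \item each proliferation-origin agent dies with the probability from
#'     mu_np and independently spawns one new proliferation-origin agent
#'     with the probability from c * h (the parent persists);
#'   \item each memory agent faces competing death (mu_m) and reversion
#'     to the proliferating naive pool (lambda_mn).
#' }
#' Competing events use one combined exponential-waiting-time draw with
#' proportional attribution, so no event class is privileged by
#' evaluation order.  In the default \code{"binomial"} mode the
#' per-agent Bernoulli draws are collapsed into the distributionally
#' identical per-compartment binomial draws; \code{"agent"} mode draws
#' one uniform per agent.
#'
#' @param scenario A \code{\link{scenario_parameters}} object (or id 1-5).
#' @param actives An \code{\link{active_table}}.
#' @param config An \code{\link{abm_config}}.
#' @param run_seed Integer seed; the run is fully reproducible from it.
#' @param mode Execution mode, \code{"binomial"} (default) or
#'   \code{"agent"}.
#' @param init Initial counts \code{c(N, Np, M)} (integers).
#' @param instrument Logical; when TRUE the result carries an
#'   \code{"events"} attribute with cumulative arrival/birth/death/
#'   transition counts for bookkeeping checks.
#' @return A \code{\link{tcell_trajectory}} with simulator tag "ABM".
#' @export
simulate_abm_run <- function(scenario, actives, config = abm_config(),
                             run_seed = 1L,
                             mode = c("binomial", "agent"),
                             init = c(N = 3673, Np = 0, M = 0),
                             instrument = FALSE) {
  if (is.numeric(scenario)) scenario <- scenario_parameters(scenario)
  stopifnot(inherits(scenario, "tcell_scenario"),
            inherits(actives, "active_table"),
            inherits(config, "abm_config"))
  mode <- match.arg(mode)
  p <- scenario$parameters
  dt <- config$dt
  spy <- as.integer(round(1 / dt))
  n_steps <- as.integer(round(config$t_end / dt))
  years <- 0:floor(config$t_end)
  out <- matrix(NA_real_, nrow = length(years), ncol = 3,
                dimnames = list(NULL, c("N", "Np", "M")))

  step_t <- (seq_len(n_steps) - 1L) * dt
  a_step <- active_at(actives, step_t)

  N <- as.integer(init[["N"]]); Np <- as.integer(init[["Np"]])
  M <- as.integer(init[["M"]])
  out[1L, ] <- c(N, Np, M)
  rec <- 2L
  ev <- c(thymic = 0, mem_arrivals = 0, n_death = 0, n_conv = 0,
          np_death = 0, np_birth = 0, m_death = 0, m_rev = 0)

  set.seed(run_seed)
  draw <- if (mode == "binomial") .competing_binomial else .competing_per_agent
  for (i in seq_len(n_steps)) {
    t0 <- step_t[i]
    g <- death_modifier_g(Np, p)
    h <- dilution_modifier_h(N, Np, p)
    out_rate <- thymic_output_rate(t0, Np, p)
    if (!is.finite(out_rate) || !is.finite(g) || !is.finite(h))
      stop("non-finite rate at t = ", t0, call. = FALSE)

    arr_n <- stats::rpois(1L, out_rate * dt)
    arr_m <- stats::rpois(1L, p$lambda_a * a_step[i] * dt)

    kn <- draw(N, p$mu_n * g, p$lambda_n, dt)       # deaths, conversions
    if (mode == "binomial") {
      np_d <- stats::rbinom(1L, Np, rate_to_probability(p$mu_np, dt))
      np_b <- stats::rbinom(1L, Np, rate_to_probability(p$c * h, dt))
    } else {
      np_d <- sum(stats::runif(Np) < rate_to_probability(p$mu_np, dt))
      np_b <- sum(stats::runif(Np) < rate_to_probability(p$c * h, dt))
    }
    km <- draw(M, p$mu_m, p$lambda_mn, dt)          # deaths, reversions

    N  <- N + arr_n - kn[1L] - kn[2L]
    Np <- Np + kn[2L] + np_b - np_d + km[2L]
    M  <- M + arr_m - km[1L] - km[2L]
    ev <- ev + c(arr_n, arr_m, kn[1L], kn[2L], np_d, np_b, km[1L], km[2L])

    if (i %% spy == 0L && rec <= length(years)) {
      out[rec, ] <- c(N, Np, M)
      rec <- rec + 1L
    }
  }
  traj <- tcell_trajectory(times = years, N = out[, "N"], Np = out[, "Np"],
                           M = out[, "M"], scenario_id = scenario$id,
                           simulator = "ABM")
  if (instrument) attr(traj, "events") <- ev
  traj
}

#' Ensemble of agent-based runs with pointwise mean
#'
#' Runs \code{config$n_runs} replicates with seeds
#' \code{config$seed + 1, ..., config$seed + n_runs} and collects the
#' pointwise arithmetic mean trajectory (the quantity the study design
#' compares against the deterministic simulator).
#'
#' @inheritParams simulate_abm_run
#' @return An object of class \code{abm_ensemble}: list with
#'   \code{per_run} (list of \code{\link{tcell_trajectory}}),
#'   \code{mean} (trajectory tagged "ABM_MEAN") and \code{seeds}.
#' @export
#' @examples
#' ens <- simulate_abm_ensemble(2, synthetic_active_table(),
#'                              abm_config(n_runs = 2, t_end = 5, seed = 7))
#' length(ens$per_run)   # 2
simulate_abm_ensemble <- function(scenario, actives, config = abm_config(),
                                  mode = c("binomial", "agent"),
                                  init = c(N = 3673, Np = 0, M = 0)) {
  if (is.numeric(scenario)) scenario <- scenario_parameters(scenario)
  mode <- match.arg(mode)
  seeds <- config$seed + seq_len(config$n_runs)
  runs <- lapply(seeds, function(s)
    simulate_abm_run(scenario, actives, config, run_seed = s, mode = mode,
                     init = init))
  mean_of <- function(field)
    rowMeans(vapply(runs, function(r) r[[field]],
                    numeric(length(runs[[1L]]$times))))
  mean_traj <- tcell_trajectory(times = runs[[1L]]$times,
                                N = mean_of("N"), Np = mean_of("Np"),
                                M = mean_of("M"),
                                scenario_id = scenario$id,
                                simulator = "ABM_MEAN")
  structure(list(per_run = runs, mean = mean_traj, seeds = seeds,
                 config = config),
            class = "abm_ensemble")
}

#' @export
print.abm_ensemble <- function(x, ...) {
  cat(sprintf("ABM ensemble: %d runs, base seed %d\n",
              length(x$per_run), x$config$seed))
  print(x$mean)
  invisible(x)
}
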