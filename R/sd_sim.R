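#' Deterministic stock-and-flow simulation
#'
#' Integrates the three-compartment ODE system with classical fixed-step
#' fourth-order Runge-Kutta from the initial state N(0) = 3673,
#' Np(0) = 0, M(0) = 0 (at birth essentially all naive cells are of
#' thymic origin).  Stocks are clamped at zero from below after every
#' step, mirroring stock semantics (a stock cannot go negative), and the
#' state is sampled on the yearly grid 0, 1, ..., t_end.  The run is
#' bit-reproducible: no randomness, fixed step size.
#'
#' @param scenario A \code{\link{scenario_parameters}} object (or id 1-5).
#' @param actives An \code{\link{active_table}} supplying A(t).
#' @param t_end Simulation horizon, years.
#' @param dt Integration step, years; must divide one year evenly and be
#'   at most 0.1.
#' @param init Initial state \code{c(N, Np, M)}, cells mm^-3.
#' @return A \code{\link{tcell_trajectory}} with simulator tag "SD".
#' @export
#' @examples
#' traj <- simulate_sd(scenario_parameters(2), synthetic_active_table(),
#'                     t_end = 10)
#' traj$total_naive[11]   # total naive pool at age 10
simulate_sd <- function(scenario, actives, t_end = 100, dt = 0.01,
                        init = c(N = 3673, Np = 0, M = 0)) {
  if (is.numeric(scenario)) scenario <- scenario_parameters(scenario)
  stopifnot(inherits(scenario, "tcell_scenario"),
            inherits(actives, "active_table"))
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  if (dt <= 0 || dt > 0.1) stop("need 0 < dt <= 0.1", call. = FALSE)
  spy <- round(1 / dt)
  if (abs(spy * dt - 1) > 1e-9)
    stop("dt must divide one year evenly", call. = FALSE)
  p <- scenario$parameters

  n_steps <- as.integer(round(t_end / dt))
  years <- 0:floor(t_end)
  out <- matrix(NA_real_, nrow = length(years), ncol = 3,
                dimnames = list(NULL, c("N", "Np", "M")))
  # precompute A(t) on the step grid (and midpoints for the RK stages)
  a_grid <- active_at(actives, seq(0, t_end, by = dt / 2))

  y <- c(init[["N"]], init[["Np"]], init[["M"]])
  out[1L, ] <- y
  rec <- 2L
  rhs <- function(t, y, a) {
    s <- export_modifier_s(y[2L], p)
    g <- death_modifier_g(y[2L], p)
    h <- dilution_modifier_h(y[1L], y[2L], p)
    c(p$s0 * exp(-p$lambda_t * t) * s - (p$lambda_n + p$mu_n * g) * y[1L],
      p$lambda_n * y[1L] + (p$c * h - p$mu_np) * y[2L] + p$lambda_mn * y[3L],
      p$lambda_a * a - p$mu_m * y[3L] - p$lambda_mn * y[3L])
  }
  for (i in seq_len(n_steps)) {
    t0 <- (i - 1L) * dt
    a0 <- a_grid[2L * i - 1L]   # A(t0)
    am <- a_grid[2L * i]        # A(t0 + dt/2)
    a1 <- a_grid[2L * i + 1L]   # A(t0 + dt)
    k1 <- rhs(t0, y, a0)
    k2 <- rhs(t0 + dt / 2, pmax(0, y + dt / 2 * k1), am)
    k3 <- rhs(t0 + dt / 2, pmax(0, y + dt / 2 * k2), am)
    k4 <- rhs(t0 + dt, pmax(0, y + dt * k3), a1)
    y <- pmax(0, y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    if (any(!is.finite(y)))
      stop(sprintf("SD integration blew up at t = %.3f (state %s)",
                   t0 + dt, paste(signif(y, 4), collapse = ", ")),
           call. = FALSE)
    if (i %% spy == 0L && rec <= length(years)) {
      out[rec, ] <- y
      rec <- rec + 1L
    }
  }
  tcell_trajectory(times = years, N = out[, "N"], Np = out[, "Np"],
                   M = out[, "M"], scenario_id = scenario$id,
                   simulator = "SD")
}
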