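# shared fixtures: a small deterministic active table and short study
# settings used across test files

fixture_actives <- function() synthetic_active_table()

# a parameter set with a single death process and nothing else: N decays
# as a pure exponential, giving a closed-form oracle
pure_death_scenario <- function(mu = 4.4) {
  sc <- scenario_parameters(1)
  sc$parameters <- tcell_params(s0 = 0, lambda_n = 0, mu_n = mu, c = 0,
                                lambda_mn = 0, lambda_a = 0, mu_np = 0,
                                mu_m = 0, b = 0, s_bar = 0)
  sc
}

null_scenario <- function() {
  sc <- scenario_parameters(1)
  sc$parameters <- tcell_params(s0 = 0, lambda_t = 0, lambda_n = 0,
                                mu_n = 0, mu_np = 0, c = 0, lambda_mn = 0,
                                mu_m = 0, lambda_a = 0, b = 0, s_bar = 0)
  sc
}

# independent adaptive-step integration oracle built on deSolve (lsoda),
# fed by the package's derivative definition evaluated symbolically anew
# (rates written out directly, not via simulate_sd)
sd_oracle <- function(scenario, actives, t_end = 100) {
  p <- scenario$parameters
  a_fun <- function(t) active_at(actives, t)
  rhs <- function(t, y, parms) {
    np_ratio <- y[2] / p$np_bar
    s <- 1 / (1 + p$s_bar * np_ratio)
    g <- if (p$constant_g) 1 else (1 + p$b * np_ratio) / (1 + np_ratio)
    h <- 1 / (1 + (y[1] + y[2]) / p$np_bar)
    list(c(p$s0 * exp(-p$lambda_t * t) * s - (p$lambda_n + p$mu_n * g) * y[1],
           p$lambda_n * y[1] + (p$c * h - p$mu_np) * y[2] +
             p$lambda_mn * y[3],
           p$lambda_a * a_fun(t) - (p$mu_m + p$lambda_mn) * y[3]))
  }
  out <- deSolve::ode(y = c(N = 3673, Np = 0, M = 0), times = 0:t_end,
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-8)
  as.data.frame(out)
}

# brute-force exact two-sided rank-sum p by enumerating all C(n, n_x)
# assignments of ranks to the first sample (no ties assumed)
exact_ranksum_p <- function(x, y) {
  n_x <- length(x); n <- n_x + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2
  combos <- utils::combn(n, n_x)
  u_all <- apply(combos, 2, function(idx) sum(idx) - n_x * (n_x + 1) / 2)
  mu <- n_x * (n - n_x) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  min(1, p)
}
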