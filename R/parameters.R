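#' Model parameters for the naive T-cell compartment model
#'
#' Bundles every rate and homeostasis constant of the three-compartment
#' naive T-cell model: thymic-origin naive cells (N), naive cells from
#' peripheral proliferation (Np) and memory cells (M), driven by an
#' external activated-CD4+ count A(t).
#'
#' @param s0 Thymic output scale at birth, cells mm^-3 year^-1.
#' @param lambda_t Thymic involution (decay) rate, year^-1.  The default
#'   \code{log(2)/15.7} corresponds to a thymic-output half-life of
#'   15.7 years.
#' @param lambda_n Conversion rate of thymic naive cells into the
#'   proliferating naive pool, year^-1.
#' @param mu_n Death rate of thymic-origin naive cells, year^-1
#'   (scaled by the density-dependent modifier \code{\link{death_modifier_g}}).
#' @param mu_np Death rate of proliferation-origin naive cells, year^-1.
#' @param c Peripheral proliferation coefficient, year^-1 (scaled by the
#'   dilution modifier \code{\link{dilution_modifier_h}}).
#' @param lambda_mn Reversion rate from memory back into the proliferating
#'   naive pool, year^-1.
#' @param mu_m Memory cell death rate, year^-1.
#' @param lambda_a Reversion rate of active cells into memory, year^-1.
#' @param np_bar Equilibrium constant for the proliferating naive pool,
#'   cells mm^-3; sets the scale of all three homeostatic modifiers.
#' @param s_bar Thymic-export scaling constant, unitless; \code{s_bar = 0}
#'   switches homeostatic reduction of thymic export off.
#' @param b Shape constant of the naive death modifier, unitless.
#' @param constant_g Logical; when \code{TRUE} the death modifier g is
#'   held at 1 for every population size.  Defaults to \code{b == 0},
#'   the reading under which b = 0 means "no homeostatic alteration of
#'   the naive death rate" (the raw formula with b = 0 would still fall
#'   with Np, which contradicts that scenario description).
#'
#' @return An object of class \code{tcell_params}: a named list of the
#'   validated parameters.
#' @seealso \code{\link{scenario_parameters}} for the five study scenarios.
#' @export
#' @examples
#' p <- tcell_params(s0 = 56615, lambda_n = 2.1, np_bar = 713,
#'                   s_bar = 0, b = 0, mu_np = 4.4, c = 6.25)
#' p$constant_g   # TRUE, because b == 0
tcell_params <- function(s0 = 56615,
                         lambda_t = log(2) / 15.7,
                         lambda_n = 0,
                         mu_n = 4.4,
                         mu_np = 4.4,
                         c = 0,
                         lambda_mn = 0,
                         mu_m = 0.05,
                         lambda_a = 1,
                         np_bar = 387,
                         s_bar = 0,
                         b = 0,
                         constant_g = (b == 0)) {
  p <- list(s0 = s0, lambda_t = lambda_t, lambda_n = lambda_n,
            mu_n = mu_n, mu_np = mu_np, c = c, lambda_mn = lambda_mn,
            mu_m = mu_m, lambda_a = lambda_a, np_bar = np_bar,
            s_bar = s_bar, b = b, constant_g = isTRUE(constant_g))
  rates <- p[setdiff(names(p), "constant_g")]
  if (!all(vapply(rates, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1L))))
    stop("all model parameters must be single finite numbers", call. = FALSE)
  if (any(unlist(rates) < 0))
    stop("all model rates and constants must be non-negative", call. = FALSE)
  if (p$np_bar <= 0)
    stop("np_bar must be strictly positive", call. = FALSE)
  class(p) <- "tcell_params"
  p
}

#' @export
print.tcell_params <- function(x, ...) {
  cat("Naive T-cell model parameters\n")
  cat(sprintf("  thymus:   s0 = %g, lambda_t = %.5f (half-life %.1f y), s_bar = %g\n",
              x$s0, x$lambda_t, log(2) / x$lambda_t, x$s_bar))
  cat(sprintf("  naive N:  mu_n = %g, lambda_n = %g, b = %g%s\n",
              x$mu_n, x$lambda_n, x$b,
              if (x$constant_g) " (g held at 1)" else ""))
  cat(sprintf("  naive Np: mu_np = %g, c = %g, np_bar = %g\n",
              x$mu_np, x$c, x$np_bar))
  cat(sprintf("  memory:   mu_m = %g, lambda_mn = %g, lambda_a = %g\n",
              x$mu_m, x$lambda_mn, x$lambda_a))
  invisible(x)
}

#' Population state of the compartment model
#'
#' @param t Age in years.
#' @param N Thymic-origin naive count, cells mm^-3.
#' @param Np Proliferation-origin naive count, cells mm^-3.
#' @param M Memory count, cells mm^-3.
#' @return A \code{tcell_state} object (named list).
#' @export
tcell_state <- function(t, N, Np, M) {
  v <- c(t = t, N = N, Np = Np, M = M)
  if (!all(is.finite(v))) stop("state components must be finite", call. = FALSE)
  if (any(v < 0)) stop("state components must be non-negative", call. = FALSE)
  structure(list(t = t, N = N, Np = Np, M = M), class = "tcell_state")
}

# scenario registry: per-scenario columns of the study design; all other
# rates are shared across scenarios (mu_n = 4.4, mu_m = 0.05, lambda_a = 1,
# s0 = 56615, lambda_t = log(2)/15.7).
.scenario_table <- data.frame(
  id        = 1:5,
  lambda_n  = c(0.22, 2.1, 0.003, 0.005, 0.005),
  lambda_mn = c(0.05, 0,   0,     0,     0),
  np_bar    = c(387,  713, 392,   378,   378),
  s_bar     = c(0.48, 0,   0,     2.4,   2.2),
  b         = c(3.4,  0,   4.2,   0,     0.13),
  mu_np     = c(0.13, 4.4, 4.4,   4.4,   4.4),
  description = c(
    "No peripheral proliferation",
    "No homeostatic reduction in thymic export, no homeostatic alteration of naive death rate",
    "Homeostatic alteration of naive death rate but not thymic export",
    "Homeostatic alteration of thymic export but no naive death rate",
    "No restrictions"),
  stringsAsFactors = FALSE)

#' Peripheral proliferation coefficient of a scenario
#'
#' Scenario 1 switches peripheral proliferation off (\code{c = 0}); every
#' other scenario uses \code{c = 4.4 * (1 + 300 / np_bar)}.
#'
#' @param scenario A \code{tcell_scenario} object, or a scenario id 1-5.
#' @return The proliferation coefficient, year^-1.
#' @export
#' @examples
#' proliferation_coefficient(1)   # 0
#' proliferation_coefficient(2)   # 4.4 * (1 + 300/713)
proliferation_coefficient <- function(scenario) {
  if (is.numeric(scenario)) scenario <- scenario_parameters(scenario)
  if (!inherits(scenario, "tcell_scenario"))
    stop("'scenario' must be a tcell_scenario or an id in 1..5", call. = FALSE)
  if (scenario$id == 1L) 0 else 4.4 * (1 + 300 / scenario$parameters$np_bar)
}

#' Parameterisation of the five homeostasis scenarios
#'
#' Returns the full parameter set for one of the five study scenarios:
#' \enumerate{
#'   \item no peripheral proliferation (c = 0, with memory-to-naive
#'     reversion active),
#'   \item no homeostatic reduction in thymic export and constant naive
#'     death modifier (s_bar = 0, b = 0), with fast conversion
#'     lambda_n = 2.1,
#'   \item homeostatic alteration of the naive death rate only (b = 4.2),
#'   \item homeostatic alteration of thymic export only (s_bar = 2.4),
#'   \item no restrictions (s_bar = 2.2, b = 0.13).
#' }
#' All scenarios share s0 = 56615, a thymic half-life of 15.7 years,
#' mu_n = 4.4, mu_m = 0.05 and lambda_a = 1.
#'
#' @param id Integer scenario id in 1..5.
#' @return A \code{tcell_scenario} object with elements \code{id},
#'   \code{description} and \code{parameters} (a \code{\link{tcell_params}}).
#' @export
#' @examples
#' sc <- scenario_parameters(3)
#' sc$parameters$b        # 4.2
#' sc$parameters$lambda_n # 0.003
scenario_parameters <- function(id) {
  if (length(id) != 1L || !is.numeric(id) || is.na(id) || id != as.integer(id) ||
      !(id %in% .scenario_table$id))
    stop("scenario id must be a single integer in 1..5", call. = FALSE)
  row <- .scenario_table[.scenario_table$id == id, ]
  sc <- structure(list(id = as.integer(id),
                       description = row$description,
                       parameters = NULL),
                  class = "tcell_scenario")
  p <- tcell_params(lambda_n = row$lambda_n, lambda_mn = row$lambda_mn,
                    np_bar = row$np_bar, s_bar = row$s_bar, b = row$b,
                    mu_np = row$mu_np)
  sc$parameters <- p
  sc$parameters$c <- proliferation_coefficient(sc)
  sc
}

#' @export
print.tcell_scenario <- function(x, ...) {
  cat(sprintf("Scenario %d: %s\n", x$id, x$description))
  print(x$parameters)
  invisible(x)
}

#' Read and write scenario configurations as JSON
#'
#' A scenario serialises to a JSON object with keys \code{id},
#' \code{description} and \code{parameters}.  On reading, any parameter
#' may be overridden by key; unknown keys are an error rather than being
#' silently dropped.
#'
#' @param scenario A \code{tcell_scenario}.
#' @param path File path of the JSON config.
#' @param overrides Named list of parameter overrides applied after
#'   reading (same keys as \code{\link{tcell_params}}).
#' @return \code{write_scenario_json} returns \code{path} invisibly;
#'   \code{read_scenario_json} returns a \code{tcell_scenario}.
#' @export
write_scenario_json <- function(scenario, path) {
  stopifnot(inherits(scenario, "tcell_scenario"))
  x <- list(id = scenario$id, description = scenario$description,
            parameters = unclass(scenario$parameters))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path, overrides = list()) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("id", "description", "parameters")
  if (!all(need %in% names(x)))
    stop("scenario JSON must contain keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  pars <- as.list(x$parameters)
  known <- names(formals(tcell_params))
  bad <- setdiff(names(pars), known)
  if (length(bad))
    stop("unknown parameter keys in scenario JSON: ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("unknown override keys: ", paste(bad, collapse = ", "), call. = FALSE)
  pars[names(overrides)] <- overrides
  sc <- structure(list(id = as.integer(x$id), description = x$description,
                       parameters = do.call(tcell_params, pars)),
                  class = "tcell_scenario")
  sc
}
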