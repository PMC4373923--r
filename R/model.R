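#' Homeostatic modifier functions
#'
#' Three density-dependent, unitless factors regulate the compartment
#' model:
#' \describe{
#'   \item{thymic export, \code{export_modifier_s}}{
#'     \code{s(Np) = 1 / (1 + s_bar * Np / np_bar)} — falls from 1 as the
#'     proliferating naive pool grows; identically 1 when \code{s_bar = 0}.}
#'   \item{naive death, \code{death_modifier_g}}{
#'     \code{g(Np) = (1 + b * Np / np_bar) / (1 + Np / np_bar)} — moves
#'     monotonically from 1 towards \code{b} as Np grows.  When the
#'     parameter set carries \code{constant_g} (scenarios with b = 0), g
#'     is held at 1 regardless of Np.}
#'   \item{proliferation dilution, \code{dilution_modifier_h}}{
#'     \code{h(N, Np) = 1 / (1 + (N + Np) / np_bar)} — dilution of the
#'     per-cell proliferation rate by the total naive pool.}
#' }
#'
#' @param np Proliferation-origin naive count, cells mm^-3 (vectorised).
#' @param n Thymic-origin naive count, cells mm^-3 (vectorised).
#' @param p A \code{\link{tcell_params}} object.
#' @return The unitless modifier value(s).
#' @export
#' @examples
#' p <- tcell_params(s_bar = 0.48, np_bar = 387, b = 3.4)
#' export_modifier_s(387, p)   # 1 / 1.48
#' death_modifier_g(387, p)    # 4.4 / 2
#' dilution_modifier_h(0, 387, p)  # 0.5
export_modifier_s <- function(np, p) {
  stopifnot(inherits(p, "tcell_params"))
  if (any(np < 0)) stop("np must be non-negative", call. = FALSE)
  1 / (1 + p$s_bar * np / p$np_bar)
}

#' @rdname export_modifier_s
#' @param raw Logical; evaluate the raw formula even when the parameter
#'   set carries \code{constant_g} (for sensitivity checks).
#' @export
death_modifier_g <- function(np, p, raw = FALSE) {
  stopifnot(inherits(p, "tcell_params"))
  if (any(np < 0)) stop("np must be non-negative", call. = FALSE)
  if (p$constant_g && !raw) return(rep(1, length(np)))
  x <- np / p$np_bar
  (1 + p$b * x) / (1 + x)
}

#' @rdname export_modifier_s
#' @export
dilution_modifier_h <- function(n, np, p) {
  stopifnot(inherits(p, "tcell_params"))
  if (any(n < 0) || any(np < 0))
    stop("n and np must be non-negative", call. = FALSE)
  1 / (1 + (n + np) / p$np_bar)
}

#' Thymic output rate
#'
#' Cells exported by the thymus per year and mm^3 of peripheral blood:
#' \code{s0 * exp(-lambda_t * t) * s(Np)}.  At fixed Np the output halves
#' every \code{log(2) / lambda_t} years (15.7 years at the default
#' involution rate).
#'
#' @param t Age, years (vectorised).
#' @param np Proliferation-origin naive count, cells mm^-3.
#' @param p A \code{\link{tcell_params}} object.
#' @return Output rate, cells mm^-3 year^-1.
#' @export
#' @examples
#' p <- tcell_params()
#' thymic_output_rate(0, 0, p)      # s0 = 56615
#' thymic_output_rate(15.7, 0, p)   # half of s0
thymic_output_rate <- function(t, np, p) {
  stopifnot(inherits(p, "tcell_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  p$s0 * exp(-p$lambda_t * t) * export_modifier_s(np, p)
}

#' Right-hand sides of the compartment ODE system
#'
#' The instantaneous rates of change of the three stocks:
#' \deqn{dN/dt = s_0 e^{-\lambda_t t} s(N_p) - [\lambda_n + \mu_n g(N_p)] N}
#' \deqn{dN_p/dt = \lambda_n N + [c\,h(N, N_p) - \mu_{N_p}] N_p + \lambda_{mn} M}
#' \deqn{dM/dt = \lambda_a A(t) - \mu_m M - \lambda_{mn} M}
#' Thymic-origin naive cells die at \code{mu_n * g}; proliferation-origin
#' naive cells die at their own rate \code{mu_np}.  The active count A is
#' not a state: it is supplied externally through \code{a_of_t}.
#'
#' @param state A \code{\link{tcell_state}} (or list with \code{t},
#'   \code{N}, \code{Np}, \code{M}).
#' @param p A \code{\link{tcell_params}} object.
#' @param a_of_t Function of age returning the activated-CD4+ count,
#'   cells mm^-3 (e.g. built from an \code{\link{active_table}}).
#' @return Named numeric vector \code{c(dN, dNp, dM)},
#'   cells mm^-3 year^-1.
#' @export
derivatives <- function(state, p, a_of_t) {
  stopifnot(inherits(p, "tcell_params"), is.function(a_of_t))
  a <- a_of_t(state$t)
  if (!is.finite(a)) stop("active-cell lookup undefined at t = ", state$t,
                          call. = FALSE)
  s <- export_modifier_s(state$Np, p)
  g <- death_modifier_g(state$Np, p)
  h <- dilution_modifier_h(state$N, state$Np, p)
  dN  <- p$s0 * exp(-p$lambda_t * state$t) * s -
         (p$lambda_n + p$mu_n * g) * state$N
  dNp <- p$lambda_n * state$N + (p$c * h - p$mu_np) * state$Np +
         p$lambda_mn * state$M
  dM  <- p$lambda_a * a - p$mu_m * state$M - p$lambda_mn * state$M
  c(dN = dN, dNp = dNp, dM = dM)
}
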