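#' Trajectory container
#'
#' A yearly time series of the three cell populations produced by either
#' simulator, plus the derived total naive pool (N + Np).
#'
#' @param times Yearly grid in years, starting at 0.
#' @param N,Np,M Population series, cells mm^-3, same length as \code{times}.
#' @param scenario_id Integer scenario id (or NA for ad-hoc runs).
#' @param simulator One of \code{"SD"}, \code{"ABM"}, \code{"ABM_MEAN"}.
#' @return An object of class \code{tcell_trajectory}.
#' @export
tcell_trajectory <- function(times, N, Np, M, scenario_id = NA_integer_,
                             simulator = c("SD", "ABM", "ABM_MEAN")) {
  simulator <- match.arg(simulator)
  n <- length(times)
  if (n == 0L || times[1L] != 0)
    stop("times must start at 0", call. = FALSE)
  if (length(N) != n || length(Np) != n || length(M) != n)
    stop("series lengths must match the time grid", call. = FALSE)
  if (any(N < 0) || any(Np < 0) || any(M < 0))
    stop("population series must be non-negative", call. = FALSE)
  structure(list(times = times, N = N, Np = Np, M = M,
                 total_naive = N + Np,
                 scenario_id = as.integer(scenario_id),
                 simulator = simulator),
            class = "tcell_trajectory")
}

#' @export
print.tcell_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory%s: %d yearly points over %g years\n",
              x$simulator,
              if (is.na(x$scenario_id)) "" else
                sprintf(" (scenario %d)", x$scenario_id),
              length(x$times), max(x$times)))
  last <- length(x$times)
  cat(sprintf("  at t=0:   N = %8.1f  Np = %8.1f  M = %8.1f\n",
              x$N[1L], x$Np[1L], x$M[1L]))
  cat(sprintf("  at t=%-3g: N = %8.1f  Np = %8.1f  M = %8.1f  (total naive %.1f)\n",
              x$times[last], x$N[last], x$Np[last], x$M[last],
              x$total_naive[last]))
  invisible(x)
}

#' @export
as.data.frame.tcell_trajectory <- function(x, ...) {
  data.frame(time = x$times, N = x$N, Np = x$Np, M = x$M,
             total_naive = x$total_naive,
             scenario = x$scenario_id, simulator = x$simulator)
}

#' @export
plot.tcell_trajectory <- function(x, log = "", ...) {
  df <- cbind(x$N, x$Np, x$total_naive)
  graphics::matplot(x$times, df, type = "l", lty = 1,
                    col = c("firebrick", "steelblue", "black"),
                    xlab = "age (years)", ylab = "cells / mm^3",
                    log = log,
                    main = sprintf("%s trajectory%s", x$simulator,
                                   if (is.na(x$scenario_id)) "" else
                                     sprintf(", scenario %d", x$scenario_id)),
                    ...)
  graphics::legend("topright", c("N (thymic naive)", "Np (proliferation)",
                                 "total naive"),
                   col = c("firebrick", "steelblue", "black"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: \code{time,N,Np,M,total_naive,scenario,simulator}.
#'
#' @param traj A \code{\link{tcell_trajectory}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "tcell_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
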