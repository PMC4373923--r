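#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test
#'
#' The statistical yardstick of the study: a nonparametric two-sample
#' test of whether the yearly values of the two simulators could come
#' from the same distribution.  The exact null distribution is
#' enumerated for small untied samples (n_x + n_y <= 12, no ties);
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used.  Computation is delegated to
#' \code{\link[stats]{wilcox.test}}, with the branch chosen here.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A \code{rank_sum_result}: list with \code{u_statistic} (the
#'   Mann-Whitney U for \code{x}), \code{p_value} (two-sided),
#'   \code{n_x}, \code{n_y} and \code{method} (\code{"exact"} or
#'   \code{"normal_approximation"}).
#' @export
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p_value   # exact, 1/3
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y) <= 12L)
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(u_statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 n_x = length(x), n_y = length(y),
                 method = if (exact) "exact" else "normal_approximation"),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Rank-sum test (%s): U = %g, n = (%d, %d), two-sided p = %.4f\n",
              x$method, x$u_statistic, x$n_x, x$n_y, x$p_value))
  invisible(x)
}

#' Compare deterministic and agent-based trajectories
#'
#' Applies the two-sided rank-sum test to the yearly series of each
#' population (N, Np, M and the total naive pool) of two trajectories on
#' the same time grid.  The headline comparison is the total naive pool;
#' the trajectories are declared similar when the headline p-value
#' exceeds the significance level (failure to reject the similarity
#' hypothesis).
#'
#' @param sd A \code{\link{tcell_trajectory}} (typically the SD run).
#' @param abm_mean A trajectory on the same grid (typically the ABM
#'   ensemble mean).
#' @param level Significance level, default 0.05.
#' @return A \code{tcell_comparison}: list with \code{scenario_id},
#'   \code{tests} (named list of \code{rank_sum_result} for N, Np, M,
#'   total_naive), \code{headline_p}, \code{level} and \code{verdict}
#'   (\code{"similar"} or \code{"dissimilar"}).
#' @export
compare_trajectories <- function(sd, abm_mean, level = 0.05) {
  stopifnot(inherits(sd, "tcell_trajectory"),
            inherits(abm_mean, "tcell_trajectory"))
  if (!isTRUE(all.equal(sd$times, abm_mean$times)))
    stop("trajectories are on different time grids", call. = FALSE)
  if (!is.na(sd$scenario_id) && !is.na(abm_mean$scenario_id) &&
      sd$scenario_id != abm_mean$scenario_id)
    stop("trajectories come from different scenarios", call. = FALSE)
  pops <- c("N", "Np", "M", "total_naive")
  tests <- lapply(pops, function(f) rank_sum_test(sd[[f]], abm_mean[[f]]))
  names(tests) <- pops
  headline <- tests$total_naive$p_value
  structure(list(scenario_id = sd$scenario_id, tests = tests,
                 headline_p = headline, level = level,
                 verdict = if (headline > level) "similar" else "dissimilar"),
            class = "tcell_comparison")
}

#' @export
print.tcell_comparison <- function(x, ...) {
  cat(sprintf("SD vs ABM comparison%s (rank-sum, level %.2f)\n",
              if (is.na(x$scenario_id)) "" else
                sprintf(", scenario %d", x$scenario_id), x$level))
  for (nm in names(x$tests))
    cat(sprintf("  %-12s p = %.4f\n", nm, x$tests[[nm]]$p_value))
  cat(sprintf("  verdict: %s (headline total-naive p = %.4f)\n",
              x$verdict, x$headline_p))
  invisible(x)
}

#' Goodness of fit of a trajectory against a TREC table
#'
#' The TREC validation data are on a different scale (log10 TREC per
#' 10^6 PBMC) than the model (cells per mm^3); the minimal bridge is a
#' single additive offset in log10 space (a multiplicative rescaling),
#' fitted by least squares.  The thymic-naive series N(t) is evaluated
#' at the midpoint of each age range, log10-transformed, offset, and
#' compared with the tabulated means.  Only relative fit quality across
#' scenarios is meaningful.
#'
#' @param traj A \code{\link{tcell_trajectory}} covering all age-range
#'   midpoints.
#' @param trec A \code{\link{trec_table}}.
#' @return A \code{trec_fit}: list with \code{offset} (log10 units),
#'   \code{midpoints}, \code{residuals} (per age range) and \code{ssr}
#'   (sum of squared residuals).
#' @export
trec_goodness_of_fit <- function(traj, trec) {
  stopifnot(inherits(traj, "tcell_trajectory"),
            inherits(trec, "trec_table"))
  mid <- (trec$age_lo + trec$age_hi) / 2
  if (max(mid) > max(traj$times))
    stop("trajectory does not cover all TREC age-range midpoints",
         call. = FALSE)
  n_mid <- stats::approx(traj$times, traj$N, xout = mid)$y
  if (any(n_mid <= 0))
    stop("thymic-naive count non-positive at age ",
         mid[which(n_mid <= 0)[1L]], call. = FALSE)
  log_n <- log10(n_mid)
  offset <- mean(trec$mean_log10_trec - log_n)
  resid <- trec$mean_log10_trec - (log_n + offset)
  structure(list(offset = offset, midpoints = mid, residuals = resid,
                 ssr = sum(resid^2)),
            class = "trec_fit")
}

#' @export
print.trec_fit <- function(x, ...) {
  cat(sprintf("TREC fit: offset %.3f log10 units over %d age ranges, SSR = %.4f\n",
              x$offset, length(x$residuals), x$ssr))
  invisible(x)
}
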