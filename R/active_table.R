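#' Activated-CD4+ lookup table
#'
#' The memory compartment is fed by reversion of activated CD4+ cells,
#' whose abundance is not a model state but an external age-indexed input
#' (counts per mm^3 of peripheral blood).  An \code{active_table} holds
#' that lookup as (age, count) nodes; \code{\link{active_at}} evaluates
#' it by linear interpolation.
#'
#' @param ages Strictly increasing ages in years, starting at 0.
#' @param counts Activated CD4+ counts, cells mm^-3, same length as
#'   \code{ages}, all non-negative.
#' @return An object of class \code{active_table}.
#' @seealso \code{\link{synthetic_active_table}},
#'   \code{\link{read_active_table}}, \code{\link{active_at}}.
#' @export
active_table <- function(ages, counts) {
  ages <- as.numeric(ages); counts <- as.numeric(counts)
  if (length(ages) == 0L) stop("active table is empty", call. = FALSE)
  if (length(ages) != length(counts))
    stop("ages and counts must have the same length", call. = FALSE)
  if (any(!is.finite(ages)) || any(!is.finite(counts)))
    stop("ages and counts must be finite", call. = FALSE)
  if (ages[1L] != 0) stop("ages must start at 0", call. = FALSE)
  if (length(ages) > 1L && any(diff(ages) <= 0))
    stop("ages must be strictly increasing", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(ages = ages, counts = counts), class = "active_table")
}

#' @export
print.active_table <- function(x, ...) {
  cat(sprintf("Activated-CD4+ lookup table: %d nodes, ages %g-%g y, counts %g-%g cells/mm^3\n",
              length(x$ages), min(x$ages), max(x$ages),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Synthetic activated-CD4+ table
#'
#' Generates a stand-in lookup for the activated-CD4+ count per mm^3 of
#' peripheral blood as a function of age: a saturating-exponential rise
#' from a small childhood value to a stable adult plateau, reached to
#' within 5\% by \code{rise_years}, and held thereafter.  Optional
#' multiplicative noise emulates sampling scatter; counts are clamped at
#' zero.
#'
#' @param plateau Adult plateau count, cells mm^-3.
#' @param rise_years Age by which the plateau is essentially reached, years.
#' @param max_age Last tabulated age, years.
#' @param step Age spacing of the nodes, years.
#' @param start Count at age 0, cells mm^-3.
#' @param noise_sd Standard deviation of additive Gaussian noise,
#'   cells mm^-3 (0 = none).
#' @param seed Optional integer seed making noisy tables reproducible.
#' @return An \code{\link{active_table}}.
#' @export
#' @examples
#' tab <- synthetic_active_table()
#' active_at(tab, 50)   # the adult plateau
synthetic_active_table <- function(plateau = 200, rise_years = 20,
                                   max_age = 100, step = 1, start = 10,
                                   noise_sd = 0, seed = NULL) {
  if (plateau <= 0) stop("plateau must be positive", call. = FALSE)
  if (rise_years <= 0 || rise_years >= max_age)
    stop("need 0 < rise_years < max_age", call. = FALSE)
  if (step <= 0 || start < 0 || noise_sd < 0)
    stop("invalid shape parameters", call. = FALSE)
  ages <- seq(0, max_age, by = step)
  # rate such that the gap to the plateau has shrunk to 5% at rise_years
  k <- -log(0.05) / rise_years
  counts <- plateau - (plateau - start) * exp(-k * ages)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    counts <- pmax(0, counts + stats::rnorm(length(counts), sd = noise_sd))
  }
  active_table(ages, counts)
}

#' Evaluate an activated-CD4+ table at an age
#'
#' Linear interpolation between nodes; beyond the last tabulated age the
#' last count is held (the table describes early life, and the adult
#' plateau is the least-structured extension).
#'
#' @param table An \code{\link{active_table}}.
#' @param t Age(s), years, non-negative.
#' @return Interpolated count(s), cells mm^-3.
#' @export
active_at <- function(table, t) {
  stopifnot(inherits(table, "active_table"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (length(table$ages) == 1L) return(rep(table$counts, length(t)))
  stats::approx(table$ages, table$counts, xout = t, method = "linear",
                rule = 2)$y
}

#' Read and write activated-CD4+ tables as CSV
#'
#' The CSV dialect is comma-separated with a mandatory
#' \code{age,active_per_mm3} header, '.' decimal, UTF-8.
#'
#' @param path CSV file path.
#' @param table An \code{\link{active_table}} (writer).
#' @return \code{read_active_table} returns an \code{active_table};
#'   \code{write_active_table} returns \code{path} invisibly.
#' @export
read_active_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed active-table CSV: ", conditionMessage(e),
                        call. = FALSE))
  if (nrow(df) == 0L) stop("active-table CSV is empty", call. = FALSE)
  if (!identical(names(df), c("age", "active_per_mm3")))
    stop("active-table CSV must have header 'age,active_per_mm3'",
         call. = FALSE)
  bad <- which(!is.finite(df$age) | !is.finite(df$active_per_mm3))
  if (length(bad))
    stop("malformed active-table row ", bad[1L], call. = FALSE)
  if (any(df$active_per_mm3 < 0))
    stop("negative count at row ", which(df$active_per_mm3 < 0)[1L],
         call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$age) <= 0))
    stop("ages not strictly increasing at row ",
         which(diff(df$age) <= 0)[1L] + 1L, call. = FALSE)
  active_table(df$age, df$active_per_mm3)
}

#' @rdname read_active_table
#' @export
write_active_table <- function(table, path) {
  stopifnot(inherits(table, "active_table"))
  utils::write.csv(data.frame(age = table$ages,
                              active_per_mm3 = table$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' TREC validation tables
#'
#' Cross-sectional TREC (T-cell receptor excision circle) measurements
#' used to validate the thymic-naive trajectory: individuals grouped in
#' age ranges with the mean log10 TREC per 10^6 PBMC and the group size.
#' Two published tables ship as fixtures: \code{"murray_douek"} (the data
#' the original compartment model was fitted against) and
#' \code{"lorenzi"} (an independent cohort).
#'
#' @param name Fixture name, \code{"murray_douek"} or \code{"lorenzi"}.
#' @return A \code{trec_table}: data frame with columns \code{age_lo},
#'   \code{age_hi} (years), \code{mean_log10_trec} (log10 TREC per 10^6
#'   PBMC) and \code{n_individuals}.
#' @export
#' @examples
#' trec <- load_trec_table("murray_douek")
#' trec[trec$age_lo == 0, "mean_log10_trec"]   # 5.03
load_trec_table <- function(name) {
  fixtures <- c(murray_douek = "trec_murray_douek.csv",
                lorenzi = "trec_lorenzi.csv")
  if (length(name) != 1L || !name %in% names(fixtures))
    stop("unknown TREC table '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", fixtures[[name]], package = "tcellsim",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  trec_table(df)
}

#' @rdname load_trec_table
#' @param df Data frame with columns \code{age_lo}, \code{age_hi},
#'   \code{mean_log10_trec}, \code{n_individuals}.
#' @export
trec_table <- function(df) {
  need <- c("age_lo", "age_hi", "mean_log10_trec", "n_individuals")
  if (!all(need %in% names(df)))
    stop("TREC table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[need]
  if (any(df$age_hi < df$age_lo)) stop("age_hi < age_lo", call. = FALSE)
  if (any(df$n_individuals < 1)) stop("n_individuals must be >= 1",
                                      call. = FALSE)
  if (nrow(df) > 1L && any(df$age_lo[-1L] <= df$age_hi[-nrow(df)]))
    stop("age ranges must be ascending and non-overlapping", call. = FALSE)
  structure(df, class = c("trec_table", "data.frame"))
}
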