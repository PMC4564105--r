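# Exact association between cohort membership and positivity: two-sided
# Fisher test by full enumeration of the hypergeometric support, with the
# probability-mass two-sided convention (tables no more probable than the
# observed one), log-gamma arithmetic throughout.

.as_two_by_two <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m))) {
    stop("2x2 table entries must be non-negative integers", call. = FALSE)
  }
  m
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Enumerates the full hypergeometric support of tables with the observed
#' margins and sums the probabilities of all tables whose probability does
#' not exceed that of the observed table (relative tolerance `1 + 1e-7`
#' guards floating-point ties).  This is the probability-mass two-sided
#' convention of mainstream statistical software.
#'
#' @param table 2x2 matrix: rows = group, columns = (positive, negative).
#' @return The two-sided p-value; a table with an empty margin is
#'   degenerate and returns `p = 1`.
#' @examples
#' fisher_exact_two_sided(matrix(c(15, 22, 4, 109), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  m <- .as_two_by_two(table)
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  sup <- seq.int(max(0, c1 - r2), min(r1, c1))
  logp <- lgamma(r1 + 1) - lgamma(sup + 1) - lgamma(r1 - sup + 1) +
    lgamma(r2 + 1) - lgamma(c1 - sup + 1) - lgamma(r2 - c1 + sup + 1) -
    (lgamma(r1 + r2 + 1) - lgamma(c1 + 1) - lgamma(r1 + r2 - c1 + 1))
  obs <- logp[sup == m[1, 1]]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

# one-sided (upper-tail in cell [1,1]) companion, used by property tests
fisher_exact_one_sided <- function(table) {
  m <- .as_two_by_two(table)
  r1 <- m[1, 1] + m[1, 2]; r2 <- m[2, 1] + m[2, 2]
  c1 <- m[1, 1] + m[2, 1]
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  sum(dhyper(seq.int(m[1, 1], min(r1, c1)), r1, r2, c1))
}

#' Odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)` with an optional continuity constant added to every
#' cell.  With the default `continuity = 0`, a Haldane correction of 0.5 is
#' applied automatically when any cell is zero, keeping the estimate finite.
#'
#' @param table 2x2 matrix as in [fisher_exact_two_sided()].
#' @param continuity Constant added to all four cells (default 0 = automatic
#'   Haldane correction on zero cells only).
#' @return A positive odds ratio.
#' @export
odds_ratio <- function(table, continuity = 0) {
  m <- .as_two_by_two(table)
  cc <- if (continuity == 0 && any(m == 0)) 0.5 else continuity
  m <- m + cc
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Assemble a cohort association result from positivity calls
#'
#' Builds the 2x2 table of (positive, negative) individuals for the two
#' requested groups from a [call_cohort()] summary, and reports the exact
#' two-sided p, odds ratio and per-group prevalences.
#'
#' @param summary A `cohort_call_summary`.
#' @param groups Character vector of exactly two cohort labels (default
#'   `c("WM_FAMILY", "MM_FAMILY")`).
#' @return An object of class `association_result`: list with `table`
#'   (2x2 matrix), `p_two_sided`, `odds_ratio`, `prevalence` (named pair),
#'   `groups`.
#' @export
build_association <- function(summary, groups = c("WM_FAMILY", "MM_FAMILY")) {
  stopifnot(inherits(summary, "cohort_call_summary"), length(groups) == 2L)
  g <- summary$groups
  missing <- setdiff(groups, g$cohort)
  if (length(missing) > 0L) {
    stop("cohort group(s) absent from the call summary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- g[match(groups, g$cohort), ]
  tab <- matrix(c(rows$n_positive[1], rows$n_evaluable[1] - rows$n_positive[1],
                  rows$n_positive[2], rows$n_evaluable[2] - rows$n_positive[2]),
                nrow = 2, byrow = TRUE,
                dimnames = list(groups, c("positive", "negative")))
  prev <- ifelse(rows$n_evaluable > 0, rows$n_positive / rows$n_evaluable, 0)
  names(prev) <- groups
  out <- list(table = tab,
              p_two_sided = fisher_exact_two_sided(tab),
              odds_ratio = odds_ratio(tab),
              prevalence = prev,
              groups = groups)
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat("cohort association (Fisher exact, two-sided)\n")
  print(x$table)
  cat(sprintf("  prevalence: %s %.1f%% vs %s %.1f%%\n",
              x$groups[1], 100 * x$prevalence[1],
              x$groups[2], 100 * x$prevalence[2]))
  cat(sprintf("  odds ratio %.2f, p = %.4g\n", x$odds_ratio, x$p_two_sided))
  invisible(x)
}
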