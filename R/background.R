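# Background-error model: the detection threshold is set from mutation-free
# reference samples whose allele fractions, transformed to log-odds, are
# approximately normal.  Threshold = inverse-logit(trimmed mean + k * trimmed
# SD); the default k = 6 corresponds to a two-sided normal tail of ~2e-9.

#' Allele fraction from read counts
#'
#' @param total_reads Total reads at the locus (> 0).
#' @param alt_reads Reads carrying the mutant allele (0 <= alt <= total).
#' @return `alt_reads / total_reads`, vectorized.
#' @examples
#' allele_fraction(18208, 67)   # 0.00368
#' @export
allele_fraction <- function(total_reads, alt_reads) {
  if (any(total_reads == 0)) {
    stop("allele fraction undefined for total_reads = 0", call. = FALSE)
  }
  if (any(alt_reads > total_reads) || any(alt_reads < 0)) {
    stop("need 0 <= alt_reads <= total_reads", call. = FALSE)
  }
  alt_reads / total_reads
}

#' Log-odds (logit) transform of an allele fraction
#'
#' Given read counts, returns `log((alt + pseudocount) / (total - alt +
#' pseudocount))` -- the Haldane-corrected empirical logit, finite even for
#' zero mutant reads.  Given a bare fraction, returns `log(f / (1 - f))`;
#' a bare fraction of exactly 0 or 1 has no finite logit and count-based
#' input is required instead.
#'
#' @param fraction Allele fraction in (0, 1); mutually exclusive with counts.
#' @param total_reads,alt_reads Read counts (supply both).
#' @param pseudocount Continuity correction added to both odds terms when
#'   counts are given (default 0.5); negligible at depths above a few
#'   thousand reads.
#' @return Log-odds, natural log, vectorized.
#' @examples
#' to_log_odds(fraction = 0.5)                      # 0
#' to_log_odds(total_reads = 100, alt_reads = 0)    # log(0.5 / 100.5)
#' @export
to_log_odds <- function(fraction = NULL, total_reads = NULL, alt_reads = NULL,
                        pseudocount = 0.5) {
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (!is.null(fraction)) {
    if (!is.null(total_reads) || !is.null(alt_reads)) {
      stop("supply either a fraction or a count pair, not both", call. = FALSE)
    }
    if (any(fraction < 0) || any(fraction > 1)) {
      stop("fraction must lie in [0, 1]", call. = FALSE)
    }
    if (any(fraction == 0 | fraction == 1)) {
      stop("fraction exactly 0 or 1 has infinite log-odds; ",
           "supply read counts so the pseudocount applies", call. = FALSE)
    }
    return(qlogis(fraction))
  }
  if (is.null(total_reads) || is.null(alt_reads)) {
    stop("supply either 'fraction' or both 'total_reads' and 'alt_reads'",
         call. = FALSE)
  }
  if (any(alt_reads > total_reads) || any(alt_reads < 0)) {
    stop("need 0 <= alt_reads <= total_reads", call. = FALSE)
  }
  if (pseudocount == 0 && any(alt_reads == 0 | alt_reads == total_reads)) {
    stop("zero or saturated alt counts give infinite log-odds with ",
         "pseudocount = 0", call. = FALSE)
  }
  log((alt_reads + pseudocount) / (total_reads - alt_reads + pseudocount))
}

#' Trimmed location and scale
#'
#' Sorts the values, removes the `n_trim_each_end` smallest and largest
#' (by count, stable in input order for ties), and returns the arithmetic
#' mean and the sample standard deviation (n - 1 denominator) of the rest.
#'
#' @param values Numeric vector.
#' @param n_trim_each_end Number of extreme values dropped at each end
#'   (default 2).
#' @return A list with elements `mean`, `sd` and `n_used`.
#' @export
trimmed_location_scale <- function(values, n_trim_each_end = 2L) {
  n_trim_each_end <- as.integer(n_trim_each_end)
  if (n_trim_each_end < 0L) stop("n_trim_each_end must be >= 0", call. = FALSE)
  n <- length(values)
  n_min <- 2L * n_trim_each_end + 2L
  if (n < n_min) {
    stop("need at least ", n_min, " values to trim ", n_trim_each_end,
         " at each end (got ", n, ")", call. = FALSE)
  }
  ord <- order(values)  # stable: ties keep input order
  keep <- ord[seq.int(n_trim_each_end + 1L, n - n_trim_each_end)]
  v <- values[keep]
  list(mean = mean(v), sd = sd(v), n_used = length(v))
}

#' Two-sided normal tail probability of a k-sigma threshold
#'
#' Maps a sigma multiplier to the significance level it implies under the
#' normal background model: `2 * (1 - Phi(k))`.  At the default threshold
#' multiplier k = 6 this is about 1.97e-9.
#'
#' @param k_sigma Non-negative sigma multiplier.
#' @return Probability in (0, 1].
#' @examples
#' sigma_to_alpha(6)         # ~1.97e-9
#' sigma_to_alpha(1.959964)  # ~0.05
#' @export
sigma_to_alpha <- function(k_sigma) {
  if (any(k_sigma < 0)) stop("k_sigma must be >= 0", call. = FALSE)
  2 * pnorm(k_sigma, lower.tail = FALSE)
}

#' Estimate the background-error detection threshold
#'
#' Transforms each reference sample's counts to log-odds, takes the trimmed
#' mean and SD, and back-transforms `mean + k_sigma * sd` to the allele
#' fraction above which a sample cannot be explained by sequencing/PCR
#' error at the implied significance level.
#'
#' @param reference A `cohort_table` containing only `REFERENCE` samples.
#' @param k_sigma Threshold multiplier (default 6).
#' @param n_trim_each_end Extreme values removed at each end before the
#'   location/scale estimate (default 2).
#' @param pseudocount Continuity correction for the logit (default 0.5).
#' @return An object of class `background_model`: a list with
#'   `mu_logodds`, `sd_logodds`, `k_sigma`, `n_trim_each_end`,
#'   `n_reference_used`, `threshold_fraction`, `implied_alpha`,
#'   `pseudocount`.
#' @export
estimate_background <- function(reference, k_sigma = 6, n_trim_each_end = 2L,
                                pseudocount = 0.5) {
  stopifnot(is.data.frame(reference))
  if (k_sigma <= 0) stop("k_sigma must be positive", call. = FALSE)
  if (!all(reference$cohort == "REFERENCE")) {
    stop("estimate_background expects REFERENCE samples only; found cohort(s): ",
         paste(setdiff(unique(reference$cohort), "REFERENCE"), collapse = ", "),
         call. = FALSE)
  }
  lo <- to_log_odds(total_reads = reference$total_reads,
                    alt_reads = reference$alt_reads,
                    pseudocount = pseudocount)
  ts <- trimmed_location_scale(lo, n_trim_each_end)
  model <- list(
    mu_logodds = ts$mean,
    sd_logodds = ts$sd,
    k_sigma = k_sigma,
    n_trim_each_end = as.integer(n_trim_each_end),
    n_reference_used = ts$n_used,
    threshold_fraction = plogis(ts$mean + k_sigma * ts$sd),
    implied_alpha = sigma_to_alpha(k_sigma),
    pseudocount = pseudocount
  )
  class(model) <- "background_model"
  model
}

#' @export
print.background_model <- function(x, ...) {
  cat("background error model (trimmed log-odds)\n")
  cat(sprintf("  reference samples used : %d (trimmed %d each end)\n",
              x$n_reference_used, x$n_trim_each_end))
  cat(sprintf("  log-odds mean / sd     : %.4f / %.4f\n",
              x$mu_logodds, x$sd_logodds))
  cat(sprintf("  threshold (k = %g sd)  : %.4f%% allele fraction\n",
              x$k_sigma, 100 * x$threshold_fraction))
  cat(sprintf("  implied alpha          : %.3g\n", x$implied_alpha))
  invisible(x)
}

#' Serialize / restore a background model as flat JSON
#'
#' @param model A `background_model`.
#' @param path JSON file path.
#' @return `write_background_model` returns `path` invisibly;
#'   `read_background_model` returns the model.
#' @export
write_background_model <- function(model, path) {
  stopifnot(inherits(model, "background_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_model
#' @export
read_background_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("mu_logodds", "sd_logodds", "k_sigma", "n_trim_each_end",
            "n_reference_used", "threshold_fraction", "implied_alpha",
            "pseudocount")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("background model file is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  model <- x[need]
  model$n_trim_each_end <- as.integer(model$n_trim_each_end)
  model$n_reference_used <- as.integer(model$n_reference_used)
  class(model) <- "background_model"
  model
}
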