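# Positivity calling: depth QC, then a strict full-precision comparison of
# each sample's allele fraction against the background threshold.

#' Depth quality control
#'
#' A sample is evaluable when its total read count reaches `min_depth`
#' (inclusive).  Total amplicon reads serve as the depth proxy in a count
#' table; the conventional cut-off is 500x.
#'
#' @param sample An `AmpliconSample`-style row (list/data.frame with a
#'   `total_reads` field) or a bare numeric vector of total read counts.
#' @param min_depth Minimum depth (default 500).
#' @return Logical, vectorized.
#' @export
qc_pass <- function(sample, min_depth = 500L) {
  total <- if (is.numeric(sample)) sample else sample$total_reads
  if (is.null(total)) stop("no total_reads found in 'sample'", call. = FALSE)
  total >= min_depth
}

#' Call a single sample against a background model
#'
#' @param sample A one-row `cohort_table` (or list with `sample_id`,
#'   `total_reads`, `alt_reads`).
#' @param model A `background_model`.
#' @param min_depth Depth QC cut-off (default 500).
#' @return A list of class `call_result`: `sample_id`, `allele_fraction`,
#'   `qc_pass`, `qc_reason` (empty when passing) and `positive` (strict
#'   `allele_fraction > threshold_fraction`, full precision; `NA` when QC
#'   fails).
#' @export
call_sample <- function(sample, model, min_depth = 500L) {
  stopifnot(inherits(model, "background_model"))
  af <- allele_fraction(sample$total_reads, sample$alt_reads)
  ok <- qc_pass(sample, min_depth)
  res <- list(
    sample_id = as.character(sample$sample_id),
    allele_fraction = af,
    qc_pass = ok,
    qc_reason = if (ok) "" else sprintf("depth %d < %d", sample$total_reads,
                                        as.integer(min_depth)),
    positive = if (ok) af > model$threshold_fraction else NA
  )
  class(res) <- "call_result"
  res
}

#' @export
print.call_result <- function(x, ...) {
  cat(sprintf("sample %s: AF %.4f%%, QC %s%s\n", x$sample_id,
              100 * x$allele_fraction,
              if (x$qc_pass) "pass" else paste("FAIL:", x$qc_reason),
              if (isTRUE(x$qc_pass))
                paste0(", ", if (isTRUE(x$positive)) "POSITIVE" else "negative")
              else ""))
  invisible(x)
}

call_samples <- function(table, model, min_depth = 500L) {
  af <- allele_fraction(table$total_reads, table$alt_reads)
  ok <- table$total_reads >= min_depth
  data.frame(
    sample_id = table$sample_id,
    individual_id = table$individual_id,
    cohort = table$cohort,
    passage = table$passage,
    replicate = table$replicate,
    total_reads = table$total_reads,
    alt_reads = table$alt_reads,
    allele_fraction = af,
    qc_pass = ok,
    qc_reason = ifelse(ok, "", sprintf("depth %d < %d", table$total_reads,
                                       as.integer(min_depth))),
    positive = ifelse(ok, af > model$threshold_fraction, NA),
    stringsAsFactors = FALSE
  )
}

#' Call every sample in a cohort table and tally positives per group
#'
#' An individual is *evaluable* when at least one of its (selected) samples
#' passes depth QC, and *positive* when any passing replicate exceeds the
#' threshold.
#'
#' @param table A `cohort_table`.
#' @param model A `background_model`.
#' @param min_depth Depth QC cut-off (default 500).
#' @param passage Optional single passage number; when given, only samples
#'   at that passage are considered (error if none match).
#' @return An object of class `cohort_call_summary`: list with `calls`
#'   (per-sample data.frame), `groups` (per-cohort counts of individuals:
#'   total, evaluable, positive), `excluded` (QC-failed samples with
#'   reasons), `passage`, `threshold_fraction`, `min_depth`.
#' @examples
#' tab <- load_table1_fixture()
#' model <- manual_background_model(0.0047)
#' call_cohort(tab, model, passage = 0)
#' @export
call_cohort <- function(table, model, min_depth = 500L, passage = NULL) {
  stopifnot(inherits(model, "background_model"))
  sel <- table
  if (!is.null(passage)) {
    sel <- table[table$passage == passage, , drop = FALSE]
    if (nrow(sel) == 0L) {
      stop("no samples at passage ", passage, call. = FALSE)
    }
  }
  calls <- call_samples(sel, model, min_depth)
  key <- paste(calls$cohort, calls$individual_id, sep = "\r")
  first <- !duplicated(key)
  # positive is NA only where qc failed, and NA & FALSE is FALSE
  ind <- data.frame(
    cohort = calls$cohort[first][order(unique(key))],
    individual_id = calls$individual_id[first][order(unique(key))],
    evaluable = as.vector(tapply(calls$qc_pass, key, any)),
    positive = as.vector(tapply(calls$positive & calls$qc_pass, key, any)),
    stringsAsFactors = FALSE)
  groups <- data.frame(
    cohort = sort(unique(ind$cohort)),
    n_individuals = as.vector(table(ind$cohort)),
    n_evaluable = as.vector(tapply(ind$evaluable, ind$cohort, sum)),
    n_positive = as.vector(tapply(ind$positive & ind$evaluable, ind$cohort,
                                  sum)),
    stringsAsFactors = FALSE)
  excluded <- calls[!calls$qc_pass, c("sample_id", "individual_id", "cohort",
                                      "passage", "qc_reason")]
  rownames(excluded) <- NULL
  out <- list(calls = calls, groups = groups, excluded = excluded,
              passage = passage, threshold_fraction = model$threshold_fraction,
              min_depth = as.integer(min_depth))
  class(out) <- "cohort_call_summary"
  out
}

#' @export
print.cohort_call_summary <- function(x, ...) {
  cat(sprintf("positivity calls (threshold %.4f%%%s, min depth %dx)\n",
              100 * x$threshold_fraction,
              if (is.null(x$passage)) "" else sprintf(", passage %d", x$passage),
              x$min_depth))
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %-10s %d/%d positive (%d individuals, %d excluded)\n",
                g$cohort, g$n_positive, g$n_evaluable, g$n_individuals,
                g$n_individuals - g$n_evaluable))
  }
  if (nrow(x$excluded) > 0L) {
    cat(sprintf("  %d sample(s) failed depth QC\n", nrow(x$excluded)))
  }
  invisible(x)
}

#' Build a background model from a known threshold
#'
#' Occasionally only the published threshold fraction is available, not the
#' reference samples behind it.  This constructs a degenerate
#' `background_model` (zero spread, mean at the threshold's logit) whose
#' `threshold_fraction` is exactly the supplied value, for use with
#' [call_sample()] / [call_cohort()].
#'
#' @param threshold_fraction Detection threshold as a fraction in (0, 1),
#'   e.g. `0.0047` for 0.47%.
#' @param k_sigma Significance multiplier recorded on the model (default 6).
#' @return A `background_model`.
#' @export
manual_background_model <- function(threshold_fraction, k_sigma = 6) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  model <- list(
    mu_logodds = qlogis(threshold_fraction),
    sd_logodds = 0,
    k_sigma = k_sigma,
    n_trim_each_end = 0L,
    n_reference_used = 0L,
    threshold_fraction = threshold_fraction,
    implied_alpha = sigma_to_alpha(k_sigma),
    pseudocount = 0.5
  )
  class(model) <- "background_model"
  model
}
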