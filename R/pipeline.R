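# End-to-end pipeline: threshold -> call -> associate -> enrich, with all
# machine outputs written as JSON/TSV and a deterministic human-readable
# summary.  Logging goes to stderr; files carry no timestamps so identical
# configurations give byte-identical outputs.

#' Pipeline configuration
#'
#' @param reference_path TSV of error-only reference samples.
#' @param cohort_path TSV of the study cohort.
#' @param out_dir Output directory (created if absent).
#' @param k_sigma,n_trim,pseudocount Background-threshold settings (see
#'   [estimate_background()]).
#' @param min_depth Depth QC cut-off (default 500).
#' @param passages Passages at which positivity is tallied; `NULL` = every
#'   passage present in the cohort table.
#' @param association_groups Two cohort labels compared by the exact test.
#' @param association_passage Passage at which the association 2x2 is
#'   built; `NULL` = the highest tallied passage.
#' @param segments Breakpoints for the segmented enrichment fits.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when inputs are simulated).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_path, cohort_path, out_dir,
                            k_sigma = 6, n_trim = 2L, pseudocount = 0.5,
                            min_depth = 500L, passages = NULL,
                            association_groups = c("WM_FAMILY", "MM_FAMILY"),
                            association_passage = NULL,
                            segments = c(0, 4, 9), seed = 1L) {
  stopifnot(k_sigma > 0, n_trim >= 0, pseudocount >= 0, min_depth > 0,
            length(association_groups) == 2L)
  cfg <- list(reference_path = reference_path, cohort_path = cohort_path,
              out_dir = out_dir, k_sigma = k_sigma, n_trim = as.integer(n_trim),
              pseudocount = pseudocount, min_depth = as.integer(min_depth),
              passages = passages, association_groups = association_groups,
              association_passage = association_passage,
              segments = segments, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.log <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes threshold estimation, positivity calling, cohort association
#' and enrichment fitting in order, writing `model.json`, `calls.tsv`,
#' `assoc.json`, `fit.json` and `summary.txt` under the configured output
#' directory.  Any stage error aborts subsequent stages and names the
#' stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects (`model`, `summaries`,
#'   `association`, `fit_all`, `fit_segments`) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log("pipeline: ampliclone %s, seed %d",
       as.character(utils::packageVersion("ampliclone")), config$seed)
  .log("settings: k_sigma=%g trim=%d pseudocount=%g min_depth=%d",
       config$k_sigma, config$n_trim, config$pseudocount, config$min_depth)

  model <- .stage("threshold", {
    ref <- read_count_table(config$reference_path)
    estimate_background(ref, k_sigma = config$k_sigma,
                        n_trim_each_end = config$n_trim,
                        pseudocount = config$pseudocount)
  })
  write_background_model(model, file.path(config$out_dir, "model.json"))
  .log("threshold: %.4f%% from %d reference samples",
       100 * model$threshold_fraction, model$n_reference_used)

  cohort <- .stage("call", read_count_table(config$cohort_path))
  passages <- config$passages
  if (is.null(passages)) passages <- sort(unique(cohort$passage))
  summaries <- .stage("call", {
    s <- lapply(passages, function(p)
      call_cohort(cohort, model, min_depth = config$min_depth, passage = p))
    names(s) <- as.character(passages)
    s
  })
  all_calls <- do.call(rbind, lapply(summaries, function(s) s$calls))
  rownames(all_calls) <- NULL
  write.table(all_calls, file.path(config$out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  assoc_passage <- config$association_passage
  if (is.null(assoc_passage)) assoc_passage <- max(passages)
  association <- .stage("associate", {
    s <- summaries[[as.character(assoc_passage)]]
    if (is.null(s)) stop("no call summary at passage ", assoc_passage)
    if (all(config$association_groups %in% s$groups$cohort)) {
      build_association(s, config$association_groups)
    } else {
      .log("associate: skipped (groups %s not all present)",
           paste(config$association_groups, collapse = "/"))
      NULL
    }
  })
  if (!is.null(association)) {
    jsonlite::write_json(list(
      groups = association$groups,
      table = unname(apply(association$table, 1, as.list)),
      p_two_sided = association$p_two_sided,
      odds_ratio = association$odds_ratio,
      prevalence = as.list(association$prevalence),
      passage = assoc_passage
    ), file.path(config$out_dir, "assoc.json"), auto_unbox = TRUE, digits = NA)
  }

  fits <- .stage("enrich", {
    non_ref <- cohort[cohort$cohort != "REFERENCE", , drop = FALSE]
    list(all = fit_enrichment(non_ref),
         segments = fit_enrichment_segments(non_ref,
                                            breakpoints = config$segments))
  })
  write_enrichment_fit(c(list(all = fits$all), fits$segments),
                       file.path(config$out_dir, "fit.json"))

  summary_path <- file.path(config$out_dir, "summary.txt")
  .stage("report", {
    con <- file(summary_path, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("ampliclone pipeline summary")
    w("threshold: %.6f%% allele fraction (k = %g sd, alpha = %.3g, n_ref = %d)",
      100 * model$threshold_fraction, model$k_sigma, model$implied_alpha,
      model$n_reference_used)
    for (p in passages) {
      s <- summaries[[as.character(p)]]
      for (i in seq_len(nrow(s$groups))) {
        g <- s$groups[i, ]
        w("passage %s: %-10s %d/%d positive", p, g$cohort, g$n_positive,
          g$n_evaluable)
      }
    }
    if (!is.null(association)) {
      w("association (%s vs %s, passage %d): p = %.6g, OR = %.4g",
        association$groups[1], association$groups[2], assoc_passage,
        association$p_two_sided, association$odds_ratio)
    }
    w("enrichment (all passages): rate ratio %.4f (%.4f-%.4f), p = %.3g",
      fits$all$rate_ratio_per_passage, fits$all$ci_low, fits$all$ci_high,
      fits$all$p_value)
    for (nm in names(fits$segments)) {
      f <- fits$segments[[nm]]
      w("enrichment (%s): rate ratio %.4f (%.4f-%.4f), p = %.3g", nm,
        f$rate_ratio_per_passage, f$ci_low, f$ci_high, f$p_value)
    }
  })
  .log("pipeline: outputs written to %s", config$out_dir)
  invisible(list(model = model, summaries = summaries,
                 association = association, fit_all = fits$all,
                 fit_segments = fits$segments, calls = all_calls,
                 out_dir = config$out_dir))
}

#' Per-passage distribution report of allele fractions
#'
#' Tukey box summaries (median, quartiles, whiskers at 1.5 IQR, outlier
#' count) of the called allele fractions per passage, as a text table and
#' optionally a boxplot with the detection threshold drawn as a reference
#' line.
#'
#' @param calls Per-sample call data.frame (from [call_cohort()]`$calls` or
#'   the pipeline's `calls.tsv`).
#' @param model Optional `background_model` whose threshold is drawn on the
#'   plot.
#' @param path_prefix If non-NULL, writes `<prefix>_distribution.tsv` and
#'   `<prefix>_distribution.pdf`.
#' @return The summary data.frame (one row per passage), invisibly when
#'   files are written.
#' @export
render_distribution_report <- function(calls, model = NULL, path_prefix = NULL) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L) stop("no calls to report", call. = FALSE)
  by_p <- split(calls$allele_fraction, calls$passage)
  tab <- do.call(rbind, lapply(names(by_p), function(p) {
    v <- by_p[[p]]
    bs <- grDevices::boxplot.stats(v)
    data.frame(passage = as.integer(p), n = length(v),
               median = median(v),
               q1 = unname(quantile(v, 0.25)), q3 = unname(quantile(v, 0.75)),
               whisker_low = bs$stats[1], whisker_high = bs$stats[5],
               n_outliers = length(bs$out))
  }))
  tab <- tab[order(tab$passage), ]
  rownames(tab) <- NULL
  if (!is.null(path_prefix)) {
    write.table(tab, paste0(path_prefix, "_distribution.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    grDevices::pdf(paste0(path_prefix, "_distribution.pdf"), width = 6,
                   height = 5)
    on.exit(grDevices::dev.off())
    graphics::boxplot(allele_fraction ~ passage, data = calls,
                      xlab = "passage", ylab = "allele fraction",
                      main = "allele fraction by passage")
    if (!is.null(model)) {
      graphics::abline(h = model$threshold_fraction, lwd = 2)
    }
    return(invisible(tab))
  }
  tab
}
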