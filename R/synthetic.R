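# Synthetic count-table generator.  The stated world it emulates:
#  * reference samples whose allele fractions arise from sequencing error
#    alone, logit-normal around ~0.1%, with the 6-sigma point at ~0.47%;
#  * patients carrying a true mutant clone whose fraction grows
#    logit-linearly with passage number (a per-passage fitness advantage on
#    the odds scale), optionally plateauing after a changepoint passage;
#  * ultra-deep amplicon depths (~1e4-3e4 reads) drawn negative-binomially;
#  * observed mutant reads drawn binomially at the combined clone + error
#    fraction.
# Determinism: every draw flows from the configured seed through named
# substreams, so e.g. adding patients never perturbs the reference draws.

#' Simulation configuration
#'
#' Defaults describe a study at the scale of the motivating assay: 55
#' reference samples, error fractions logit-normal with mean `qlogis(0.001)`
#' (~0.1%) and SD such that the mean + 6 SD point back-transforms to ~0.47%;
#' depths negative-binomial around 15000 (size 5, spanning roughly
#' 6.5k-49k); patient baseline fraction `af0 = 0.005` with between-patient
#' logit SD 1 (matching the spread of observed pre-culture fractions);
#' fitness `log(1.46)` per passage up to a plateau at passage 4; passages
#' 0, 4, 9; two patient groups of 37 and 113 with positivity prevalences
#' 40.5% and 3.5%.
#'
#' @param n_reference Number of error-only reference samples.
#' @param reference_logodds_mean,reference_logodds_sd Logit-normal error
#'   model of the reference allele fractions.
#' @param depth_mean,depth_dispersion Negative-binomial depth draw
#'   (`mu`, `size`); a floor of 1 read is applied.
#' @param af0 True mutant-clone fraction at passage 0 (location).
#' @param af0_logodds_sd Between-individual SD of the baseline fraction on
#'   the logit scale (0 = identical baselines).
#' @param fitness_logodds_per_passage Log odds-ratio increment of the clone
#'   fraction per passage (>= 0 for a gain-of-function advantage).
#' @param plateau_passage Passage beyond which fitness becomes 0 (hard
#'   changepoint); `NULL` for unbounded growth.
#' @param passages Ordered integer passages at which patients are measured.
#' @param n_patients_per_group Named integer pair: patients per cohort
#'   (names become cohort labels).
#' @param prevalence_per_group True positivity prevalence per cohort.
#' @param seed Master seed; all randomness derives from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_reference = 55L,
                              reference_logodds_mean = qlogis(0.001),
                              reference_logodds_sd =
                                (qlogis(0.0047) - qlogis(0.001)) / 6,
                              depth_mean = 15000,
                              depth_dispersion = 5,
                              af0 = 0.005,
                              af0_logodds_sd = 1,
                              fitness_logodds_per_passage = log(1.46),
                              plateau_passage = 4L,
                              passages = c(0L, 4L, 9L),
                              n_patients_per_group =
                                c(WM_FAMILY = 37L, MM_FAMILY = 113L),
                              prevalence_per_group = c(0.405, 0.035),
                              seed = 1L) {
  cfg <- list(
    n_reference = as.integer(n_reference),
    reference_logodds_mean = reference_logodds_mean,
    reference_logodds_sd = reference_logodds_sd,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    af0 = af0,
    af0_logodds_sd = af0_logodds_sd,
    fitness_logodds_per_passage = fitness_logodds_per_passage,
    plateau_passage = if (is.null(plateau_passage)) NULL
                      else as.integer(plateau_passage),
    passages = as.integer(passages),
    n_patients_per_group = n_patients_per_group,
    prevalence_per_group = prevalence_per_group,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_reference >= 0, reference_logodds_sd >= 0,
              depth_mean > 0, depth_dispersion > 0,
              af0 > 0, af0 < 1, af0_logodds_sd >= 0,
              all(passages >= 0), all(n_patients_per_group >= 0),
              all(prevalence_per_group >= 0 & prevalence_per_group <= 1),
              length(n_patients_per_group) == length(prevalence_per_group))
  })
  if (is.null(names(cfg$n_patients_per_group))) {
    names(cfg$n_patients_per_group) <-
      c("WM_FAMILY", "MM_FAMILY")[seq_along(cfg$n_patients_per_group)]
  }
  class(cfg) <- "simulation_config"
  cfg
}

# deterministic 31-bit substream seed from (seed, label); draws inside a
# substream run under set.seed(substream) with the caller's RNG state
# saved and restored.
.substream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + (as.numeric(seed) %% 2147483647) * 7919) %% 2147483647 + 1)
}

.with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.substream_seed(seed, label))
  force(code)
}

.draw_depth <- function(n, cfg) {
  pmax(1L, rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion))
}

#' Simulate error-only reference samples
#'
#' Each reference sample gets a per-sample error fraction drawn
#' logit-normally, a negative-binomial depth, and a binomial mutant-read
#' count: the null world of the background-threshold estimator.
#'
#' @param config A [simulation_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return A `cohort_table` of `n_reference` samples, cohort `REFERENCE`,
#'   recorded at passage 9 (reference lines are assayed after culture).
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_reference
  df <- .with_stream(seed, "reference", {
    lo <- rnorm(n, config$reference_logodds_mean, config$reference_logodds_sd)
    depth <- .draw_depth(n, config)
    alt <- rbinom(n, depth, plogis(lo))
    data.frame(
      sample_id = sprintf("ref%03d_p9", seq_len(n)),
      individual_id = sprintf("ref%03d", seq_len(n)),
      family_id = "", cohort = "REFERENCE", disease = "OTHER",
      component = "NONE", passage = 9L, replicate = 1L,
      total_reads = as.integer(depth), alt_reads = as.integer(alt),
      stringsAsFactors = FALSE)
  })
  cohort_table(df, provenance = sprintf("simulated reference (seed %d)", seed))
}

#' Simulate one mutation-positive patient's passage series
#'
#' The true clone fraction at passage `p` is
#' `plogis(logit(af0_i) + fitness * min(p, plateau_passage))` with
#' `logit(af0_i)` drawn once per individual around `logit(af0)`; sequencing
#' error adds reads at the reference error rate, independently of clone
#' content, and the observed mutant count is a single binomial draw at the
#' combined fraction.
#'
#' @param config A [simulation_config()].
#' @param individual_id Identifier (also keys this patient's random
#'   substream).
#' @param seed Seed override (defaults to `config$seed`).
#' @return A data.frame passage series with columns `individual_id`,
#'   `passage`, `total_reads`, `alt_reads`, plus the latent `true_fraction`.
#' @export
simulate_patient_series <- function(config, individual_id = "pt001",
                                    seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  raw <- .sim_series_raw(config, individual_id, seed)
  data.frame(individual_id = individual_id, passage = config$passages,
             total_reads = raw$total, alt_reads = raw$alt,
             true_fraction = raw$true_fraction, stringsAsFactors = FALSE)
}

# list-valued core of the patient series draw (data.frame assembly is the
# bottleneck when thousands of patients are generated)
.sim_series_raw <- function(config, individual_id, seed) {
  p <- config$passages
  .with_stream(seed, paste0("patient:", individual_id), {
    lg0 <- rnorm(1, qlogis(config$af0), config$af0_logodds_sd)
    eff <- if (is.null(config$plateau_passage)) p
           else pmin(p, config$plateau_passage)
    f_clone <- plogis(lg0 + config$fitness_logodds_per_passage * eff)
    f_err <- plogis(rnorm(length(p), config$reference_logodds_mean,
                          config$reference_logodds_sd))
    f_obs <- f_clone + f_err * (1 - f_clone)
    depth <- .draw_depth(length(p), config)
    list(total = as.integer(depth),
         alt = as.integer(rbinom(length(p), depth, f_obs)),
         true_fraction = f_clone)
  })
}

.sim_null_raw <- function(config, individual_id, seed) {
  p <- config$passages
  .with_stream(seed, paste0("null:", individual_id), {
    lo <- rnorm(length(p), config$reference_logodds_mean,
                config$reference_logodds_sd)
    depth <- .draw_depth(length(p), config)
    list(total = as.integer(depth),
         alt = as.integer(rbinom(length(p), depth, plogis(lo))))
  })
}

#' Simulate a full two-cohort study
#'
#' Two patient groups of configured sizes: each patient is truly positive
#' with its group's prevalence; positives follow the clonal-growth model,
#' negatives carry error-only counts at every passage.  An error-only
#' reference set is appended.  Labels are populated so the table feeds
#' directly into [call_cohort()] and [build_association()].
#'
#' @param config A [simulation_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return A `cohort_table`.
#' @export
simulate_cohort_study <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  groups <- names(config$n_patients_per_group)
  np <- length(config$passages)
  parts <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- config$n_patients_per_group[[gi]]
    if (n == 0L) next
    truth <- .with_stream(seed, paste0("prevalence:", g),
                          rbinom(n, 1L, config$prevalence_per_group[[gi]]))
    ids <- sprintf("%s_%03d", tolower(g), seq_len(n))
    draws <- lapply(seq_len(n), function(i) {
      if (truth[i] == 1L) .sim_series_raw(config, ids[i], seed)
      else .sim_null_raw(config, ids[i], seed)
    })
    id_rep <- rep(ids, each = np)
    parts[[g]] <- data.frame(
      sample_id = sprintf("%s_p%d", id_rep, rep(config$passages, n)),
      individual_id = id_rep, family_id = "", cohort = g,
      disease = "OTHER", component = "NONE",
      passage = rep(config$passages, n), replicate = 1L,
      total_reads = unlist(lapply(draws, `[[`, "total")),
      alt_reads = unlist(lapply(draws, `[[`, "alt")),
      true_positive = rep(truth == 1L, each = np),
      stringsAsFactors = FALSE)
  }
  ref <- if (config$n_reference > 0L)
    as.data.frame(simulate_reference(config, seed)) else NULL
  if (!is.null(ref)) ref$true_positive <- FALSE
  all <- do.call(rbind, c(unname(parts), list(ref)))
  cohort_table(all, provenance = sprintf("simulated cohort study (seed %d)", seed))
}
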