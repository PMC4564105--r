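test_that("generation is deterministic and stream-isolated", {
  cfg <- simulation_config(n_patients_per_group = c(WM_FAMILY = 8L,
                                                    MM_FAMILY = 12L),
                           n_reference = 15L, seed = 21L)
  a <- simulate_cohort_study(cfg)
  b <- simulate_cohort_study(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(simulate_cohort_study(cfg, seed = 22L)),
                         as.data.frame(a)))

  # adding patients must not perturb the reference draws
  bigger <- simulation_config(n_patients_per_group = c(WM_FAMILY = 30L,
                                                       MM_FAMILY = 12L),
                              n_reference = 15L, seed = 21L)
  ra <- a[a$cohort == "REFERENCE", c("total_reads", "alt_reads")]
  rb <- simulate_cohort_study(bigger)
  rb <- rb[rb$cohort == "REFERENCE", c("total_reads", "alt_reads")]
  rownames(ra) <- rownames(rb) <- NULL
  expect_identical(as.data.frame(ra), as.data.frame(rb))

  # tables always satisfy the container invariants (constructor validates)
  expect_s3_class(a, "cohort_table")
  expect_true(all(a$alt_reads <= a$total_reads))
})

test_that("degenerate noise settings give the configured expectations", {
  cfg <- simulation_config(n_reference = 1000L, reference_logodds_sd = 0,
                           depth_mean = 20000, seed = 31L)
  ref <- simulate_reference(cfg)
  f <- mean(ref$alt_reads / ref$total_reads)
  p0 <- plogis(cfg$reference_logodds_mean)
  se_mean <- sqrt(mean(p0 * (1 - p0) / ref$total_reads) / nrow(ref))
  expect_lt(abs(f - p0), 3 * se_mean)

  # neutral clone: expected fraction flat across passages
  flat <- simulation_config(fitness_logodds_per_passage = 0,
                            af0_logodds_sd = 0, plateau_passage = NULL,
                            seed = 32L)
  s <- simulate_patient_series(flat, "p1")
  expect_equal(s$true_fraction, rep(s$true_fraction[1], 3))

  # logit arithmetic of the growth rule
  shift <- simulation_config(af0 = plogis(-3), af0_logodds_sd = 0,
                             fitness_logodds_per_passage = 1,
                             plateau_passage = NULL, passages = c(0L, 4L),
                             seed = 33L)
  s <- simulate_patient_series(shift, "p1")
  expect_equal(s$true_fraction[2], plogis(1), tolerance = 1e-12)

  # hard plateau: fraction at passage 9 equals the passage-4 value
  plat <- simulation_config(af0 = plogis(-3), af0_logodds_sd = 0,
                            fitness_logodds_per_passage = 1,
                            plateau_passage = 4L, seed = 33L)
  s <- simulate_patient_series(plat, "p1")
  expect_equal(s$true_fraction[3], s$true_fraction[2])
})

test_that("observed fractions track the latent truth at every passage", {
  cfg <- simulation_config(af0 = 0.01, af0_logodds_sd = 0,
                           fitness_logodds_per_passage = log(1.3),
                           plateau_passage = NULL, depth_mean = 15000,
                           reference_logodds_mean = qlogis(1e-8),
                           reference_logodds_sd = 0, seed = 41L)
  series <- do.call(rbind, lapply(sprintf("m%03d", 1:300), function(id)
    simulate_patient_series(cfg, id)))
  for (p in cfg$passages) {
    sub <- series[series$passage == p, ]
    truth <- sub$true_fraction[1]
    obs <- sub$alt_reads / sub$total_reads
    se <- sd(obs) / sqrt(nrow(sub))
    expect_lt(abs(mean(obs) - truth), 3 * se + 1e-12)
  }
})

test_that("empty patient groups leave a reference-only table", {
  cfg <- simulation_config(n_patients_per_group = c(WM_FAMILY = 0L,
                                                    MM_FAMILY = 0L),
                           n_reference = 10L, seed = 51L)
  tab <- simulate_cohort_study(cfg)
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$cohort == "REFERENCE"))

  expect_error(simulation_config(af0 = 1.2), "af0")
  expect_error(simulation_config(depth_mean = -1), "depth_mean")
})
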