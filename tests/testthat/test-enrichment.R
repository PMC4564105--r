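test_that("single-subject two-point Poisson fit matches the closed form", {
  d <- data.frame(individual_id = "a", passage = c(0L, 2L),
                  total_reads = c(10000L, 10000L), alt_reads = c(100L, 121L))
  fit <- fit_enrichment(d, family = "poisson", random_effect = "none")
  expect_equal(fit$rate_ratio_per_passage, (121 / 100)^(1 / 2),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$random_effect_sd, 0)

  # general closed form: slope = (alt-ratio * total-ratio^-1)^(1/dp)
  d2 <- data.frame(individual_id = "a", passage = c(0L, 4L),
                   total_reads = c(20000L, 10000L), alt_reads = c(60L, 90L))
  fit2 <- fit_enrichment(d2, family = "poisson", random_effect = "none")
  expect_equal(fit2$rate_ratio_per_passage, ((90 / 10000) / (60 / 20000))^(1 / 4),
               tolerance = 1e-6)
})

test_that("offset correctness and scale equivariance", {
  tab <- load_table1_fixture()
  base <- fit_enrichment(tab, family = "poisson", random_effect = "none")
  doubled <- as.data.frame(tab)
  doubled$total_reads <- 2L * doubled$total_reads
  f2 <- fit_enrichment(doubled, family = "poisson", random_effect = "none")
  expect_equal(f2$rate_ratio_per_passage, base$rate_ratio_per_passage,
               tolerance = 1e-8)
  expect_equal(exp(f2$intercept), exp(base$intercept) / 2, tolerance = 1e-6)

  scaled <- as.data.frame(tab)
  scaled$total_reads <- 3L * scaled$total_reads
  scaled$alt_reads <- 3L * scaled$alt_reads
  f3 <- fit_enrichment(scaled, random_effect = "beta")
  full <- fit_enrichment(tab, random_effect = "beta")
  expect_equal(f3$rate_ratio_per_passage, full$rate_ratio_per_passage,
               tolerance = 1e-3)
})

test_that("negbin collapses to Poisson when dispersion vanishes", {
  set.seed(42)
  n <- 40L
  d <- data.frame(individual_id = rep(sprintf("i%02d", 1:10), each = 4),
                  passage = rep(c(0L, 2L, 4L, 6L), 10))
  d$total_reads <- 20000L
  d$alt_reads <- rbinom(n, d$total_reads, 0.01 * 1.1^d$passage)
  fp <- fit_enrichment(d, family = "poisson", random_effect = "none")
  fn <- fit_enrichment(d, family = "negbin", random_effect = "none")
  expect_equal(fn$rate_ratio_per_passage, fp$rate_ratio_per_passage,
               tolerance = 1e-3)
  expect_gt(fn$dispersion, 100)  # near-Poisson data -> huge theta
})

test_that("mixed fits on the bundled fixture are sane across flavours", {
  tab <- load_table1_fixture()
  beta <- fit_enrichment(tab)            # default: beta-dispersion panel NB
  expect_true(beta$converged)
  expect_lte(beta$ci_low, beta$rate_ratio_per_passage)
  expect_gte(beta$ci_high, beta$rate_ratio_per_passage)
  expect_identical(beta$n_individuals, 19L)
  expect_identical(beta$n_observations, 57L)
  expect_lt(beta$p_value, 0.001)

  normal <- fit_enrichment(tab, random_effect = "normal")
  expect_true(normal$converged)
  expect_gt(normal$rate_ratio_per_passage, 1)
  expect_lt(normal$rate_ratio_per_passage, 1.5)

  segs <- fit_enrichment_segments(tab)
  expect_named(segs, c("0-4", "4-9"))
  expect_gt(segs[["0-4"]]$rate_ratio_per_passage,
            segs[["4-9"]]$rate_ratio_per_passage)

  expect_error(fit_enrichment(tab, passages = 4), "degeneracy")
  expect_error(fit_enrichment(tab, passages = c(7, 8)), "no observations")
  one <- data.frame(individual_id = "a", passage = c(0L, 4L),
                    total_reads = 1000L, alt_reads = c(5L, 9L))
  expect_error(fit_enrichment(one, random_effect = "normal"), "2 individuals")
  expect_error(fit_enrichment(tab, family = "poisson",
                              random_effect = "beta"), "negbin")
})

test_that("two-phase synthetic data recovers both segment regimes", {
  cfg <- simulation_config(af0 = 0.005, af0_logodds_sd = 0.8,
                           fitness_logodds_per_passage = log(1.4),
                           plateau_passage = 4L, depth_mean = 20000,
                           reference_logodds_mean = qlogis(1e-8),
                           reference_logodds_sd = 0, seed = 9L)
  series <- do.call(rbind, lapply(sprintf("pt%02d", 1:40), function(id)
    simulate_patient_series(cfg, id)))
  segs <- fit_enrichment_segments(series, random_effect = "normal",
                                  family = "poisson")
  expect_equal(segs[["0-4"]]$rate_ratio_per_passage, 1.4, tolerance = 0.05)
  expect_equal(segs[["4-9"]]$rate_ratio_per_passage, 1.0, tolerance = 0.05)
})

test_that("ICC: perfect concordance, null behaviour, and recovery", {
  pairs <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_identical(icc_oneway(pairs)$icc, 1)
  expect_error(icc_oneway(pairs[1:2, ]), "at least 3")
  expect_error(icc_oneway(cbind(1:5)), "two columns")

  set.seed(11)
  null_mean <- mean(replicate(400, icc_oneway(matrix(rnorm(26), 13, 2))$icc))
  # E[ICC] under the null is ~ -1/(n-1) = -0.083, near zero
  expect_lt(abs(null_mean), 0.12)

  # between:within SD ratio chosen so true ICC = 0.84
  b <- sqrt(0.84 / (1 - 0.84))
  est <- replicate(400, {
    subj <- rnorm(13, 0, b)
    icc_oneway(cbind(subj + rnorm(13), subj + rnorm(13)))$icc
  })
  expect_equal(mean(est), 0.84, tolerance = 0.05)

  # two-way absolute agreement close to one-way for exchangeable replicates
  set.seed(12)
  subj <- rnorm(20, 0, 2)
  m <- cbind(subj + rnorm(20), subj + rnorm(20))
  expect_equal(icc_oneway(m, type = "twoway")$icc, icc_oneway(m)$icc,
               tolerance = 0.1)
})
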