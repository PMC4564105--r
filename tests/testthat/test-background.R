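test_that("allele fraction and log-odds transforms behave", {
  expect_equal(allele_fraction(18208, 67), 67 / 18208)
  expect_equal(allele_fraction(20127, 7531), 7531 / 20127)
  expect_identical(allele_fraction(100, 0), 0)
  expect_error(allele_fraction(0, 0), "undefined")
  expect_error(allele_fraction(10, 11), "alt_reads")

  expect_identical(to_log_odds(fraction = 0.5), 0)
  expect_equal(to_log_odds(total_reads = 100, alt_reads = 0),
               log(0.5 / 100.5))
  f <- c(0.001, 0.2, 0.4, 0.49)
  expect_equal(to_log_odds(fraction = f), -to_log_odds(fraction = 1 - f))
  expect_error(to_log_odds(fraction = 0), "counts")
  expect_error(to_log_odds(fraction = 1), "counts")
  expect_error(to_log_odds(total_reads = 10, alt_reads = 0, pseudocount = 0),
               "pseudocount")
  # transform consistency on (0.001, 0.999)
  g <- seq(0.001, 0.999, length.out = 200)
  expect_equal(plogis(to_log_odds(fraction = g)), g, tolerance = 1e-12)
})

test_that("trimmed location/scale matches hand counts and a brute oracle", {
  ts <- trimmed_location_scale(c(1, 2, 3, 4, 5, 6, 7, 8), 2)
  expect_equal(ts$mean, 4.5)
  expect_equal(ts$sd, sd(3:6))
  expect_identical(ts$n_used, 4L)

  same <- trimmed_location_scale(rep(3.2, 10), 2)
  expect_equal(same$mean, 3.2)
  expect_equal(same$sd, 0)

  expect_error(trimmed_location_scale(1:5, 2), "at least 6")

  set.seed(401)
  v <- qlogis(plogis(rnorm(55, -6.9, 0.26)))
  oracle <- brute_trimmed(v, 2)
  ts <- trimmed_location_scale(v, 2)
  expect_equal(ts$mean, oracle$mean)
  expect_equal(ts$sd, oracle$sd)
})

test_that("sigma-to-alpha mapping is the two-sided normal tail", {
  expect_identical(sigma_to_alpha(0), 1)
  expect_lt(sigma_to_alpha(6), 2e-9)
  expect_equal(sigma_to_alpha(6), 1.97e-9, tolerance = 0.005)
  expect_equal(sigma_to_alpha(1.959964), 0.05, tolerance = 1e-5)
  ks <- seq(0, 8, by = 0.25)
  expect_true(all(diff(sigma_to_alpha(ks)) < 0))
  expect_error(sigma_to_alpha(-1), ">= 0")
})

test_that("background estimation: degenerate, permutation and monotonic cases", {
  ref <- degenerate_reference(total = 10000L, alt = 10L)
  m <- estimate_background(ref)
  expect_equal(m$sd_logodds, 0)
  expect_equal(m$threshold_fraction, 10 / 10000, tolerance = 5e-2)
  expect_identical(m$n_reference_used, 55L - 4L)

  set.seed(77)
  noisy <- degenerate_reference()
  noisy$alt_reads <- rbinom(55, noisy$total_reads, 0.001)
  noisy <- cohort_table(as.data.frame(noisy))
  m1 <- estimate_background(noisy)
  shuffled <- cohort_table(as.data.frame(noisy)[sample(55), ])
  expect_equal(estimate_background(shuffled)[c("mu_logodds", "sd_logodds",
                                               "threshold_fraction")],
               m1[c("mu_logodds", "sd_logodds", "threshold_fraction")])

  thresholds <- vapply(c(2, 4, 6, 8), function(k)
    estimate_background(noisy, k_sigma = k)$threshold_fraction, numeric(1))
  expect_true(all(diff(thresholds) > 0))

  # symmetric grid: trimming extremes shrinks the scale, hence the threshold
  grid <- plogis(-6.9 + 0.26 * qnorm(ppoints(55)))
  sym <- degenerate_reference(total = 1000000L, alt = 1L)
  sym$alt_reads <- as.integer(round(grid * 1e6))
  sym <- cohort_table(as.data.frame(sym))
  t_trims <- vapply(c(2, 4, 6), function(k)
    estimate_background(sym, n_trim_each_end = k)$threshold_fraction,
    numeric(1))
  expect_true(all(diff(t_trims) < 0))

  mixed <- as.data.frame(noisy)
  mixed$cohort[1] <- "WM_FAMILY"
  expect_error(estimate_background(cohort_table(mixed)), "REFERENCE")
})

test_that("background model JSON round-trips", {
  m <- estimate_background(degenerate_reference())
  f <- withr::local_tempfile(fileext = ".json")
  write_background_model(m, f)
  back <- read_background_model(f)
  expect_equal(unclass(back), unclass(m))
  expect_s3_class(back, "background_model")
})
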