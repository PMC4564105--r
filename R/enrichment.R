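# Passage-enrichment modelling: mutant read counts are regressed on passage
# number with log(total reads) as exposure offset, so exp(slope) is the
# multiplicative change in mutant-read rate per culture passage.
#
# Three random-effect flavours:
#   "beta"   - the classic panel negative binomial (Hausman-Hall-Griliches):
#              a beta-distributed dispersion shared within each individual,
#              marginal likelihood in closed form.  This is the estimator
#              behind Stata's xtnbreg and reproduces published per-passage
#              factors computed with it; package default.
#   "normal" - normal random intercept on the log mean (NB2 or Poisson),
#              adaptive Gauss-Hermite quadrature via lme4 (15 nodes).
#   "none"   - fixed-effects glm / glm.nb fallback (required for a single
#              individual, where a random effect is unidentifiable).

.series_frame <- function(table, passages = NULL) {
  x <- as.data.frame(table)
  need <- c("individual_id", "passage", "total_reads", "alt_reads")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0L) {
    stop("enrichment input needs column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(passages)) x <- x[x$passage %in% passages, , drop = FALSE]
  if (nrow(x) == 0L) stop("no observations left after passage subsetting",
                          call. = FALSE)
  if (length(unique(x$passage)) < 2L) {
    stop("design degeneracy: need at least 2 distinct passage values, got ",
         length(unique(x$passage)), call. = FALSE)
  }
  if (any(x$total_reads <= 0L)) {
    stop("total_reads must be positive for the exposure offset", call. = FALSE)
  }
  per_ind <- tapply(x$passage, x$individual_id, function(p) length(unique(p)))
  if (!any(per_ind >= 2L)) {
    stop("no individual observed at 2 or more distinct passages", call. = FALSE)
  }
  x$individual_id <- as.character(x$individual_id)
  x
}

# Hausman-Hall-Griliches random-effects negative binomial, ML via optim.
# lambda_ij = exp(b0 + b1 * passage + log(total)); group-level dispersion
# probability gamma_i ~ Beta(r, s) integrates out in closed form.
.hhg_nll <- function(par, y, off, x, grp) {
  b0 <- par[1]; b1 <- par[2]; r <- exp(par[3]); s <- exp(par[4])
  lam <- exp(b0 + b1 * x + off)
  ll <- sum(lgamma(lam + y) - lgamma(lam) - lgamma(y + 1))
  L <- rowsum(lam, grp); Y <- rowsum(y, grp)
  ll <- ll + sum(lgamma(r + s) + lgamma(r + L) + lgamma(s + Y) -
                   lgamma(r) - lgamma(s) - lgamma(r + s + L + Y))
  if (!is.finite(ll)) return(1e12)
  -ll
}

.fit_hhg <- function(d, conf_level, maxit) {
  y <- d$alt_reads; off <- log(d$total_reads); x <- d$passage
  grp <- d$individual_id
  start <- c(log(max(sum(y), 0.5) / sum(d$total_reads)), 0, 0, 1)
  o1 <- optim(start, .hhg_nll, y = y, off = off, x = x, grp = grp,
              method = "Nelder-Mead",
              control = list(maxit = 10L * maxit, reltol = 1e-12))
  o <- optim(o1$par, .hhg_nll, y = y, off = off, x = x, grp = grp,
             method = "BFGS", hessian = TRUE,
             control = list(maxit = maxit, reltol = 1e-12))
  se <- tryCatch(sqrt(diag(solve(o$hessian))[2]), error = function(e) NA_real_)
  r <- exp(o$par[3]); s <- exp(o$par[4])
  list(beta0 = o$par[1], beta1 = o$par[2], se1 = se,
       loglik = -o$value,
       converged = o$convergence == 0 && o1$convergence == 0 &&
         is.finite(se) && se > 0,
       dispersion = r / s,
       random_effect_sd = sqrt(r * s / ((r + s)^2 * (r + s + 1))),
       re_params = c(r = r, s = s))
}

.fit_lme4 <- function(d, family, conf_level, maxit) {
  d$individual_id <- factor(d$individual_id)
  d$.off <- log(d$total_reads)
  ctrl <- lme4::glmerControl(
    check.conv.singular = "ignore",
    optCtrl = list(maxfun = 100L * maxit))
  fit <- withCallingHandlers(
    if (family == "poisson") {
      lme4::glmer(alt_reads ~ passage + (1 | individual_id) + offset(.off),
                  data = d, family = poisson, nAGQ = 15L, control = ctrl)
    } else {
      lme4::glmer.nb(alt_reads ~ passage + (1 | individual_id) + offset(.off),
                     data = d, nAGQ = 15L, control = ctrl)
    },
    warning = function(w) invokeRestart("muffleWarning"))
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))[2]
  conv <- length(fit@optinfo$conv$lme4) == 0L ||
    is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code == 0L
  theta <- if (family == "negbin") lme4::getME(fit, "glmer.nb.theta") else Inf
  list(beta0 = unname(b[1]), beta1 = unname(b[2]), se1 = unname(se),
       loglik = as.numeric(stats::logLik(fit)),
       converged = conv && is.finite(se) && se > 0,
       dispersion = theta,
       random_effect_sd = sqrt(unname(lme4::VarCorr(fit)$individual_id[1, 1])),
       re_params = NULL)
}

.fit_fixed <- function(d, family, conf_level, maxit) {
  d$.off <- log(d$total_reads)
  if (family == "poisson") {
    fit <- glm(alt_reads ~ passage + offset(.off), data = d, family = poisson(),
               control = list(maxit = maxit, epsilon = 1e-10))
    theta <- Inf
    conv <- fit$converged
  } else {
    fit <- suppressWarnings(
      MASS::glm.nb(alt_reads ~ passage + offset(.off), data = d,
                   control = stats::glm.control(maxit = maxit, epsilon = 1e-10)))
    theta <- fit$theta
    conv <- fit$converged
  }
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))[2]
  list(beta0 = unname(b[1]), beta1 = unname(b[2]), se1 = unname(se),
       loglik = as.numeric(stats::logLik(fit)),
       converged = conv && is.finite(se) && se > 0,
       dispersion = theta, random_effect_sd = 0, re_params = NULL)
}

#' Fit the per-passage enrichment model
#'
#' Maximum-likelihood count regression of mutant reads on passage number
#' with `log(total_reads)` as exposure offset and a per-individual random
#' effect.  The exponentiated passage coefficient is the rate ratio per
#' passage: the multiplicative change in mutant-allele rate for each
#' additional culture passage.
#'
#' @param table A `cohort_table` or data.frame with columns
#'   `individual_id`, `passage`, `total_reads`, `alt_reads`.
#' @param passages Optional subset of passage values to fit on (e.g.
#'   `c(0, 4)` for the early growth phase).
#' @param family `"negbin"` (NB2 variance `mu + mu^2/theta`; default) or
#'   `"poisson"` (`theta = Inf`).
#' @param random_effect `"beta"` (panel NB with beta-distributed
#'   within-individual dispersion; default, negbin only), `"normal"`
#'   (normal log-mean intercept, adaptive Gauss-Hermite quadrature with 15
#'   nodes via lme4) or `"none"` (fixed-effects glm).
#' @param conf_level Wald confidence level on the log scale (default 0.95).
#' @param maxit Optimizer iteration cap (default 500).
#' @return An object of class `enrichment_fit`: list with
#'   `rate_ratio_per_passage`, `ci_low`, `ci_high`, `p_value`,
#'   `dispersion`, `random_effect_sd`, `log_likelihood`, `converged`,
#'   `n_individuals`, `n_observations`, plus the settings used.
#' @examples
#' fit <- fit_enrichment(load_table1_fixture())
#' round(fit$rate_ratio_per_passage, 2)
#' @export
fit_enrichment <- function(table, passages = NULL,
                           family = c("negbin", "poisson"),
                           random_effect = c("beta", "normal", "none"),
                           conf_level = 0.95, maxit = 500L) {
  family <- match.arg(family)
  random_effect <- match.arg(random_effect)
  if (random_effect == "beta" && family != "negbin") {
    stop("random_effect = 'beta' is defined for the negbin family only",
         call. = FALSE)
  }
  d <- .series_frame(table, passages)
  if (length(unique(d$individual_id)) < 2L && random_effect != "none") {
    stop("a per-individual random effect needs >= 2 individuals; ",
         "use random_effect = 'none'", call. = FALSE)
  }
  res <- switch(random_effect,
                beta   = .fit_hhg(d, conf_level, maxit),
                normal = .fit_lme4(d, family, conf_level, maxit),
                none   = .fit_fixed(d, family, conf_level, maxit))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(
    rate_ratio_per_passage = exp(res$beta1),
    ci_low = exp(res$beta1 - z * res$se1),
    ci_high = exp(res$beta1 + z * res$se1),
    p_value = 2 * pnorm(-abs(res$beta1 / res$se1)),
    dispersion = res$dispersion,
    random_effect_sd = res$random_effect_sd,
    log_likelihood = res$loglik,
    converged = res$converged,
    n_individuals = length(unique(d$individual_id)),
    n_observations = nrow(d),
    intercept = res$beta0,
    family = family,
    random_effect = random_effect,
    re_params = res$re_params,
    passages = sort(unique(d$passage)),
    conf_level = conf_level
  )
  class(out) <- "enrichment_fit"
  if (!out$converged) {
    warning("enrichment fit did not converge; estimates are unreliable",
            call. = FALSE)
  }
  out
}

#' @export
print.enrichment_fit <- function(x, ...) {
  cat(sprintf("passage enrichment (%s, random effect: %s)\n",
              x$family, x$random_effect))
  cat(sprintf("  passages %s | %d individuals, %d observations\n",
              paste(x$passages, collapse = ","), x$n_individuals,
              x$n_observations))
  cat(sprintf("  rate ratio per passage: %.3f (%g%% CI %.3f-%.3f), p = %.3g\n",
              x$rate_ratio_per_passage, 100 * x$conf_level, x$ci_low,
              x$ci_high, x$p_value))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' Segmented per-passage enrichment fits
#'
#' Fits the enrichment model separately on each consecutive pair of
#' breakpoint passages (e.g. breakpoints `c(0, 4, 9)` give the 0->4 growth
#' phase and the 4->9 phase).
#'
#' @param table As in [fit_enrichment()].
#' @param breakpoints Ordered passage values delimiting the segments
#'   (default `c(0, 4, 9)`).
#' @param ... Passed to [fit_enrichment()].
#' @return Named list of `enrichment_fit` objects (`"0-4"`, `"4-9"`, ...).
#' @export
fit_enrichment_segments <- function(table, breakpoints = c(0, 4, 9), ...) {
  breakpoints <- sort(unique(breakpoints))
  if (length(breakpoints) < 2L) {
    stop("need at least two breakpoint passages", call. = FALSE)
  }
  fits <- lapply(seq_len(length(breakpoints) - 1L), function(i) {
    fit_enrichment(table, passages = breakpoints[c(i, i + 1L)], ...)
  })
  names(fits) <- paste(breakpoints[-length(breakpoints)], breakpoints[-1L],
                       sep = "-")
  fits
}

#' Intraclass correlation for replicate measurements
#'
#' One-way random-effects ICC(1,1) for paired replicate measurements:
#' `(MS_between - MS_within) / (MS_between + MS_within)` for two
#' measurements per subject.  The two-way absolute-agreement flavour
#' ICC(A,1), which additionally removes a systematic replicate effect, is
#' available via `type = "twoway"`.
#'
#' @param pairs Two-column matrix/data.frame, one row per subject, columns
#'   the replicate measurements (e.g. allele fractions from independent
#'   amplification and sequencing of the same DNA).
#' @param type `"oneway"` (default) or `"twoway"` (absolute agreement).
#' @return An object of class `icc_result`: list with `icc`, `n_pairs`,
#'   `type`.
#' @export
icc_oneway <- function(pairs, type = c("oneway", "twoway")) {
  type <- match.arg(type)
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop("'pairs' must have exactly two columns", call. = FALSE)
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 pairs, got ", n, call. = FALSE)
  storage.mode(m) <- "double"
  k <- 2
  mi <- rowMeans(m); gm <- mean(m)
  msb <- k * sum((mi - gm)^2) / (n - 1)
  msw <- sum((m - mi)^2) / n
  icc <- if (type == "oneway") {
    (msb - msw) / (msb + (k - 1) * msw)
  } else {
    cj <- colMeans(m)
    msc <- n * sum((cj - gm)^2) / (k - 1)
    sse <- sum((m - outer(mi, rep(1, k)) - outer(rep(1, n), cj) + gm)^2)
    mse <- sse / ((n - 1) * (k - 1))
    (msb - mse) / (msb + (k - 1) * mse + (k / n) * (msc - mse))
  }
  out <- list(icc = icc, n_pairs = n, type = type)
  class(out) <- "icc_result"
  out
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f over %d pairs\n", x$type, x$icc, x$n_pairs))
  invisible(x)
}

#' Serialize an enrichment fit (or list of fits) as JSON
#'
#' @param fit An `enrichment_fit` or a named list of them.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_fit <- function(fit, path) {
  strip <- function(f) {
    f <- unclass(f)
    f$re_params <- as.list(f$re_params)
    f$dispersion <- if (is.infinite(f$dispersion)) "Inf" else f$dispersion
    f
  }
  payload <- if (inherits(fit, "enrichment_fit")) strip(fit) else lapply(fit, strip)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
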