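# Shared builders and independent oracles for the test suite.

# minimal valid cohort row(s)
make_rows <- function(n = 1L, cohort = "REFERENCE", total = 10000L, alt = 10L,
                      passage = 0L, individual = NULL) {
  if (is.null(individual)) individual <- sprintf("i%03d", seq_len(n))
  data.frame(
    sample_id = sprintf("%s_p%d", individual, rep_len(passage, n)),
    individual_id = individual, family_id = rep_len("", n),
    cohort = rep_len(cohort, n), disease = rep_len("OTHER", n),
    component = rep_len("NONE", n),
    passage = rep_len(as.integer(passage), n), replicate = rep_len(1L, n),
    total_reads = rep_len(total, n), alt_reads = rep_len(alt, n),
    stringsAsFactors = FALSE)
}

# a reference table whose 55 identical rows pin the threshold at ~0.47%
# (alt = 94 of 20000 with the 0.5 pseudocount back-transforms to 0.4726%)
degenerate_reference <- function(n = 55L, total = 20000L, alt = 94L) {
  cohort_table(make_rows(n, total = total, alt = alt, passage = 9L,
                         individual = sprintf("ref%03d", seq_len(n))))
}

# independent Fisher oracle: enumerate every 2x2 table with the observed
# margins using base choose() -- no shared code with the implementation
brute_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); N <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == N) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(N, c1), numeric(1))
  obs <- probs[xs == m[1, 1]]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# brute-force trimmed location/scale: sort, drop, average
brute_trimmed <- function(v, k) {
  s <- sort(v)
  kept <- s[(k + 1):(length(s) - k)]
  list(mean = sum(kept) / length(kept),
       sd = sqrt(sum((kept - mean(kept))^2) / (length(kept) - 1)))
}
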