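# ampliclone

Rare mutant-clone detection and passage enrichment from ultra-deep amplicon
read counts.

## What problem this solves

A somatic driver mutation (the motivating case is a recurrent
gain-of-function point mutation in B cells) may be carried by only a tiny
fraction of a patient's circulating cells. Ultra-deep amplicon sequencing
(10–30 thousand reads over the locus) can see allele fractions well below
1% — but sequencing and PCR error also produce mutant-looking reads, so a
bare fraction is not a detection. And when patient blood is immortalized
into cell lines and cultured, a mutation that confers a survival advantage
is progressively enriched across passages; quantifying that enrichment is a
mixed-model count-regression problem.

`ampliclone` is for analysts with per-sample read-count tables (total reads
and mutant reads per individual, passage and replicate) who need:

1. **A detection threshold** from mutation-free reference samples: allele
   fractions are transformed to log-odds (approximately normal), the 2 most
   extreme values at each end are removed, and the threshold is the
   back-transform of `mean + k·sd` (default `k = 6`, i.e. error rejected at
   `2(1−Φ(6)) ≈ 1.97e−9`).
2. **Positivity calls** with depth QC (≥ 500× by default) and a strict
   full-precision comparison against the threshold.
3. **Cohort association**: exact two-sided Fisher test (probability-mass
   convention, full enumeration via log-gamma) with odds ratio and
   prevalences.
4. **Passage enrichment**: random-effects negative binomial regression of
   mutant counts on passage number with `log(total reads)` as exposure
   offset,

   `E[y_ip | u_i] = N_ip · exp(β0 + β1·p + u_i)`,

   reporting the rate ratio per passage `exp(β1)`. The default random
   effect is the beta-dispersion panel NB (Hausman–Hall–Griliches, the
   classic "xtnbreg" estimator); a normal-intercept NB2/Poisson GLMM
   (adaptive Gauss–Hermite, 15 nodes, via lme4) and fixed-effects fits are
   options. Replicate concordance is summarised by ICC(1,1).
5. **Synthetic data**: a fully seeded generator of reference samples,
   patient passage series (logit-linear clonal growth with optional
   plateau) and whole two-cohort studies, so the entire pipeline is
   testable without sequencing data.

A published 19-individual × 3-passage count table ships as a plain-text
fixture (`load_table1_fixture()`).

## Worked example

```r
library(ampliclone)
tab <- load_table1_fixture()          # 57 samples, 19 individuals
model <- manual_background_model(0.0047)   # published 0.47% threshold

call_cohort(tab, model, passage = 0)
#> positivity calls (threshold 0.4700%, passage 0, min depth 500x)
#>   MM_FAMILY  1/4 positive (4 individuals, 0 excluded)
#>   WM_FAMILY  7/15 positive (15 individuals, 0 excluded)
```

8 of 19 individuals are detectable before culture; at passages 4 and 9 the
same call rises to 18 of 19 (individual "14" is the sole persistent
negative).

```r
fit_enrichment(tab)
#> passage enrichment (negbin, random effect: beta)
#>   passages 0,4,9 | 19 individuals, 57 observations
#>   rate ratio per passage: 1.111 (95% CI 1.066-1.158), p = 5.75e-07

segs <- fit_enrichment_segments(tab)
segs[["0-4"]]
#>   rate ratio per passage: 1.456 (95% CI 1.333-1.591), p = 7.11e-17
segs[["4-9"]]
#>   rate ratio per passage: 0.969 (95% CI 0.915-1.027), p = 0.29
```

The mutant-read rate grows 1.11-fold per passage overall; the enrichment is
concentrated between passages 0 and 4 (1.46-fold per passage) and plateaus
between 4 and 9 (0.97, not significant) — the signature of a clone with a
culture survival advantage that saturates.

```r
s <- list(groups = data.frame(cohort = c("MM_FAMILY", "WM_FAMILY"),
                              n_individuals = c(113L, 37L),
                              n_evaluable = c(113L, 37L),
                              n_positive = c(4L, 15L)))
class(s) <- "cohort_call_summary"
build_association(s)
#> cohort association (Fisher exact, two-sided)
#>           positive negative
#> WM_FAMILY       15       22
#> MM_FAMILY        4      109
#>   prevalence: WM_FAMILY 40.5% vs MM_FAMILY 3.5%
#>   odds ratio 18.58, p = 1.144e-07
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ampliclone", package = "ampliclone"))')
Rscript "$CLI" threshold --reference ref.tsv --k-sigma 6 --trim 2 --out model.json
Rscript "$CLI" call      --table cohort.tsv --model model.json --passage 9 --out calls.tsv
Rscript "$CLI" associate --table cohort.tsv --model model.json --out assoc.json
Rscript "$CLI" enrich    --table cohort.tsv --segments --out fit.json
Rscript "$CLI" simulate  --config sim.cfg --seed 17 --out synthetic.tsv
Rscript "$CLI" run       --reference ref.tsv --table cohort.tsv --out-dir out/
```

`run` executes threshold → call → associate → enrich and writes
`model.json`, `calls.tsv`, `assoc.json`, `fit.json` and a deterministic
`summary.txt`.

## Layout

- `R/` — data model & TSV I/O, background threshold, calling, association,
  enrichment, synthetic generator, pipeline, CLI
- `inst/extdata/table1_myd88_l265p.tsv` — bundled published count table
- `inst/cli/ampliclone` — CLI launcher
- `tests/testthat/` — unit, property and acceptance suites
- `vignettes/rare-clone-detection.Rmd` — methods and design rationale
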