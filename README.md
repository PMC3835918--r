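# warmclock

Does the clock that starts when a tumor leaves the body show up in its
transcriptome? Between surgical resection and snap-freezing, tissue sits at
room temperature under *warm ischemia*; mRNA can decay and stress genes can
fire, so expression measured on banked samples may partly reflect handling
rather than disease. `warmclock` implements the full statistical pipeline for
quantifying that effect on Illumina-style bead arrays — for biobank
methodologists, microarray analysts, and anyone validating
time-to-cryopreservation protocols — together with a synthetic-data generator
that emulates the study design with known ground truth, so every stage is
testable without any data download.

The design analyzed: 2 tumor types (hepatocellular and lung carcinoma) × 3
patients × 2 sampling sites (tumor center / periphery) × 4 delays to
cryopreservation (5, 15, 30, 120 min; 5 min is the reference), profiled on
arrays with ~48,800 probes (1–3 probes per gene) plus negative-control
probes.

## What it computes

- **QC** — detection p-values as add-one empirical exceedance against the
  sample's negative controls, *p* = (1 + #{controls ≥ signal})/(N+1), with
  "detected" meaning *p* < 0.01; per-sample detected-gene counts and their
  Poisson regression on the design; the P95/P05 percentile ratio (pass if
  > 10); RIN-on-time OLS; central/peripheral Pearson r².
- **Preprocessing** — natural-log transform (bead noise is proportional to
  mean signal, so logs are homoskedastic), quantile normalization, a
  detection-eligibility filter, and the excess-dispersion rule (exclude a
  probe when > 80% of raw values differ from its median by > 1.5-fold).
- **Overall trend** — per-sample inverse-variance weighted mean log
  expression, modelled as y ~ time with a random intercept per tissue series
  (REML); the slope β per hour is reported as a rate of 100(e^β − 1) %/hr
  with Satterthwaite-t Wald intervals, plus a quadratic-in-time test, across
  subsets (per type, per site, expression tails, gene sets).
- **Per-probe time courses** — OLS of log expression on centered time + time²
  with fixed series intercepts, a 2-df F-test of "no time effect", BH-FDR at
  0.05, and a gene-level significance table with directions.
- **Gene-set tests** — Neyman smooth contrasts on the ranks of per-probe
  slopes: components β_j = mean over the set of φ_j(u), with
  φ₁ = √3(2u−1), φ₂ = √5(6u²−6u+1), u = (rank−0.5)/N, exact null SE 1/√m;
  raw and SE-normalized variants; inverse-variance pooling of multi-probe
  genes; block-logistic direction-consistency against literature up/down
  calls (clustered by gene, Firth fallback under separation). Fixtures for a
  21-gene ischemia-response list and a 34-gene liver-cancer signature with
  per-study literature calls ship in `inst/extdata/`.
- **Clustering & report** — average-linkage clustering on 1 − Pearson r
  ("centred correlation") with newick export, 2-fold outlier counts vs the
  reference time, and a deterministic aggregated report.

## Worked example

Simulate the study design, spike a 2-gene decay signature at −40 %/hr, and
recover it:

```r
library(warmclock)
cfg <- sim_config(n_probes = 6000, seed = 42)
sim <- simulate_dataset(cfg)

# pick two mid-range measurable genes and make them decay
pv  <- detection_pvalues(sim$data)
flt <- eligibility_filter(sim$data$signal, pv)
med <- matrixStats::rowMedians(sim$data$signal)
mid <- flt$eligible & med > quantile(med[flt$eligible], 0.4) &
                      med < quantile(med[flt$eligible], 0.6)
targets <- unique(sim$data$probes$symbol[mid])[1:2]   # GENE00013, GENE00014
es <- inject_signature(sim$data, targets, rate_pct_per_hr = -40)

qc <- qc_report(es, array_effects = "fixed")
#> samples passing P95/P05 > 10: 48/48; RIN~time p = 0.96

ns   <- normalize_matrix(es, qc$detection_pvals)
#> 1677 of 6000 probes eligible (28%)
hcc  <- es$samples$tumor_type == "HCC"
fits <- fit_timecourse(ns$log_expr[, hcc], ns$samples[hcc, ])
significant_genes(fits, ns$probes)[, c("symbol","q","rate_pct_per_hr","direction")]
#>      symbol            q rate_pct_per_hr direction
#> 1 GENE01062 2.049607e-07       -56.04822      down
#> 2 GENE00119 2.747476e-07       -52.89450      down
#> 3 GENE00013 4.257240e-06       -27.75186      down
#> 4 GENE00014 7.607738e-06       -39.89699      down
#> 5 GENE02393 8.201553e-05       -45.30580      down
#> 6 GENE00452 4.759988e-04       -30.62248      down
#> 7 GENE02617 5.760269e-04       -37.60527      down
#> 8 GENE01598 1.026373e-03       -26.36922      down
```

Both injected genes are recovered at close to their true rates; the other
six hits are the generator's own background trend probes (0.1% of probes
decay at −30 %/hr by default), all correctly called `down`. QC passes every
sample and RIN shows no time trend, as designed.

The numbered drivers in `analysis/` (`01_simulate.R` … `07_cluster_report.R`)
run the same pipeline end to end as a narrative workflow, writing tables
under `results/`.

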