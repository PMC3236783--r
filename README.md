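# cnvassay

Copy-number genotyping of multicopy loci at population scale leans on two
PCR-based techniques: **quantitative PCR (qPCR)**, which compares threshold
cycles (Ct) of a target assay against an invariant reference assay, and the
**paralog ratio test (PRT)**, which amplifies the variable locus and a
fixed-copy paralog with a single primer pair and reads the copy number from
the peak-area ratio of the two products. Both yield a continuous estimate
that must then be snapped to an integer genotype, and both can miscall for
reasons that have nothing to do with the locus: qPCR is sensitive to the
interaction of **amplification-efficiency mismatch with input DNA amount**,
and PRT, with its longer amplicons, is sensitive to **template
degradation**.

`cnvassay` is an R package for people who run or evaluate such assays. It
provides:

* a **generative simulator** of both assays with the two failure mechanisms
  built in — Poisson sampling of amplifiable template molecules, a
  random-breakage degradation model (intact fraction `exp(-L/λ)` for an
  `L`-bp amplicon at mean fragment length `λ`), per-assay amplification
  efficiencies, and configurable measurement noise;
* the **ΔΔCt qPCR caller**: per-sample ΔCt = mean target Ct − mean
  reference Ct over usable replicates, continuous copy number
  `CN = m·2^(−(ΔCt − ΔCt_cal))` anchored so the cohort median equals the
  modal copy number `m`;
* the **PRT caller**: per-sample mean target/paralog area ratio, scaled by
  the paralog's fixed copy number and the same median-to-mode anchoring;
* a shared **maximum-likelihood integer assignment**: candidate integers
  `k = 0..k_max` scored with Gaussian likelihoods of SD
  `σ(k) = σ₀ + cv·k`, calls as the argmax with a normalized-likelihood
  confidence;
* **agreement analyses**: concordance matrices and on/above/below-diagonal
  rates, replicate reproducibility, Bland–Altman limits of agreement, and a
  χ² comparison of call distributions with sparse-category pooling;
* **assay diagnostics**: standard-curve fitting with
  `E = 10^(−1/slope) − 1`, and a closed-form predictor of how far ΔCt — and
  hence the called copy number — drifts per decade of input DNA when the
  target and reference efficiencies differ.

## Worked example

Simulate a non-normalized cohort (400 two-copy samples, lognormal input
with mean 13.28 ng clamped to 2–120 ng) assayed by a duplex qPCR whose
reference is 5.95 efficiency points above the 108.23%-efficient target,
then call copy numbers and test for input-driven bias:

```r
library(cnvassay)

target    <- assay_profile("PRELID1_qpcr", efficiency = 1.0823,
                           amplicon_length = 107, role = "qpcr_target")
reference <- assay_profile("RNaseP_qpcr", efficiency = 1.1418,
                           amplicon_length = 87, role = "qpcr_reference")

cfg    <- sim_config(400, c("2" = 1), input_model = input_lognormal(13.28),
                     seed = 1)
cohort <- make_cohort(cfg)
calls  <- call_qpcr(simulate_qpcr_plate(cohort, target, reference, cfg),
                    modal_cn = 2)
head(calls, 3)
#> # A tibble: 3 × 6
#>   sample_id continuous_cn predicted_cn confidence method input_mass
#> 1 S0001              2.14            2      1.000 qpcr         13.4
#> 2 S0002              1.98            2      1.000 qpcr         37.2
#> 3 S0003              2.14            2      1.000 qpcr         34.3

str(input_cn_correlation(calls))
#> $ pearson_r : num 0.458
#> $ p_value   : num 3.81e-22
#> $ n         : int 400
```

Every sample truly has two copies, yet the called copy number climbs
significantly with input DNA (r = 0.46 here) — exactly the artifact the
drift predictor quantifies:

```r
str(predict_dct_drift(1.0823, 1.1418))
#> $ dct_per_decade      : num -0.116
#> $ cn_factor_per_decade: num 1.08
```

i.e. ΔCt falls by 0.116 cycles, and the called copy number inflates by
about 8%, per tenfold increase of input. With equal efficiencies the drift
is zero and the correlation disappears; with normalized input the bias
cannot manifest at all.

Standard curves recover an assay's efficiency from a dilution series:

```r
ser <- data.frame(log10_input = log10(c(0.02, 0.2, 2, 20, 200)),
                  ct = c(33.73, 30.59, 27.45, 24.31, 21.17))
fit_standard_curve(ser)
#> <standard_curve>
#>   slope: -3.1400 cycles/decade  intercept: 28.395
#>   efficiency: 108.20%  R^2: 1.00000  (n = 5)
```

And published cross-tabulations of two callers load directly:

```r
m <- read_matrix(system.file("extdata", "defb4_qpcr_prt_concordance.csv",
                             package = "cnvassay"), "prt", "qpcr")
str(concordance_rates(m))
#> $ frac_same    : num 0.62
#> $ frac_b_higher: num 0.23   # qPCR called higher
#> $ frac_b_lower : num 0.15
```

## Scenarios and command line

Four bundled YAML scenarios (`normalized_intact`, `nonnormalized`,
`degraded`, `defb4_modal4`) describe complete in-silico experiments;
`run_scenario("nonnormalized", "out/")` chains simulate → call-qPCR →
call-PRT → agreement and writes six CSV/JSON outputs plus a manifest,
byte-reproducibly for a given seed. A thin CLI wrapper with the same
subcommands (`simulate`, `standard-curve`, `call-qpcr`, `call-prt`,
`concord`, `run-scenario`) ships in `inst/cli/cnvassay.R`.

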