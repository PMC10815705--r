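---
title: "Methods: knockout transcriptome contrasts, dominance classes and cosinor rhythms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout transcriptome contrasts, dominance classes and cosinor rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kodeg)
```

## The design and the question

Two paralogous transcriptional repressors often buffer each other: ablating
either one alone leaves many targets unchanged because the other compensates,
while ablating both reveals the full regulon. The four-genotype design —
wild type (`WT`), each single knockout (`N1KO`, `N2KO`), and the double
knockout (`NDKO`), with replicate cultures per genotype — lets one separate
three regimes per target gene: *redundant* regulation (changed only in the
double knockout), *additive/shared* regulation (both singles contribute),
and *isoform-dominant* regulation (one single knockout reproduces the double
knockout while the other leaves the gene essentially unchanged). The package
operationalises exactly this partition, plus the reporter-level assays used
to confirm that such knockouts dysregulate clock-controlled transcription.

## Differential expression on TPM

The analysis is deliberately the transparent threshold-based pipeline used
with TPM-level data, not a count-model fit:

* **Expression filter.** `filter_expressed()` keeps exactly
  `floor(q · n_genes)` genes with the highest mean TPM over all samples
  (default `q = 0.25`, the "significantly detected" upper quartile). Ties at
  the cutoff are broken lexicographically by gene id so the retained set is
  a deterministic function of the matrix.
* **Contrast.** `contrast()` computes `FC = mean(TPM_mut)/mean(TPM_WT)` on
  the raw scale — so FC does not depend on the pseudocount — and a
  two-sided pooled-variance Student's *t* on `log2(TPM + pseudocount)`
  (default pseudocount 1), `df = n1 + n2 − 2`. The log transform is the
  variance stabiliser consistent with TPM inputs; Welch's unequal-variance
  form is available via `var_equal = FALSE`. Whether the original analyses
  of such datasets test TPM or log-TPM is rarely stated, so both the scale
  (via the pseudocount) and the variance assumption are exposed as options.
* **DEG flags.** `deg_up` iff `FC > 1.5` and `p < 0.05`; `deg_down` iff
  `FC < 1/1.5` and `p < 0.05`. Inequalities are strict, one fold-change
  criterion is applied symmetrically to both directions, and the flags use
  raw p-values (that is how such DEG sets are conventionally defined);
  BH-adjusted q-values are emitted as an extra column for users who want
  FDR control.
* **Degenerate genes.** Zero pooled variance with equal means gives `p = 1`
  (no evidence); zero variance with unequal means gives `p = 0` with a
  `degenerate` flag (infinite *t*); a 0/0 fold change is `NaN` with
  `fc_undefined = TRUE` and is never flagged as a DEG.

## Dominance classification and Venn summaries

`classify_isoforms()` assigns each NDKO DEG one class per direction.
For upregulated genes: `alpha_dominant` requires a same-direction DEG call
in N1KO **and** `FC_N2KO < 1.3`; `beta_dominant` is the mirror image;
`ndko_exclusive` requires a DEG call in neither single knockout; everything
else is `shared`. Three points were genuinely open and are resolved as
follows:

* The down-direction secondary criterion is read as "less than a 1.3-fold
  decrease", i.e. `FC > 1/1.3 ≈ 0.769` — the exact mirror of the
  unambiguous up-direction rule.
* The secondary criterion is a fold-change bound only; no p-value condition
  is placed on the non-dominant single knockout.
* Dominance does require direction-consistent *significance* in the
  dominant single knockout (the DEG flag, not merely a large FC).

With the default thresholds (primary FC 1.5, secondary 1.3) a gene can
never satisfy both dominance criteria at once, but the thresholds are
configurable and a conflicting configuration would yield `ambiguous` rather
than an arbitrary tie-break. `shared` deliberately absorbs all remaining
regimes (significant in one single with the other exceeding the secondary
bound, significant in both, etc.) instead of inventing finer subclasses.

`venn_summary()` reports, per direction, the three DEG-set sizes, all seven
disjoint intersection cells, and the NDKO-exclusive percentage
`100·|NDKO only|/|NDKO|` rounded to two decimals (`NA` when the NDKO set is
empty). This percentage is the headline measure of redundancy in this kind
of study.

## Overrepresentation statistics

`overrep_p(k, K, n, N)` is the upper-tail hypergeometric probability
`P(X ≥ k)` computed via `phyper`; it equals the one-sided Fisher's exact
test on the 2×2 overlap table and is the statistic behind ENRICHR-style
web tools. Only the overrepresentation side is offered. `enrich()` tests
every term of a GMT library with at least `min_term_size = 3` genes inside
the universe, BH-adjusts within that library only (libraries are queried
independently), and sorts by p, ties by descending `% overlap` (defined
ENRICHR-style as `100·k/K`, the covered fraction of the term; `k/n` is also
reported) then term name. The universe defaults, in the pipeline, to the
post-filter expressed genes rather than the whole genome: query lists are
drawn from that background, so testing against anything larger would
overstate enrichment. Web tools do not document their exact background
size, so the universe is a configuration choice here, not a reproduction
claim.

## Cosinor rhythm analysis

`cosinor_fit()` fits `y = M + b·t + β_c cos(2πt/τ) + β_s sin(2πt/τ)` by
ordinary least squares, with amplitude `A = √(β_c² + β_s²)`, acrophase
`φ = (τ/2π)·atan2(β_s, β_c)` mapped into `[0, τ)` and mesor `M`.
Choices that matter:

* **Trend inside the regression.** A linear trend term (default on) handles
  baseline drift in one stage with a closed-form OLS fit. The separate
  `detrend()` (centred moving average) exists for plotting parity with
  detrended reporter traces, not as a preprocessing requirement. Its window
  uses trapezoidal endpoint weights — the classic seasonal moving average —
  so a window of exactly one period annihilates a commensurate cosine
  *exactly*; flat weights over `period/dt + 1` points would double-count one
  phase and leave a ripple of order `A·dt/period`.
* **Rhythmicity and N/A.** The F-test of `(β_c, β_s)` jointly zero against
  the trend-only model gives `rhythmicity_p`; relative amplitude `100·A/M`
  (% of mesor) is reported only when `p < 0.05` and `M > 0`, otherwise
  `NA` — the operational version of the "not applicable" convention for
  arrhythmic traces. When the reduced and full models both fit exactly
  (noiseless constant), `p = 1`; a noiseless perfect cosine gives `p = 0`.
* **Coverage and period search.** Fitting requires at least two full
  periods of coverage. `free_period = TRUE` minimises the residual sum of
  squares over a 20–28 h grid (step 0.1 h), bounded to roughly circadian
  values to avoid aliasing onto harmonics.
* **No damping term.** The classical cosinor is undamped, and that is what
  is fitted. On a damped signal `A·e^{−λt}cos(·)` the OLS amplitude is, to
  excellent approximation, the record-average of the envelope,
  `A·(1 − e^{−λT})/(λT)` for record length `T`: a deterministic downward
  bias (~36% at `λ = 0.01 h⁻¹`, `T = 96 h`) that no amount of replication
  removes, while acrophase and mesor remain essentially unbiased. Users who
  need envelope-corrected amplitudes should either restrict the fit window
  to the early cycles or treat the fitted `A` as a record-average — the
  package reports the classical quantity and documents the bias rather than
  silently switching models.

`normalize_reporter()` (dual-luciferase endpoints) divides firefly by
renilla per well to correct transfection efficiency, excludes wells with
non-positive renilla, and scales by the reference-group mean so the
reference mean is exactly 1. `ddct()` implements comparative-Ct qPCR:
`ΔCt = Ct_target − Ct_reference`, `ΔΔCt` centred on the control-group mean,
relative expression `2^{−ΔΔCt}`. Because the centring happens on the Ct
(log) scale, it is the *geometric* mean of the control group that equals 1
exactly; the arithmetic mean exceeds 1 whenever control ΔCt varies.

## The synthetic-data module

`simulate_expression()` is first-class, tested code, not a fixture. Per
gene *g* and sample *s* of genotype *G*:

`log2 TPM = baseline_g + δ_G(class_g) + Normal(0, replicate_sd²)`, `TPM = 2^{log2}`

with baselines drawn once per gene from
`Normal(baseline_log2_mean = 4, baseline_log2_sd = 2)` (≈16 TPM typical,
spanning low-to-high expressors as in real upper-quartile-filtered data).
Planted classes set the effect triple `(δ_N1, δ_N2, δ_ND)`:
null `(0,0,0)`; NDKO-exclusive `(0,0,±δ)`; additive `(±δ/2,±δ/2,±δ)`;
alpha-dominant `(±δ,0,±δ)`; beta-dominant `(0,±δ,±δ)`, with
`δ = log2(3)` by default — a 3-fold effect, clearly past the 1.5-fold DEG
threshold, matching the magnitudes highlighted for clear targets in this
kind of study. Four replicates per genotype mirror the standard design.
Replicate dispersion is not something published TPM tables report, so the
default `replicate_sd = 0.15` log2 units is a module choice: small enough
that a 3-fold effect is essentially always detected at n = 4, large enough
that p-values are non-trivial.

Class counts are allocated by largest remainder (so they equal the rounded
fractions and sum exactly to `n_genes`), assigned to gene indices in order —
downstream stages are permutation-invariant over genes, so randomising the
assignment would only complicate truth bookkeeping. A single seed drives
all randomness. `tpm_rescale` (off by default) rescales each column to sum
to 10⁶: true TPM normalisation, but it perturbs the planted fold changes
compositionally, which is precisely why it exists as a robustness toggle
rather than a default.

What the generator does **not** emulate: read-level sampling noise
(mean–variance coupling of counts), library-size or GC bias, correlated
gene modules, and outlier replicates. Passing recovery tests on this
generator therefore demonstrates that the pipeline's arithmetic and
thresholds do what they claim under clean log-normal noise — not that the
thresholds are optimal for any particular real dataset.

`simulate_bioluminescence()` produces
`y(t) = mesor + slope·t + A·e^{−λt}·cos(2π(t−φ)/τ) + noise` on a 20-min
grid over 96 h by default — a damped, drifting, noisy version of a
synchronised reporter culture. The damping is in the simulator but not in
the fit (see above), intentionally stressing the fit's robustness.

## Problem sizes and numerical tolerances

The test suite runs the full workflow at sizes chosen to make every check
fast and airtight rather than impressive: 2,000-gene studies for recovery
and error-rate properties, exhaustive hypergeometric enumeration for all
universes up to N = 60, 100 seeded replicates for stochastic cosinor
recovery, and noiseless closed-form cases asserted to 10⁻⁶ or machine
precision. Determinism is checked end to end by byte-comparing all pipeline
outputs across two runs with the same seed; the run manifest records
parameters, seed, package version and MD5 checksums of all inputs and
outputs for the same purpose.

## Known limitations

* The DEG machinery is threshold-based by design; it does not provide
  shrinkage, dispersion modelling or FDR-controlled discovery, and should
  not be used as a substitute for count-model inference when raw counts are
  available.
* The amplitude of strongly damped rhythms is systematically
  underestimated by the undamped cosinor (quantified above).
* Gene identifiers are matched case-sensitively throughout; harmonise case
  at read time (`read_gmt(..., toupper = TRUE)`) when mixing sources.
* The genotype vocabulary is fixed to `WT`/`N1KO`/`N2KO`/`NDKO`; map other
  schemes onto it when building the design table.
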