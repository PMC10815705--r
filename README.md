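# kodeg

Tools for dissecting **redundant versus isoform-specific gene regulation**
from a wild-type / single-knockout / double-knockout expression design, with
companion utilities for circadian reporter assays. The motivating setting is
a panel of cell lines in which one or both of a pair of paralogous
transcriptional repressors — e.g. the circadian nuclear receptors REV-ERBα
and REV-ERBβ, encoded by *NR1D1* and *NR1D2* — have been ablated
(genotypes `WT`, `N1KO`, `N2KO`, `NDKO`), and the question is which target
genes each paralog controls alone, which are buffered by redundancy, and
which respond additively.

The package is aimed at analysts who already have gene-level TPM
(transcripts-per-million) matrices and want a transparent, fully testable
version of the standard threshold-based workflow, plus the wet-lab-side
quantifications that usually accompany such a study (bioluminescence rhythm
fitting, dual-luciferase normalisation, comparative-Ct qPCR).

## What it computes

**Differential expression.** After keeping the upper expression quantile of
genes (top 25% by mean TPM by default), each mutant genotype is contrasted
against WT per gene: fold change `FC = mean(TPM_mut) / mean(TPM_WT)` and a
two-sided pooled-variance Student's *t* on `log2(TPM + 1)` with
`df = n1 + n2 − 2`. A gene is a DEG when `FC > 1.5` and `p < 0.05`
(down: `FC < 1/1.5`), with strict inequalities and no multiple-testing
correction in the flags (BH q-values are reported alongside).

**Isoform-dominance classification.** Every double-knockout DEG is assigned
one class per direction:

| class | criterion (up direction) |
|---|---|
| `alpha_dominant` | DEG in N1KO and NDKO, and `FC_N2KO < 1.3` |
| `beta_dominant` | DEG in N2KO and NDKO, and `FC_N1KO < 1.3` |
| `ndko_exclusive` | DEG in neither single knockout |
| `shared` | anything else (significant in singles but not dominant) |

The down direction mirrors this with reciprocal bounds (`FC > 1/1.3`).
`venn_summary()` tabulates all seven intersection cells of the three DEG
sets and the NDKO-exclusive percentage `100·|NDKO only|/|NDKO|`.

**Gene-set overrepresentation.** For a query list against a GMT library
within a universe of `N` expressed genes, the one-sided Fisher's exact
(upper-tail hypergeometric) p-value `P(X ≥ k)`, `X ~ Hypergeom(N, K, n)`,
with per-library BH adjustment and ENRICHR-style `% overlap = 100·k/K`.

**Cosinor rhythmometry.** Ordinary least squares of
`y = M + b·t + β_c cos(2πt/τ) + β_s sin(2πt/τ)`; amplitude
`A = √(β_c²+β_s²)`, acrophase `φ = (τ/2π)·atan2(β_s, β_c)` in `[0, τ)`,
relative amplitude `100·A/M` (% of mesor) reported only when the F-test of
`(β_c, β_s) = 0` gives p < 0.05, otherwise N/A. Optional grid search for τ
over 20–28 h.

**Synthetic data with planted truth.** `simulate_expression()` builds a
4-genotype × 4-replicate TPM matrix with genes planted as null /
NDKO-exclusive / additive / alpha-dominant / beta-dominant (log2 effects
applied before exponentiation, so fold changes are exact), and
`simulate_bioluminescence()` produces damped-cosine reporter traces sampled
every 20 min. Both return/accompany truth tables so recovery is measurable.

## Worked example

```r
library(kodeg)

sim <- simulate_expression(sim_config(n_genes = 1000, seed = 42))
sim$study
#> ExpressionStudy: 1000 genes x 16 samples
#> samples per genotype: WT=4, N1KO=4, N2KO=4, NDKO=4

ct <- contrast_all(filter_expressed(sim$study, quantile = 1.0))
venn_summary(ct)
#>   direction n_N1 n_N2 n_ND n1_only n2_only nd_only n1_n2 n1_nd n2_nd all3
#> 1        up   39   39  100       0       0      41     0    20    20   19
#> 2      down   39   39  100       0       0      40     0    21    21   18
#>   ndko_exclusive_pct
#> 1                 41
#> 2                 40

table(classify_isoforms(ct)$class)
#> alpha_dominant  beta_dominant ndko_exclusive         shared
#>             40             40             81             39
```

With the default simulation 8% of genes are planted NDKO-exclusive (here 81
of 1000 recovered, 41 up + 40 down — one additive gene leaks in), 4% in
each dominant class (all 80 recovered), and the `shared` class collects the
planted additive genes whose half-effects reach significance in the single
knockouts. The `ndko_exclusive_pct` column is the study's headline measure
of redundant regulation.

```r
ts <- simulate_bioluminescence(biolum_sim_config(
  mesor = 120, amplitude = 25, acrophase = 18,
  damping_rate = 0.005, noise_sd = 2, seed = 42))
cosinor_fit(ts)
#> cosinor fit (n = 289, period = 24.00 h)
#>   mesor 119.5  amplitude 19.74  acrophase 18.001 h  trend 0.001732/h
#>   rhythmicity p = 2.27e-202; relative amplitude = 16.52% of mesor
```

The acrophase is recovered to 0.001 h; the amplitude estimate (19.7 vs the
planted initial 25) is the record-average of the damped envelope — see the
vignette for why the classical undamped cosinor behaves this way.

An end-to-end run (`filter → contrasts → venn → classify → enrich`) with a
reproducibility manifest:

```r
run_pipeline(list(simulate = list(n_genes = 2000), seed = 1,
                  gmt = list(kegg = "path/to/library.gmt")),
             outdir = "results/run1")
```

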