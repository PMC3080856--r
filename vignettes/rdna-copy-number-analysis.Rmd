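---
title: "Methods: analysing genome-wide expression responses to rDNA copy-number variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing genome-wide expression responses to rDNA copy-number variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdnasense)
```

## The scientific question

The ribosomal DNA (rDNA) locus is a tandem array of rRNA genes whose copy
number varies widely between chromosomes and individuals. In *Drosophila
melanogaster* the Y chromosome carries one of the two rDNA arrays, and
laboratory-induced deletions within it provide an allelic series — a wild-type
array, two mild deletions near 87% and 85% of wild-type copy number, and one
gross deletion near 46% — on an otherwise isogenic background. `rdnasense`
implements the analysis chain used to ask what such deletions do to the rest
of the transcriptome: which genes respond, how response magnitude scales with
deletion severity, whether the same genes respond in males and XXY females,
whether responding genes cluster near heterochromatin or anywhere else in the
genome, how many small-effect genes the experiment must have missed, which
functional categories are over-represented, and how the rDNA copy number
itself is quantified by qPCR.

Every stage runs on simulated data with the statistical structure of the real
study, so the full pipeline is testable end to end without any external data.

## The simulated study design

`generate_annotation()` scatters genes over a fly-like cytological map: six
arms (X, 2L, 2R, 3L, 3R, 4) with euchromatic lengths 22, 23, 21, 24, 28 and
1.3 Mb, genes placed uniformly within arms chosen proportionally to length,
and positions binned into the 102 cytological divisions by linear division of
each arm. The default gene count, 8073, matches the number of unique gene IDs
analysed in the study this package emulates.

`generate_truth()` marks a fraction of genes (default 10%) as
*rDNA-sensitive* and draws their base log2 fold-change — the effect under the
gross deletion — from a zero-mean Gaussian truncated at ±2. The default SD of
0.4 was chosen once, from the inverse-normal calculation
`0.585 / qnorm(0.925) ≈ 0.4`, so that about 85% of sensitive genes change by
no more than 50% on the natural scale (`|2^e − 1| ≤ 0.5`), matching the
small-effect profile the experiment reports. Each genotype's effect is the
base effect times a severity factor, by default 0 (wild type), 0.3 and 0.35
(mild deletions) and 1.0 (gross). The factors are free simulation parameters,
not claims about biology: they are fixed so that mild DE sets nest inside the
gross set under realistic noise. Signs are therefore consistent across
genotypes by construction, which is the property the concordance analyses are
designed to detect. Females are emulated by a global `effect_scale`
attenuation (default 0.6 where used) rather than a mechanistic model: the
package asserts only that the same genes respond more weakly, not why.

`make_design()` mirrors the study's array topology: each deletion genotype is
hybridized directly against wild type, with dye orientation alternating
across replicates so every comparison is dye-balanced. The replicate count
(default 6 per comparison) is configurable because the source design figure
gives no machine-readable count.

`simulate_arrays()` composes each spot's log ratio as true effect difference
+ dye bias + Gaussian noise (default SD 0.2 on the M scale), then
reconstructs channel intensities around an average log2 intensity drawn from
N(10, 1.5²). The dye bias is a low-order polynomial in centred A (default
`0.2 − 0.1·z + 0.05·z²`), deliberately smooth so that loess normalisation has
a real, removable artefact to remove. Spot morphology, background and scanner
artefacts are not modelled; intensities are generated directly at the
foreground level. A small fraction of spots (default 2%) is flagged as
failing QC at random — real QC failure is not random, so tests passing here
say nothing about robustness to structured missingness.

## Normalisation and differential expression

`loess_normalize()` regresses M on A within each hybridization (degree-1
loess, span 0.4, symmetric family with three robustness iterations) and keeps
the residuals. The span and iteration count follow common two-colour
practice; when the residual spread is degenerate (noise-free synthetic data)
the robust weights are undefined and the fit falls back to least squares.

Each contrast is a *direct* comparison, so `fit_contrast()` reduces to
oriented per-gene means: M values are signed mutant-minus-reference, and a
gene is tested only with at least `min_obs = 2` usable observations.
`moderate_and_test()` implements the empirical-Bayes moderated t: the
per-gene variances are modelled as draws from a scaled inverse-chi-square
prior whose parameters (d0, s0²) are estimated by matching the mean and
variance of `log(s2)` across genes, inverting the trigamma function by Newton
iteration. The posterior variance `(d0·s0² + df·s2)/(d0 + df)` feeds
`t = log_fc / sqrt(s2_post/n)` on `df + d0` degrees of freedom. Numerical
choices: d0 is capped at 1e6 (an effectively infinite prior); when the
log-variances have (numerically) zero spread the prior is a point mass at the
common variance, so the shrinkage target equals the data; when every variance
is exactly zero the test falls back to a machine-precision prior with a
warning. With `prior_df = 0` the statistic is the ordinary one-sample t,
which the tests exploit as an oracle; the estimation path is cross-checked
against an independent implementation of the same moment-matching scheme.
Because each contrast is a single coefficient, the moderated F of the
original analysis is simply the square of this t.

Multiplicity is handled twice, as in the study: `adjust_bh()` applies the
Benjamini–Hochberg step-up per contrast, and `permutation_fdr()` estimates
the FDR empirically by re-signing whole hybridization M vectors — a valid
null for dye-balanced direct designs — and counting discoveries in each
permuted dataset. `call_de()` thresholds on raw p (ladder 0.05/0.01/0.005/
0.001) and optionally adjusted p (< 0.05), recording each member's direction.

## Concordance between contrasts and sexes

`mc_overlap_null()` draws, per replicate, two independent uniform subsets of
the observed DE-set sizes and counts their intersection; the empirical
p-value uses the add-one convention `(1 + #{null ≥ k})/(reps + 1)` so it is
never zero. Its closed-form counterpart `hypergeometric_overlap()` is kept
strictly separate so the Monte-Carlo path can be validated against it rather
than silently replaced by it. The universe is an explicit parameter
everywhere: the appropriate universe (genes tested in both contrasts, union,
or a custom list) is a genuine analysis decision, and the pipeline defaults
to the intersection of tested genes. `permuted_dataset_overlap()` provides
the complementary "shared by chance" expectation by permuting both datasets
and intersecting the permuted DE sets. `direction_table()` (Fisher's exact
test over the shared genes' up/down signs), `foldchange_correlation()`
(Spearman with average-rank ties and the large-sample t p-value, signed or
absolute, over all genes or a DE filter — both modes exist because the
original figures do not say which was used; the pipeline correlates over the
gross-deletion DE set, the reading consistent with a fold-change scatter of
DE genes) and `multiway_sharing()` (fraction of the union in ≥ k sets, plus
Venn cells for up to three sets) complete the module.

## Positional analyses

`division_profile()` bins DE and represented genes into the 102 cytological
divisions and reports their ratio, so positional structure is always read
against array representation rather than raw counts; `scanning_average()`
smooths such series with a centred 5-division window truncated at arm ends
(no wraparound — the edge behaviour had to be chosen, and truncation keeps
the smoothed series unbiased at boundaries at the cost of higher variance
there). `sliding_window_scan()` tiles each arm with 2-Mb windows at 1-Mb
steps (half-open intervals, final window truncated at the arm end so the
tiling covers every gene), and compares each window's DE count with the
counts from 1000 random gene sets of the DE-set's size drawn from the
represented genes. The default per-window null matches a per-increment
reading of the original analysis; a max-over-windows family-wise mode is one
flag away, because per-window p-values are multiplicity-naive by design.
`boundary_check()` ranks an arm's genes by distance from either end and
scores the nearest 20 against a binomial reference, emulating the
heterochromatin-transition and telomere checks. `arm_frequency_test()`
compares per-arm DE counts with representation-proportional expectations
(chi-square, with an exact binomial fallback when expected counts are small).

## Detection extrapolation

`decile_histogram()` bins DE genes by relative change `(2^{|log2 FC|} − 1)`
into 10-percentage-point bins; "decile" here means these fixed bins, with
half-open lower-inclusive edges, and fold-changes are folded through the
absolute log ratio. `project_first_decile()` fits ordinary least squares of
the four counts for 10–50% change on bin index (x = 2..5; index rather than
bin midpoint — the two are affinely equivalent) and evaluates at x = 1;
non-positive projections from increasing profiles are clamped to zero with a
flag. `estimate_missed()` subtracts the observed first-decile count. The
logic assumes detection power is essentially complete above 10% change and
that the true count profile is locally linear; the parameter-recovery test
builds exactly such a regime and checks the estimate against known truth.
The real experiment's reported ranges depend on its real data and are not
reproduction targets at desk scale.

## Enrichment and copy number

`category_enrichment()` tests flat category labels (no ontology DAG) with
one-sided hypergeometric tails. The "modified Bonferroni" of the enrichment
tool the study used is implemented as multiplication by the number of
categories containing at least one DE gene — the documented behaviour of
that tool — with plain Bonferroni over all categories available as an
option, since the exact multiplicity denominator of the original run is not
recoverable.

`relative_copy_number()` applies single-reference `efficiency^ΔCt`
quantification to Ct tables (technical replicates averaged within biological
replicates; mean ± SD across biological replicates; reference pinned at
100%). No normaliser locus is required because the emulated assay design
(C(1)DX/Y females carrying only Y-linked rDNA) makes the 18S signal directly
comparable; an optional normaliser column would be a straightforward
extension. Amplification efficiency is configurable in (1, 2] but not
estimated from dilution series.

## Orchestration, seeds and problem sizes

`run_config()` + `run_full()` execute the whole chain from one validated
configuration; the package's functions and this vignette are the interface —
there is no shell entry point, because the artifact is an analysis library,
not a command-line tool. One global seed expands into per-stage seeds by a
fixed integer hash of the stage name, so any stage can be re-run in
isolation; every TSV written carries a `.prov` sidecar with parameters and
seed. All generators are bit-reproducible given (parameters, seed).

The shipped defaults analyse 8073 genes with 6 replicates per comparison,
10,000 overlap-null replicates and 1000 window-scan random sets — the full
study-scale configuration, which runs in seconds. The test suite uses
smaller gene counts (300–8000) chosen to keep each statistical check's power
adequate for its assertion; the acceptance checks state their sizes inline.

## Known limitations

* The simulator draws effects independently across genes; co-regulation,
  correlated noise between genes and print-tip or batch structure are absent,
  so passing tests bound only what they model.
* QC dropout is independent and uniform, unlike real quality failure.
* The female model is a scalar attenuation of male effects.
* Permutation null is sign-flipping, which assumes symmetric noise on M.
* Categories are flat labels; GO-style propagation is out of scope.
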