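---
title: "Integrating copy number, DNA methylation and expression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating copy number, DNA methylation and expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

# The analysis

`triomics` implements an integrative analysis of three molecular layers
measured on the same panel of cancer cell lines — segmented DNA copy
number, array DNA methylation (beta values) and array mRNA expression on a
variance-stabilized (vst, approximately log2) scale — against a small set
of normal control cultures. The pipeline has five analytical stages, each
usable on its own:

1. **Per-sample aberration calling.** Each gene in each sample is scored
   on six binary channels. Copy number: a gene overlapping a segment with
   mean log-ratio at or above 0.2 is *gained*, at or below -0.2 *lost*
   (the high-gain category at 0.6 merges into gain, homozygous loss at
   -1.0 into loss). Methylation: deltaBeta, the case beta minus the mean
   control beta, strictly above 0.4 is *hyper-methylated*, strictly below
   -0.4 *hypo-methylated*. Expression: the vst ratio (case minus control
   mean on the log-like scale) strictly above 1 is *over-expressed*,
   strictly below -1 *under-expressed*. Probes collapse to genes by
   inclusion: a gene inherits the call of any of its probes, so probes in
   opposite directions put the gene on both lists. Ties at the cuts are
   not called — strict inequalities exactly as the cuts are stated.

2. **Integration and recurrence.** With two aberration types per platform
   there are 12 two-way and 8 three-way cross-platform combinations. A
   gene's recurrence count for a combination is the number of samples
   carrying all its channels simultaneously. Genes reaching the
   recurrence threshold k = 6 of 19 samples (>30%) in any of the four
   expression-consistent pairs (gain/over, hypo/over, loss/under,
   hyper/under) are selected; the *union rule* then adds genes for which
   over-expression with (gain OR hypo-methylation), or under-expression
   with (loss OR hyper-methylation), reaches k even though no single pair
   does — copy number and methylation acting as alternative mechanisms
   for the same expression change.

3. **Dependency statistics.** Within each sample, every two-way
   combination is cross-tabulated over the gene universe into a 2x2 table
   (a = both, b, c = one only, d = neither). The odds ratio ad/bc
   measures association (>1 positive, <1 negative); significance comes
   from the 1-df Pearson chi-square, adjusted within the sample's
   12-combination family. A three-way analysis conditions
   hyper-methylation-versus-expression tables on the three-state copy
   number (gain/normal/loss), asking whether the methylation-expression
   coupling differs by dosage context.

4. **Copy-number frequency versus gene density.** Cohort gain- and
   loss-frequency tracks are built on the union of all samples' segment
   breakpoints. The test statistic is the base-pair-weighted mean track
   value over gene-covered bases; the null distribution permutes the
   segment values over the fixed segment positions (Monte Carlo, 1,000
   samples). One-sided alternatives: gain frequency *higher* in
   gene-covered regions, loss frequency *lower*. The same test runs per
   chromosome arm.

5. **Differential analysis and clustering.** Cohort-level differential
   methylation uses M-values (log2 beta odds) and plain two-sample
   t-tests against the controls, with BH-adjusted p < 0.05 and |fold|
   > 6; expression analogously with |fold| > 0.5 on the vst scale.
   Samples are clustered hierarchically with Spearman-correlation
   distance (1 - rho) and complete linkage; the selected-gene heat-map
   companion uses Euclidean distance on expression profiles.

# The synthetic cohort

Real three-platform panels of this design are not redistributable at
package scale, so every stage is exercised on a seeded generator with
planted ground truth. Its defaults *are* the emulated study conditions:
19 case samples, 2 control cultures, 22 autosomes with 538 genes each
(11,836 genes, echoing an ~11.8k-gene shared platform universe), 1-2
methylation and expression probes per gene, and a 39-arm family (the five
acrocentric autosomes carry no p-arm genes).

The generator works in four seeded, platform-independent RNG streams
derived from the master seed, so enlarging one platform never perturbs
another:

* **Genome.** Chromosomes are tiled with 250 kb windows carrying a
  density weight field (smoothed log-normal; flat when `density_bias =
  0`). Genes (~12-26 kb) are allocated to windows in proportion to the
  weights, so base-pair gene coverage tracks the stored density field.
  The centromere sits at a fixed 0.4 of the chromosome length — arms are
  needed only for per-arm testing, not biology.
* **Copy number.** Per sample, breakpoints fall uniformly along the
  chromosome and are snapped out of gene bodies (no gene straddles a
  breakpoint, so per-gene truth is unambiguous, and segmentation stays
  independent of gene placement — this independence is what makes the
  permutation test's null hold exactly under zero bias). Each segment is
  gained with probability 0.18 and lost with probability 0.10 on the
  logit scale, shifted by `2 * density_bias * z` where z is the
  standardized local log-density — gains toward gene-rich, losses toward
  gene-poor regions. Segment values are the state effect (+/-0.5
  log-ratio) plus Gaussian noise (SD 0.1).
* **Methylation.** Beta values arise from a latent normal passed through
  the logistic map, so they live strictly in (0,1) and the deltaBeta cut
  is meaningful at both ends of the range. Planted hyper/hypo shifts are
  computed per probe on the latent scale so that the *beta-scale* shift
  equals the configured effect (0.55 by default) exactly at zero noise.
* **Expression.** vst-scale values couple additively to the copy-number
  state (+0.5 per state unit, the log2(3/2) dosage scale) and to the true
  methylation shift (coefficient -1: hyper-methylation represses), plus
  planted over/under shifts (+/-2) and Gaussian noise (SD 0.3).

Planted sets default to the four expression-consistent pairs (30 + 30 +
10 + 10 genes in 7-8 of 19 samples), a gain/hyper/under triple (16 genes)
and a 15-gene *split-mechanism* set whose over-expression comes with gain
in half the affected samples and hypo-methylation in the other half — the
situation the union rule exists to catch. A configuration whose planted
effects do not clear their calling thresholds by at least two noise SDs
is rejected as unsatisfiable rather than silently generating
unrecoverable truth.

## What the generator does not emulate

Array noise physics (probe affinity, background correction, batch),
SNP-level allele structure, chromothripsis-like rearrangements, the
bimodal genome-wide beta distribution of real CpG panels, and biological
heterogeneity between cell lines beyond the planted sets. Passing tests
therefore demonstrate the *algorithms* behave as specified on data with
the study's statistical structure, not that the thresholds are optimal
for any particular array platform.

# Design decisions

* **"Ratio" as difference.** The expression cut of +/-1 is applied to
  the difference of vst values (a log fold change). A literal ratio of
  intensities could never be negative, so the printed lower cut only
  makes sense on the log-like scale; deltaBeta is likewise a difference
  by definition.
* **Boundary semantics.** Probe cuts are strict (0.40 exactly is not
  called); gene copy-number cuts are inclusive (a segment at exactly 0.2
  is gain). Copy-number conflict (a gene spanning segments in opposite
  states) lists the gene in both channels with a flag; its three-state
  assignment takes the maximally overlapping segment.
* **Multiple-testing family.** The family is the 12 combinations (or the
  strata-by-states tests) *within one sample*, matching the per-sample
  presentation of the dependency heat maps. Both BH and Bonferroni are
  implemented; BH is the default because significance is displayed with
  BH in the heat maps, while the running text states Bonferroni — the
  method used is always recorded in the output.
* **Zero cells.** The default odds-ratio policy adds 0.5 to every cell
  of a table containing a zero (Haldane); `policy = "none"` reports the
  infinite/undefined value with a flag. Sparse tables make the corrected
  odds ratio biased away from 1, which is why dependency conclusions on
  sparse channels should lean on the chi-square significance, not the
  point estimate.
* **Permutation p-values** use the add-one estimator
  (1 + exceedances)/(n_perm + 1), never exactly zero; a zero-exceedance
  run at 1,000 permutations reports p < 0.001.
* **Mean-in-regions weighting.** The statistic weights segment values by
  the number of gene-covered bases; overlapping genes are flattened
  first so dense loci are not double-counted. A segment-weighted variant
  (plain mean over segments touching a gene) is available behind
  `weighting = "segment"` since the original description does not
  disambiguate; bp weighting is the default as the less
  segmentation-dependent reading.
* **Spearman distance** is 1 - rho (not 1 - |rho|, not (1 - rho)/2);
  anti-correlated samples are maximally distant. Recorded in the `dist`
  object's `method` attribute.
* **Plain t-tests** (pooled variance by default, Welch optional) stand
  in for moderated array tests by design: the procedure specifies
  t-tests, and with n = 2 controls a variance floor (`var_floor`) guards
  degenerate probes.
* **M-value fold cut.** The methylation cut of 6 is read as |delta M| >
  6 on the M scale — the reading under which the cut is commensurate
  with the M-value t-tests; it corresponds to nearly saturating
  promoter methylation shifts (e.g. beta 0.1 to 0.9 is delta M of about
  6.3), which is why the per-sample deltaBeta calling (cut 0.4) detects
  far more genes than the cohort-level differential filter.

# Evaluation conditions

Where the package's own checks need a *null*, it is a cohort with
nothing planted, `density_bias = 0`, and (for channel-independence nulls)
the cross-platform coupling coefficients set to 0. Planted-recovery
sensitivity and false-discovery proportion are evaluated against the
planted list on a `density_bias = 0` cohort: with the bias on, regionally
recurrent background gains coupled to expression by dosage legitimately
produce recurrent gain/over genes — as real cohorts do — so the planted
list is only a complete truth set when the planted sets are the sole
recurrent signal.

Problem sizes used by the test-suite and acceptance computations are the
package's own choices: full-size cohorts (22 chromosomes, 11,836 genes)
for single end-to-end runs; compact cohorts (4-10 chromosomes, 50-180
genes per chromosome) wherever a property is checked across many seeded
replicates (200 replicates for permutation calibration, 25-50 for
dependency and differential null rates); exhaustive enumeration for the
odds-ratio/chi-square/BH oracles (all 2x2 tables up to n = 8) and the
permutation-test oracle (all 720 value permutations of a six-segment
track).

# Known limitations

* The chi-square test is asymptotic; on sparse channels (few calls per
  sample) its p-values and the Haldane odds ratio are both unreliable,
  and the package reports degenerate-margin tables as not testable
  rather than switching to an exact test (which the emulated procedure
  did not use).
* The union of per-sample segment breakpoints makes cohort frequency
  tracks spatially autocorrelated; the permutation test conditions on
  the observed segmentation, as the original track-analysis framework
  does, and its null calibration is verified empirically by simulation.
* Gene-level collapse keeps no probe weights: one aberrant probe flags
  the gene regardless of how many probes disagree (by design, matching
  the inclusion rule).
* The generator's effect-size defaults are tuning parameters of the
  emulation, not estimates of any real platform's aberration sizes.
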