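---
title: "Methods: cross-species enhancer conservation and the in-silico-mutagenesis selection test"
author: "ehourglass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer conservation and selection scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Comparative embryology repeatedly finds an "hourglass": embryos of related
species diverge more at early and late stages of development than in
mid-embryogenesis (the phylotypic period). `ehourglass` implements a pipeline
for asking two questions about the *regulatory* side of that pattern, using
chromatin-accessibility peaks (DNase-seq style) sampled at five matched
embryonic stages (`TP1`–`TP5`) in two species:

1. **Conservation.** Are stage-specific enhancers (distal accessible regions
   used at exactly one stage) more often conserved between species at the
   mid-embryonic stage than at the flanks?
2. **Positive selection.** Do enhancer sequences show lineage-specific
   substitutions that *consistently* push predicted accessibility up or down
   — the signature of directional selection — and is that signature depleted
   at the mid-embryonic stage?

Because the real inputs (genome-scale peak sets, whole-genome alignments,
population SNP panels) cannot be redistributed or recomputed at desk scale,
the package pairs every analysis step with a synthetic-data generator that
emulates those inputs with known ground truth. All tests and the acceptance
script run against that generator; what they demonstrate is that the
*machinery* is correct and calibrated under the generator's assumptions, not
that any particular biological claim holds in real data.

# The synthetic world

`make_two_species_world()` builds everything the pipeline consumes:

* **Genomes and peaks.** Two species ("A", the focal species, and "B"), one
  chromosome each, assembled from interleaved units: stage-specific
  enhancers (300 bp, default 60–80 per stage), multi-stage ("pleiotropic")
  peaks, TSS-proximal peaks with their TSS points, and unaligned spacers.
  Units never overlap, so stage-specificity truth labels are exact.
  A fraction of spacers is lowercased to emulate repeat masking.
* **Enhancer sequence.** Each stage has its own set of position weight
  matrices (default 3 motifs, width 8, mean information content 1.3
  bits/column — the range typical of animal transcription-factor motifs).
  An enhancer is i.i.d. background at 40% GC with 4 motif instances planted
  at non-overlapping positions. The *true accessibility score* of a sequence
  is the sum over motifs of the best log-odds match on either strand. This
  scorer is deliberately different from the gapped k-mer model the pipeline
  trains, so classifier performance measures genuine generalization.
* **Alignment block map.** Conserved enhancers sit inside aligned blocks
  shared by the two genomes; a configurable fraction of those blocks is
  split by a partner-side insertion, and all inter-unit gaps differ in
  length between species, so coordinate translation must genuinely project
  through blocks rather than add an offset. Partner-side spacing between
  units exceeds 1 kb so that the `<1 kb` conservation definition is decided
  by partner placement, never by unrelated neighbors.
* **Evolution.** Each focal-species enhancer descends from a simulated
  ancestor; the focal, sister and outgroup sequences evolve independently
  from it by a fixed-count substitution process: the count is drawn from the
  branch length (defaults 0.05/0.05/0.12 substitutions per site — the
  within-group divergence of a close focal/sister pair with a slightly more
  distant outgroup, leaving ~15 substitutions per 300-bp enhancer), positions
  are distinct
  and uniform, and the alternative base is drawn with transition weight
  `kappa` (default 3, the classic 3:1 transition:transversion bias). No
  indels are simulated within triples, because the statistic only scores
  substitutions; indels live in the between-species block map instead.
* **Selection.** Under `selection_mode = "up"` (or `"down"`), a proposed
  focal-branch substitution with true-score effect `d` fixes with
  probability `plogis(strength * (±d - drift_threshold))`, resampling until
  the target count is reached. The drift threshold (default 0.5 bits)
  encodes the population-genetic regime of interest: under strong selection,
  effectively neutral changes rarely fix relative to beneficial ones, so
  fixed substitutions are enriched for directional effects. Without it, a
  max-based fitness landscape would let effect-free background substitutions
  (accepted with probability one half) swamp the signal, and conditioning on
  the substitution count would leave directional selection undetectable by
  construction.
* **Polymorphism.** SNP counts are Poisson(`theta` × length) with `theta` =
  0.01/bp (typical *Drosophila*-scale nucleotide diversity); enhancers under
  positive selection are thinned by `sweep_factor` (default 0.3), emulating
  the reduced segregating variation left by a selective sweep.
* **Hourglass configuration.** Defaults place the conserved fraction at
  0.25/0.25/0.5/0.25/0.25 across `TP1`–`TP5` and the selected fraction at
  0.25/0.25/0.05/0.25/0.25, with selection assigned to nonconserved
  enhancers at 3:1 odds relative to conserved ones.

All randomness flows from one root seed through named substreams
(`substream_seed()`), so any component can be regenerated independently and
whole worlds are bit-identical under a fixed seed.

# The accessibility model

The classifier is a linear model over *gapped k-mer* features: every L-bp
window (default `L = 10`) contributes one count to each of the
`choose(L, k)` placements of `k` informative positions (default `k = 6`).
Features are canonicalized against reverse complementation — a feature and
its reverse complement under the reversed mask share one index — which makes
`featurize(s)` and hence every downstream score *exactly* strand-symmetric
(the weight table and window summation are additionally symmetrized so the
equality is bit-for-bit, not just to rounding).

Training solves a ridge regression on ±1 labels (least-squares SVM form)
in the dual: per-sequence L2-normalized counts, gram matrix, and an
`(n+1)`-dimensional linear solve with an unpenalized intercept. The
regularization is scaled per sample (`lambda * n`), which makes balanced
duplication of the training set a no-op on the fitted weights. Working in
the dual keeps the ~860,000-dimensional feature space implicit during
training while still yielding explicit primal weights, from which a dense
table of all `4^L` word weights is expanded once per model (about 8 MB at
`L = 10`) for fast scoring and permutation work.

The scoring contract is the one the selection statistic needs:
`score(seq) = sum over L-windows of weight(window) + intercept`, with
`weight(word)` the dot product of the model weights with the word's
single-window features. Windows containing non-ACGT characters are skipped
and counted. Matched negatives are rejection-sampled from the genome with
identical length and GC/repeat-fraction tolerances (0.02 and 0.1), widening
stepwise with a warning when a positive is unmatchable.

# The selection test

For each enhancer with a focal/sister/outgroup alignment:

1. **Ancestor inference** is column-wise parsimony with the outgroup
   breaking ties: agreement keeps the base; focal≠sister with the outgroup
   siding with the sister is a focal-branch substitution; siding with the
   focal places the change on the sister branch; three-way disagreements,
   gaps and ambiguous bases are excluded from calling (the ancestor keeps
   the focal base, and excluded positions are barred from null sampling).
2. **deltaSVM** is `score(focal) − score(ancestor)`; the intercept cancels
   and, by linearity, only windows overlapping substituted positions
   contribute (a property the tests verify against brute-force
   enumeration).
3. **The empirical null** re-introduces the same number of substitutions at
   distinct, uniformly chosen non-excluded positions, with the alternative
   base drawn uniformly, with a 3:1 transition bias, or from the estimated
   substitution spectrum; the deltaSVM of each pseudo-focal sequence yields
   the null sample (default 10,000 permutations; the test suite and the
   analysis scripts use 500–1,000 to keep runtimes in minutes at their
   problem sizes).
4. **p-values** use the pseudo-count estimator `(r + 1)/(N + 1)` rather than
   the raw exceed fraction, so they are never zero and remain valid; the
   upper tail (selection for *stronger* accessibility) is the default, with
   lower and two-sided variants available because directional selection can
   point either way. q-values are Benjamini–Hochberg within each tested set
   and `q < 0.05` defines a positive call. Enhancers with fewer than two
   applied substitutions are dropped (counted after dinucleotide exclusion
   when that control is on — the stricter choice keeps the null comparable).
5. **Controls.** Adjacent (dinucleotide) substitutions can be excluded, and
   the substitution spectrum estimator reports opportunity-normalized rates
   split by CpG context (ancestral base participating in a CG dinucleotide)
   together with the transition/transversion ratio, so the ts/tv-weighted
   null can be matched to the data.

## Cross-fitted scanning

A model trained on the very enhancers it then tests memorizes their k-mers:
`score(focal)` is inflated relative to any perturbed version of the same
sequence, and since deltaSVM is exactly that contrast, the upper-tail test
becomes severely anticonservative (in simulation, neutral enhancers reach a
~50% positive-call rate when scored by a model trained on them). The
pipeline therefore *cross-fits*: each stage's enhancers are split into
folds, and every enhancer's deltaSVM and null are computed under a model
trained on the other folds' positives and matched negatives
(`cross_fit_test()`). In the end-to-end pipeline the Benjamini–Hochberg
correction is then applied over all tested enhancers of all stages as one
family — the whole scan is one experiment, and a shared threshold also keeps
per-stage call counts from being decided by each stage's own
discreteness cliff. This is a deliberate deviation from the simpler design
of training once per stage on all of its enhancers, and it is what makes the
end-to-end positive-call proportions interpretable.

## Calibration experiments

Two design choices in the calibration tests deserve explanation. First, the
type-I-error experiment trains its model on an *independent* sample of
enhancers from the same generative process, then tests freshly simulated
neutral enhancers — the same principle as the pipeline's cross-fitting,
taken to its clean extreme so the experiment isolates the null machinery. Second, the base-sampling mode is
matched to the generative process: neutral evolution simulated with
`kappa = 1` is tested against the uniform null, and `kappa = 3` against the
3:1 transition-weighted null. A deliberate mismatch (biased mutation,
uniform null) is exactly the situation the transition-bias control exists to
absorb, and the matched pairs are what a calibrated test must pass.

The substitution/polymorphism (divergence/diversity) validation pools counts
into a single 2×2 table — substitutions and polymorphisms, by positive /
nonpositive call — and applies a two-sided Fisher exact test with the sample
odds ratio. Exact-test p-values are discrete and therefore super-uniform
under the null; the calibration test checks exactly that (one-sided
Kolmogorov–Smirnov plus tail-rate bounds) rather than demanding strict
uniformity that no exact test satisfies.

# Conservation calling

All interval logic uses 0-based half-open coordinates and a strict
"≥ 1 bp" overlap predicate (touching intervals do not overlap). Distal
elements are peaks whose distance from every TSS point exceeds 500 bp
(strict, gap-to-nearest-edge). A peak is stage-specific iff no peak of any
other stage overlaps it. Translation projects every base of an interval
through the block map and reports the span of mapped bases with their count;
one-to-one behavior requires a single target chromosome, single strand and
colinear block order. Conservation is called in two modes — ≥ 1 bp overlap
with a same-stage-specific partner enhancer, or nearest edge-to-edge
distance strictly below 1 kb — and summarized per stage as proportions (over
species A, species B, and pooled, since the choice of denominator is a
reporting convention), the Jaccard index
`|conserved| / (|A| + |B| − |conserved|)`, and pairwise two-sided Fisher
exact tests against the mid-embryonic stage (raw p primary,
Benjamini–Hochberg q reported alongside). Enhancers overlapping both muscle
and neuron reference sets in the tissue split are flagged ambiguous and
excluded rather than assigned by an arbitrary precedence.

# Numerical choices and degenerate inputs

* Empirical p-values never reach 0 (pseudo-count estimator) and zero-margin
  Fisher tables report p = 1 with a flag.
* Jaccard with empty inputs is reported missing, not 0.
* The weight table is only materialized for `L ≤ 12`; strand symmetry is
  enforced bit-for-bit by symmetrizing the table and sorting window values
  before summation.
* Matched-negative sampling widens tolerances stepwise (×2, up to four
  times, with warnings) before failing.
* Substitution positions in the null are sampled without replacement among
  non-excluded positions; observed substitution positions stay eligible
  (exchangeability).
* Ancestor-call ties (three-allele columns) are excluded, never guessed.

# Problem sizes

The shipped analyses and tests run at reduced but statistically meaningful
sizes chosen for a single-CPU workstation: 80–150 enhancers per stage in
end-to-end worlds, 500 enhancers and 1,000–2,000 permutations in calibration
and power experiments (the method's reference permutation count is 10,000),
and 100–200 replicate worlds for the sweep-detection checks. Sizes are
stated in each script; scaling them up only tightens the Monte Carlo error
around the same expectations.

# Limitations

* Per-stage power depends on how learnable each stage's motif vocabulary is:
  with stage-distinct random motif sets, recovered per-stage positive-call
  rates confound the true selected fraction with motif learnability (in our
  simulations this varied several-fold between stages). The end-to-end
  recovery experiment therefore uses `shared_motifs = TRUE` to control that
  nuisance; in real data the analogous caveat is that between-stage
  differences in classifier AUC will distort per-stage positive-selection
  proportions.
* The generator's enhancers are motif-additive and its background i.i.d.;
  real regulatory sequence has correlated composition, repeats and
  context-dependent mutation. Passing tests demonstrate correctness and
  calibration under these assumptions, not robustness to everything real
  genomes do.
* The classifier is a regularized linear gapped k-mer model with the same
  scoring contract as a gapped k-mer SVM (a weight per 10-mer; deltaSVM as
  a sum-of-weights difference); it is not a binary-level reimplementation of
  any particular SVM package. An import path for externally produced 10-mer
  weight tables (`read_weight_table()`) provides parity runs.
* Parsimony ancestor inference is biased at high divergence (double hits,
  back substitutions); the test is intended for closely related focal/sister
  pairs, and the simulator exposes branch length so users can probe where
  calibration degrades.
* The selection test conditions on the observed substitution count, so it
  detects *directional* substitution effects, not elevated substitution
  rates; the substitution/polymorphism excess test is the complementary
  check on rates.
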