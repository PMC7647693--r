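---
title: "Predicting lysine succinylation sites from sequence context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine succinylation sites from sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysucc)
```

## The problem and the model

Lysine succinylation is a reversible post-translational modification with a
recognizable, if diffuse, substrate signature: succinylated lysines tend to
sit in flanking regions enriched for further lysines (most visibly at
positions -15..-1 and +6..+12 relative to the site) and depleted of
negatively charged residues (glutamate/aspartate) immediately around the
site. `lysucc` turns this signature into a classifier. Each candidate site
is a 31-mer window centered on a lysine (flank width `n = 15`); windows that
cross a terminus are padded with `-`, and pads (together with ambiguous
letters, which are collapsed to `X` on input) are excluded from every count
and denominator, so a near-terminal window is described only by the residues
it actually has.

Three encoders express a window's composition at increasing resolution:

* **AAC** — the 20 residue probabilities within the window.
* **AAPC** — the 400 adjacent dipeptide frequencies.
* **CKSAAP** — for every ordered residue pair at spacing `k = 1..5`, the
  occurrence count divided by the number of countable slots
  (`31 - k - 1` for a pad-free window), giving 2000 features in `[0, 1]`.

All three are compositions, so no further scaling is applied before the SVM.

## Attribute screening and selection

Two dataset-level screens mirror how practitioners inspect substrate
specificity before modeling. Dipeptides are contrasted between classes by
their pooled occurrence probabilities; a dipeptide is *significant* when the
probability difference exceeds 0.02 and a pooled two-proportion z-test (on
window-level presence, no multiple-testing correction) gives p < 0.05.
K-spaced pairs are summarized by the strength
`C = log(P+ / P-)` of their per-class conditional probabilities
`P(A_i x{k} A_j) = N(A_i x{k} A_j) / N(A_i x{k} *)`; we use the natural
logarithm (the ranking is base-invariant) and, when a pair is unseen in
either class, add a pseudocount of 1 to the pair count and 20 to its
denominator in both classes so the log-ratio stays finite without disturbing
the ordering of well-observed pairs.

For modeling, the 2000 CKSAAP attributes are ranked by greedy mRMR. Mutual
information is the plug-in estimator in bits, computed directly on the raw
integer pair counts — they take a handful of values per window, so no
binning rule is needed and the estimator is exactly the discrete form of the
defining double sum. The first attribute maximizes relevance to the label;
each later one maximizes relevance minus mean redundancy against the
already-ranked set, ties resolved by column order. Sequential forward
selection then scans prefixes of the ranking: at step *t* the top-*t*
attributes are cross-validated (10-fold, stratified, fixed SVM
configuration) and the prefix with the best MCC wins, with ties going to the
smaller attribute count. The budget defaults to 30 attributes. We rank once
and then scan prefixes rather than interleaving ranking with selection; the
interleaved variant would re-rank conditioned on the growing set, but with a
fixed mRMR criterion both orderings coincide, and the single ranking keeps
the pairwise-MI cost proportional to the budget. During selection the SVM
parameters stay at their defaults; tuning inside every SFS step would
multiply the cost roughly a hundredfold while the selection signal (relative
MCC between neighboring prefixes) is insensitive to it.

## Classifier, tuning and evaluation

The classifier is a C-classification SVM with RBF kernel
`K(x, x') = exp(-gamma ||x - x'||^2)` (so a Gaussian radius `s` corresponds
to `gamma = 1/(2 s^2)`), with `gamma = 1/n_features` when unspecified.
`grid_search()` scans the standard LIBSVM grid, `cost = 2^-5..2^15` by
`gamma = 2^-15..2^3` in steps of 4x (110 configurations), maximizing pooled
cross-validated MCC with ties resolved toward the smaller cost and then the
smaller gamma. No class weighting is applied despite the usual 1:3
positive:negative imbalance — MCC-based selection already balances the two
error types.

Probabilities come from a Platt-style sigmoid fitted to the training
decision values (with Platt's smoothed targets). We calibrate ourselves
rather than using the solver's built-in probability machinery because the
latter randomizes its internal cross-validation in a way that cannot be
seeded from R, and reproducibility of a stored model's predictions is part
of this package's contract. The sigmoid's slope is free to be negative, so
no decision-value orientation convention needs to be assumed. On perfectly
separable fits the slope diverges and probabilities saturate; scores remain
valid calls.

Cross-validation is stratified (per-class round-robin after a seeded
shuffle, so fold sizes differ by at most one instance per class) and metrics
are derived from the confusion counts pooled over held-out folds:
sensitivity, specificity, accuracy, and MCC, with MCC defined as 0 whenever
a factor of its root is zero — the standard convention, which also keeps SFS
comparable on degenerate folds. ROC curves sweep the distinct score values
(ties step simultaneously) and AUC is the trapezoidal integral, which equals
the normalized Mann-Whitney statistic; the test suite checks that equality
against an independent rank-based computation.

## Redundancy filtering and data hygiene

Training windows are de-redundified by a greedy first-kept scan: a window is
dropped when its positionwise identity with any kept (or reference) window
exceeds 40%. Identity is the fraction of the 31 aligned columns carrying
the same standard residue — windows are pre-aligned on the central K, so no
realignment is performed, and pads never match (two heavily padded windows
are not "similar" merely by being short). The protein-level clustering that
succinylome compilations apply (CD-HIT at 40%) is deliberately out of
scope: it is an upstream step on full-length sequences, and the package
documents it as a preprocessing hook rather than reimplementing it.
Annotations that do not point at a lysine are skipped with a warning instead
of failing the run, because public PTM tables routinely contain isoform
coordinate offsets. Train/test splitting is by protein, never by window, so
no protein leaks across the boundary.

## The synthetic succinylome

`generate_succinylome()` exists so that every stage — extraction, encoding,
screening, selection, modeling, evaluation — can be tested for *parameter
recovery* on data whose structure is known. Background residues are i.i.d.
uniform over the 20 letters by default (a natural-abundance mode is
available), so planted effects are the only structure. The default
`motif_spec()` emulates the published substrate signature and was calibrated
once so that the relative strengths of the feature spaces mirror what is
reported on real succinylome data (composition informative on its own,
k-spaced pairs complementary rather than dominant):

* lysine log-odds +1.0 at positions -15..-1 and +6..+12;
* glutamate/aspartate log-odds -1.0 at -5..-3 and +5;
* a mild +0.3 log-odds shift of A, L and V across the whole flank — weak at
  any single position or pair but visible to the window-level composition,
  which is what makes AAC and CIKSAAP genuinely complementary;
* five planted k-spaced pairs, one per spacing (`A_1_G`, `L_2_V`, `S_3_P`,
  `F_4_T`, `W_5_Y`; letters disjoint from K/E/D so the two signal channels
  stay separable), at 2.5-fold enrichment in positive windows.

Sites sit on a 32-residue grid at least 16 residues from each terminus, so
31-mer windows never overlap and a positive site's redrawn flanks cannot
contaminate a neighbor. The generator refuses demands beyond the available
slot capacity. With `effect = 0` all planted structure vanishes and the two
classes are exchangeable — the null-calibration test checks that the
two-sample logo then flags roughly `alpha` of its 600 cells.

What the generator does *not* emulate: real amino-acid background
composition (unless enabled), sequence autocorrelation and domain structure,
homology between proteins, position-dependent effect interactions, or any
mass-spectrometry ascertainment bias. Passing the recovery suite therefore
demonstrates that the pipeline's statistics and selection machinery recover
planted effects of realistic size at realistic sample counts — not that any
particular accuracy will be achieved on a real succinylome.

## Study sizes and numerical choices

The parameter-recovery study (`synthetic_benchmark()`) uses 500 positive and
1500 negative sites — the 1:3 imbalance typical of curated succinylome
training sets at a size where a 10-fold CV of an RBF-SVM is comfortable on a
single CPU. Its feature-set comparison covers the recommended hybrid and its
two constituent single sets (AAC, CIKSAAP, AAC+CIKSAAP); each is tuned on a
reduced grid (`cost = 2^{-1,3,7,11}`, `gamma = 2^{-7,-5,-3,-1,1}`, 3-fold)
before the reported 10-fold run — the full 110-point grid is exercised in
unit tests on small fixtures, and on this fixture the reduced grid already
brackets the optima. The 400-dimensional AAPC models and the raw
2000-dimensional CKSAAP model are omitted from the timed comparison (their
kernel computations dominate the runtime without bearing on the hybrid's
complementarity); all seven choices remain available through
`run_config(feature_set = "sweep")`.

On this generator no dipeptide reaches the 0.02 pooled probability
difference (with 400 equiprobable dipeptides the base rates are ~0.0025, so
a 0.02 difference would be a 9-fold shift); the AAPC model therefore falls
back to all 400 dipeptides, with a warning. The screening rule itself is
retained unchanged because it is part of the method's contract, and it does
select on data with strong dipeptide-level shifts (see the unit tests).

Degenerate inputs are handled conservatively throughout: all-pad windows
encode as flagged zero vectors; empty attribute lists give zero-width
matrices; two-proportion tests with degenerate pooled proportions report
p = 1; single-class training data, unsplittable single-protein window sets
and over-capacity generator demands are errors.

## Known limitations

* The fragment-identity definition (positionwise match over the 31 aligned
  columns) is declared, not inferred from any reference implementation;
  greedy first-kept filtering depends on input order, which is documented
  and deterministic.
* The mRMR/SFS path treats the published "lowest index score" step as
  "best mRMR rank first"; taking it literally would contradict the stated
  goal of the scoring function.
* Corpus-scale performance figures from curated succinylome snapshots are
  not reproducible from this package alone and are intentionally not
  asserted anywhere; the synthetic recovery suite is the package's
  verifiable evidence.
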