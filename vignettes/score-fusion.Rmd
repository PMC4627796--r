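---
title: "Hierarchical Bayes-rule fusion of conservation, disorder and sequence scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayes-rule fusion of conservation, disorder and sequence scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morffuse)
library(dplyr)
```

## The problem

Molecular recognition features (MoRFs) are short segments inside
intrinsically disordered regions (IDRs) of proteins that fold upon binding a
partner. They are sparse — a few percent of residues at most — so a useful
per-residue predictor must combine several weak, largely independent signals
into one score with a low false-positive rate at practical cutoffs.
`morffuse` implements such a combiner for three evidence tracks:

1. **Conservation**, extracted from PSI-BLAST ASCII PSSM files: the
   information per position (IPP), the relative weight of gapless real
   matches to pseudocounts (RWGRMP, which is *anti*-correlated with MoRFs
   and therefore used as its complement), and the weighted observed
   percentage of the query residue (WOP).
2. **Long disorder**, a per-residue disorder propensity from a predictor
   tuned for long disordered segments, so the track stays elevated across a
   MoRF instead of dipping there.
3. **Local sequence composition** (called `chibi` throughout), a MoRF
   propensity computed from small sequence windows by an external
   component predictor.

The package does not run PSI-BLAST or the component predictors; their
outputs are inputs here (FASTA, per-residue TSV tracks, ASCII PSSM files).

## Normalization: rank mapping onto N(0.5, 0.01)

Bayes rule combines probabilities, but component scores are not
probabilities: each lives on its own scale, and values near 0 or 1 would
dominate a naive product. Before any combination, every feature $D$ is
therefore transformed by a map fitted on a training population:

$$\mathrm{Map}_D(x) = \mu + \sigma\,\Phi^{-1}\!\big(\mathrm{clip}(F_D(x),\,
\varepsilon,\, 1-\varepsilon)\big), \qquad \mu = 0.5,\ \sigma = 0.1,$$

where $F_D$ is the empirical fraction of training scores $\le x$ (ties share
one cumulative value) and $\Phi^{-1}$ is the standard normal quantile. The
transformed population is approximately Gaussian with mean 0.5 and variance
0.01, strictly inside (0, 1), and the transform is monotone, so it never
changes a feature's ROC area. Choices the definition leaves open, decided
here once:

* **Clip bound.** $\varepsilon$ defaults to $1/(2n)$ for a training
  population of size $n$, floored at $10^{-6}$: resolution grows with data
  while $\Phi^{-1}(0)$ and $\Phi^{-1}(1)$ remain unreachable. Scores outside
  the training range get cumulative value 0 or 1 and land exactly on the
  clip floor/ceiling.
* **Interpolation.** Between observed training values the cumulative
  probability is interpolated linearly in the raw value — monotone,
  deterministic, and free of density assumptions. No parametric fit and no
  per-sequence renormalization is ever performed.
* **Training only.** Maps are fitted once on the designated training
  cohort and applied unchanged to query data. Fitting needs only the score
  populations (it is a rank transform), which is why `morf_train()` takes
  no annotations.

## Bayes-rule combination

For normalized scores $p_1,\dots,p_k$ of one residue, the combined score is
the equal-prior two-class posterior

$$c = \frac{\prod_i p_i}{\prod_i p_i + \prod_i (1 - p_i)},$$

computed as the logistic inverse of the summed log-odds
$\sum_i \ln\!\big(p_i/(1-p_i)\big)$ so long products cannot underflow. Each
$p_i$ is treated as an independent class-conditional probability; 0.5 is the
non-informative fixed point and a single input passes through unchanged. No
component weights and no class prior reflecting MoRF sparseness are used:
the scores being combined are rank-calibrated rather than calibrated
probabilities, so a shared prior would shift all scores monotonically
without changing their ranking, and the recommended calling cutoff already
absorbs that choice.

Crucially, the hierarchy re-normalizes every combined score under its own
map before the next combination. This is what makes the hierarchical result
different from (and better behaved than) a flat product of all five
features, and the test suite asserts both facts.

## The conservation branch: ics and mcs

The three normalized conservation features (with RWGRMP complemented as
$1 - v$, exact on the symmetric normalized scale) are combined into the
initial conservation score *ics*, which is re-normalized so that the
thresholds below are quantile-meaningful.

Conservation inside a MoRF concentrates on its binding residues. The MoRF
conservation score *mcs* spreads that signal across the window around each
residue with two rules, evaluated per residue with windows truncated at the
sequence ends (the center residue is always included):

* **Scenario 1 — conserved, disordered window** (checked first): if the
  centered 7-residue window has mean normalized disorder > 0.45 and holds
  $k \ge 3$ residues with ics > 0.45, then mcs is the mean ics of those
  conserved residues, and for every conserved residue beyond 3 a square
  root is applied twice — i.e. the mean is raised to $(1/4)^{k-3}$ — which
  pushes the score toward 1. The alternative reading ("a square root twice
  in total whenever $k > 3$") is selectable with
  `mcs_params(root_per_extra = FALSE)`; the per-extra-residue reading is
  the default because the boost is scoped to *every* extra conserved
  residue.
* **Scenario 2 — unconserved, structured window**: if the centered
  15-residue window has mean disorder < 0.45 and no residue with
  ics > 0.60, then mcs is the residue's ics multiplied by the window's mean
  disorder (a value < 0.45, so always a suppression).
* Otherwise mcs equals ics.

Both comparisons are strict, so a disorder track constant at exactly 0.45
fires neither rule. The two window conditions can overlap at a residue
(different window sizes); scenario 1 wins because the conserved-disordered
signal is the one the method exists to amplify. Only residues whose ics
exceeds the threshold enter the conserved average — the center residue is
included only if it qualifies. The same normalized disorder track drives
both window conditions and the later fusion; the window conditions are
defined on *normalized* disorder, and using one track everywhere keeps the
pipeline single-sourced.

All thresholds and window sizes live in `mcs_params()` and are
configuration, not learned quantities.

## The full hierarchy and the calling cutoff

```
ipp ─┐
rwgrmp(complement) ─┼─ Bayes ► ics ─ renormalize ─ mcs rules ─ renormalize ─┐
wop ─┘                                                                      ├─ Bayes ► morf_dc ─ renormalize ─┐
disorder ─ normalize ───────────────────────────────────────────────────────┘                                 ├─ Bayes ► final
chibi ─ normalize ────────────────────────────────────────────────────────────────────────────────────────────┘
```

`morf_predict()` exposes every intermediate track in its result so any stage
can be inspected or plotted (`autoplot()`), and is fully deterministic. The
final score is left on (0, 1) without a last normalization; the default
calling cutoff is 0.66, applied inclusively (`score >= cutoff`), and
`call_morfs()` reports maximal runs above it. Categorical calls are a
convenience — the score itself is the primary output.

## Evaluation conventions

Evaluation is per-residue and pooled across sequences (micro-averaged):
positives are annotated MoRF residues, negatives all unmasked non-MoRF
residues, $TPR = TP/N_{\mathrm{morf}}$, $FPR = FP/N_{\mathrm{non\_morf}}$.
Masking removes residues from both classes: explicit `masked` intervals
always, and MoRF intervals by length under `short_only` (length > 30 masked)
or `long_only` (length ≤ 30 masked) so short- and long-MoRF performance can
be reported separately; the two modes partition the MoRF residues of the
`all` mode. The ROC curve has one point per distinct threshold with ties
called together; the area is the trapezoidal integral, identical to the
Mann–Whitney statistic with ties counted half. "FPR at a TPR target" is
the smallest FPR among thresholds whose TPR reaches the target, since
discrete score sets rarely hit a target exactly. No deduplication of
near-identical sequences is applied — redundancy handling belongs to
dataset construction, not to the metric.

## The synthetic generator

`simulate_dataset()` provides a fully in-silico study so the whole pipeline
is exercisable without external predictors or alignment databases. Per
sequence it plants one MoRF (5–25 residues in `short` mode, 31–45 in
`long`) inside an IDR that extends it by 15–40 flanking residues per side,
then draws scores class-conditionally:

| feature  | MoRF/IDR class | background class | residue-level AUC |
|----------|----------------|------------------|--------------------|
| disorder (over the IDR) | Beta(5, 3) | Beta(3, 5) | ≈ 0.75 vs non-MoRF |
| chibi    | Beta(4, 3)     | Beta(3, 4)       | ≈ 0.72 |
| IPP (×2) | Beta(3.5, 3)   | Beta(2.5, 3.5)   | ≈ 0.68 |
| WOP (×100, integer) | Beta(4, 3) | Beta(3, 4)  | ≈ 0.72 |
| RWGRMP (×1.5) | Beta(3, 4) | Beta(4, 3)       | ≈ 0.72 (complement) |

The disorder track is drawn from the IDR class over the *whole* IDR, MoRF
included, so it does not dip at the MoRF; its MoRF-vs-rest AUC is diluted by
the flanks, as with a real long-disorder predictor. The Beta pairs were
chosen by direct computation of the pairwise exceedance probability so that
single-feature AUCs land in the realistic 0.65–0.75 band;
`separation = "strong"` switches every pair to Beta(8, 2)/Beta(2, 8) for
near-separable classes. Features are class-conditionally independent by
default — the fusion model's own premise — and a `correlation` knob mixes a
shared per-residue percentile into all features to probe violations.
PSSM-borne values are quantized exactly as the ASCII format stores them
(integers for WOP, two decimals for IPP and the relative weight), so
written profiles re-parse to the planted values bit-for-bit. Everything is
pure given the seed: two runs produce byte-identical files.

What the generator does **not** emulate: homology between sequences,
realistic along-sequence autocorrelation of scores (real predictor tracks
are smooth; these are i.i.d. within a class), multiple or nested MoRFs per
sequence, annotation sparsity (truly binding residues labelled negative),
and actual PSI-BLAST search behaviour. Passing tests therefore demonstrate
the correctness and internal consistency of the machinery and its expected
qualitative behaviour (fusion beats components, masking partitions, the
hierarchy matters) — not performance on real proteins.

## Numerical choices

* Combination runs in log-odds space; the logistic/log-odds pair inverts to
  better than $10^{-12}$, which the tests assert.
* Window averages are computed with `mean()` on the literal window slice
  (not a running-sum shortcut), so threshold comparisons such as
  "mean > 0.45" are exact and free of cumulative rounding drift, and the
  vectorized implementation agrees bit-for-bit with a naive per-residue
  re-implementation.
* The scenario-1 boost applies literal repeated `sqrt()` calls — the
  iterated operation the rule describes — rather than a single power.
* Tied raw scores share one cumulative value in normalization; strictly
  monotone behaviour is preserved on the observed training values.
* Map and track files store numbers at 17 significant digits, and track
  reading re-parses them with R's correctly rounded converter, so file
  round trips are bitwise.

Problem sizes used by the checks: the normalization moment check uses a
$10^5$-point exponential sample; oracle equivalences run on $10^3$ random
ROC instances and $10^4$ random mcs residues; the label-recovery study
trains and tests on independent 100-sequence cohorts (≈ 18,000 residues
each). These sizes give stable estimates while keeping the whole suite
fast.

## Limitations

* Quality on real data is bounded by the component predictors and the PSSM
  source; the package only fuses.
* The normalization maps shipped by a training run reflect their training
  cohort; applying them to data from a very different score distribution
  shifts the operating point of the fixed thresholds (0.45/0.60/0.66).
* The mcs thresholds are taken as fixed configuration; re-learning them is
  out of scope.
* With fewer than 100 training scores no map can be fitted, and heavy
  quantization (e.g. integer WOP on short training sets) coarsens the
  normalized scale.
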