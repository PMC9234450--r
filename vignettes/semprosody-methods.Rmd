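---
title: "Models and methods behind semprosody"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind semprosody}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semprosody)
```

This vignette is the package's own account of its models, numerical
choices, and limitations. It states no empirical result beyond what the
test suite and the bundled analysis scripts themselves compute.

## The scientific setting

Semantic prosody is the dissociation between a word's *explicit* valence
(what raters report on a 1–9 pleasantness scale, 5 = neutral) and the
valence of the company it keeps in natural language. A word like *cause* is
rated neutral but is followed, far more often than chance, by negative
words; *restore* by positive ones. Three quantitative instruments bear on
this: collocation statistics over a corpus, similarity geometry in a word
embedding space, and reaction-time congruity effects in evaluative priming.
The package implements all three plus the power machinery that connects
observed effect sizes to design sensitivity, and synthetic-data generators
that make every stage testable against planted ground truth.

## Collocation scoring

Tokens are split on whitespace with leading/trailing punctuation stripped
(word-internal apostrophes and hyphens are kept), case-folded, and sentence
ends marked with a boundary token. Collocation windows cover the `span`
tokens to the *right* of each node occurrence (default 4) and never cross a
sentence boundary — standard collocation practice. Left or symmetric
windows are deliberately unsupported.

Mutual information uses the span-normalized convention of the large
web-corpus interfaces,

$$MI = \log_2 \frac{co\_freq \cdot N}{node\_freq \cdot coll\_freq \cdot span},$$

which differs from plain PMI by the `span` term (exactly `log2(span)` bits);
this matters when comparing thresholds across tools, so it is stated
prominently. The collocate filter is strict (`MI > 3` bits, so a record at
exactly 3.0 is excluded), drops a user-replaceable stoplist of ~200
function words ("overly common" words are not operationally defined in the
literature, so the list is a config key), ranks by co-occurrence frequency,
and keeps the top 100. Ties at the cutoff break by higher MI, then
lexicographically, making output deterministic.

The prosody score is the frequency-weighted average collocate valence,
weighting each collocate's lexicon valence by its co-occurrence frequency.
Weighting by the collocate's *corpus* frequency is available behind a flag;
co-occurrence weighting is the default because the weight should reflect
the node-specific association, not the collocate's overall commonness.
Collocates missing from the valence lexicon drop out of numerator and
denominator alike and are counted in the report — silently imputing the
neutral midpoint would bias scores toward 5. Classification uses a neutral
band for the node's own rating (default [4.5, 6.0], covering the canonical
neutral-but-prosodic examples) and a margin of 0.5 scale points that the
weighted collocate valence must clear on either side of 5; both are config
keys reported alongside the label. Surface forms only — no lemmatization —
because corpus collocate queries are form-based; per-form scores can be
averaged by a wrapper if desired.

## Embedding valence bias

"Distance" between word vectors is read as cosine *similarity* (higher =
more associated): that is the only reading under which a positive-leaning
word receives a positive score. For a target with inflected forms
$f_1,\dots,f_k$ found in the space, the two samples are all form × attribute
cosine pairs against 25 positive and 25 negative attribute words, pooled as
independent observations; a paired-by-attribute variant exists behind a
flag but the pooled form is the default, being the plainest reading of "the
difference of similarity to positive vs. negative words". The summary is
Hedges g — the pooled-SD standardized mean difference with small-sample
correction $J = 1 - 3/(4(n_1+n_2-2)-1)$ — with a normal-approximation 95%
CI ($g \pm 1.96\,SE$, $SE = \sqrt{(n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2-2))}$).
A noncentral-t CI would be marginally more accurate at these sample sizes;
the normal form is used for transparency and the CI-coverage test allows
for that slack. Inflected verb forms default to the four-form set
{base, -s, -ed, -ing} with standard orthographic rules and a small
irregulars table, overridable per word; which forms a given study used is
rarely recoverable, so any comparison against published bias values is
tolerance-based. Out-of-vocabulary forms are dropped and reported, never
zero-filled. The packaged 25+25 attribute lists are a reconstruction of the
standard pleasant/unpleasant sets from the implicit-association literature
(the printed examples — freedom, health, love; filth, death, vomit — are
all members) and are flagged as unverified against any specific study's
materials.

## Priming analysis

Preprocessing order: drop practice trials, drop inaccurate trials
(proportion reported), log-transform, then winsorize log RTs beyond 2.5 SDs
of the grand mean — *replace* with the cutoff, never drop. The grand
statistics pool across participants and conditions; a per-participant
variant exists behind a flag, but the pooled reading matches the phrase
"grand latency mean" and standard RT-outlier practice. The natural log is
the default; the base provably cancels from F, t, p, dz and ηp²
(scale-equivariance, covered by a test), affecting only the units of CIs on
log-RT differences.

The ANOVA is the classical fully-within-subjects univariate decomposition
on participant cell means: every effect is tested against its own
effect × subject interaction, `df1 = prod(levels − 1)`,
`df2 = df1 · (n − 1)`, `ηp² = SS_eff/(SS_eff + SS_err)`. Sums of squares
are computed by Yates-style inclusion–exclusion over marginal cell totals;
the test suite verifies them to 1e−9 against two independent routes
(`aov` with an error stratum, and sequential least squares on the saturated
design matrix) and checks total-SS conservation and the F = t² identity for
two-level factors. No sphericity correction is applied: two-level factors
are exempt by construction, and for the three-level prime-type factor the
uncorrected test matches the conventional reporting of such designs.
Unbalanced tables are rejected with a pointer to the cell-means report
listing participants with empty cells.

Simple effects are paired t tests on cell means, with the 95% CI of the
mean log-RT difference and `dz = mean_diff / SD(differences)`. Published
studies are often ambiguous about which standardizer their *d* uses (dz,
d-average, or pooled-SD d can disagree for the same t and df); `dz` is this
package's definition, stated here precisely so results are comparable.
Zero-variance differences yield a flagged degenerate result (infinite t),
not a crash. Millisecond cell summaries for table-style reporting are
computed from accurate, non-winsorized raw RTs at the participant level
(mean of per-participant cell means; SD across participants), with a
winsorized-scale alternative also emitted, since published tables rarely
state which convention they used. No multiple-testing correction is
applied, matching field practice for these designs.

## Effect sizes and power

The conversions are the textbook identities `η² = f²/(1+f²)`,
`ηp² = F·df1/(F·df1+df2)`, and `r = √(F/(F+df2))` (single-df designs only).
Sensitivity analysis for a repeated-measures congruity interaction follows
the G*Power convention for a within-between interaction with one repeated
factor recast as between-groups: noncentrality `λ = f²·N·m/(1−ρ)·ε` with
`ε = 1` (two-level factors are sphericity-exempt), `df1 = (k−1)(m−1)`,
`df2 = (N−k)(m−1)`, power from the noncentral F distribution, and f solved
by bisection to a power residual below 1e−8. The "as in SPSS" effect-size
convention (f absorbing the correlation structure) is available behind a
flag. Published minimal-f values produced by power GUIs round their inputs
and may toggle conventions, so reproduction checks use a ±0.002 tolerance.
An inverse solver for required N exists but published a-priori N values are
not reproduction targets: the correlation assumptions behind them are
typically unstated.

## Synthetic-data generators

The generators define the test bed; their defaults are fixtures chosen
once, not estimates.

**Corpus.** Tokens come from a ~130-word unigram vocabulary (Zipf-like
filler tail plus high-frequency function words) arranged in fixed-length
synthetic documents of 200 tokens (long documents keep sentence-end window
truncation negligible). Node occurrences are placed first, independently at
their unigram rates; within the span after a node, each planted collocate's
probability is lifted `lift`-fold (remaining mass renormalized over
non-planted words), and *outside* windows the collocate's rate is lowered
so its corpus marginal stays at the nominal unigram rate. Without that
marginal compensation the window-inflated collocate frequency biases the
measured MI below `log2(lift)` at realistic corpus sizes; with it the
plant's asymptotic MI is exactly `log2(lift)`, and the generator also emits
the exact expected MI given the realized node placement (accounting for
truncation and node-occupied slots). When windows of two different nodes
overlap, the closer node's boost applies; default node rates make such
overlap rare. Infeasible plants (window probability mass ≥ 1, or window
draws exceeding the nominal marginal) are config errors.

**Embeddings.** Positive and negative attribute vectors scatter
isotropically (`noise_sd`, default 0.1) around centroids ±`attr_sep`/2
(default separation 1) on a valence axis. A target form with planted
standardized bias g\* is placed at axis coordinate
$\beta = \mathrm{sign}(g^*)\sqrt{g^{*2} s^2 / (sep^2 - g^{*2} s^2)}$ plus a
unit vector orthogonal to the axis, which makes its expected standardized
similarity gap equal g\* (to the accuracy of treating attribute vector
norms as constant — good at dimension 50 with small noise). Biases at or
beyond `attr_sep/noise_sd` are geometrically infeasible and rejected.

**Trials.** Reaction times are lognormal: participant intercepts
`N(0, tau²)` (default tau 0.15), residual log-SD 0.20, baseline log RT
`log(640)` ms (study-1 shape) or `log(590)` (study-2 shape), and a
per-prime-type congruity delta defined as the *congruent minus incongruent*
log-RT difference — negative values mean congruent facilitation. Defaults
(valenced −0.075, prosodic −0.060, control 0) echo a ≈45 ms congruity
spread around ≈600 ms and are labeled fixtures. Accuracy is
Bernoulli(1 − 0.04) independent of condition (published accuracy figures
for such tasks are reported as a single overall rate); responses are the
target valence or its flip. Designs are balanced by construction: each
prime appears four times per participant, twice per target valence. No item
random effects by default, matching participant-only ANOVA practice; they
can be added for robustness studies.

## Problem sizes used by the test suite

The property suites run at sizes chosen to give comfortable statistical
margins: collocation brute-force equality and planted-MI recovery on a
100,000-token corpus; ANOVA oracle agreement on random 12-participant
2×2×2 tables; null calibration of the congruity simple effect over 2,000
simulated 40-participant experiments (the type-I rate must sit inside the
exact binomial 95% interval around 0.05); parameter recovery over a grid of
congruity deltas {0, 0.02, 0.05} × N {40, 80} with 200 seeds per cell; and
embedding null-CI coverage over 500 seeds. A 5,000-participant single-seed
run checks generator consistency (planted delta recovered within ±0.003
log units).

One interaction deserves note: winsorization at 2.5 SDs slightly shrinks
condition separations (one to two percent of the delta under the lognormal
model, where the clipped tail mass is genuine signal rather than
contamination). The parameter-recovery suite therefore measures
unbiasedness with a wide winsorization band, isolating
generator–estimator consistency from outlier treatment, while null
calibration and power checks run the standard 2.5-SD pipeline (a symmetric
winsorization cannot create a spurious effect under the null). On real
data, where extreme RTs are contamination (lapses, anticipations), the
winsorization is doing its intended job; analysts comparing against the
generator's ground truth should use the wide band.

## What passing tests do and do not show

The generators produce clean lognormal RTs, condition-independent errors,
isotropic embedding noise, and stationary unigram corpora. Real data have
sequential effects, fatigue, item variance, anisotropic embedding geometry,
and bursty word usage; none of these are modeled, so passing tests certify
the *machinery* (counting, algebra, inference, calibration under the stated
model), not robustness to those violations. External claims — published
collocate tables, bias values from pretrained vectors, or human RT results
— can be checked by pointing the same pipeline at the corresponding real
inputs via the packaged readers; such checks require licensed resources
that are deliberately not bundled.

## Known limitations

- The tokenizer has no abbreviation handling; a period always ends a
  sentence. For collocation windows this only truncates an occasional
  window early.
- The word2vec *binary* format is unsupported (text format only).
- `required_n` searches integer N linearly; fine for experimental design
  ranges, slow for N in the hundreds of thousands.
- The embedding generator's planted-bias calibration is exact only in the
  large-dimension limit; at dimension 50 with default noise the residual
  placement error is well inside the sampling noise of g at 25+25
  attributes.
- Mixed-effects (crossed item) models, error-rate ANOVAs, Bayesian
  reanalysis, and WEAT-style permutation p-values are out of scope.
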