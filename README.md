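# semprosody

Quantitative machinery for studying **semantic prosody** — the phenomenon
that some words (e.g., *cause*, *restore*) are rated as neutral on explicit
valence scales yet overwhelmingly keep positively or negatively valenced
company in natural language — and for testing whether such words carry
**implicit** valence in evaluative-priming experiments.

The package is aimed at psycholinguists and cognitive scientists who want a
tested, reusable implementation of the full analysis chain:

1. **Corpus collocate-valence scoring.** For a node word, extract the
   collocates appearing within a right-hand window of *span* tokens (default
   4), filter by span-normalized mutual information
   `MI = log2( co_freq · N / (node_freq · coll_freq · span) )` at a strict
   `MI > 3` bits threshold plus a function-word stoplist, rank by
   co-occurrence frequency, keep the top 100, and compute the
   **frequency-weighted average collocate valence**
   `Σ co_freq(c)·valence(c) / Σ co_freq(c)` on the 1–9 pleasantness scale
   (5 = neutral). A word is classified as semantically prosodic when its own
   rated valence is in the neutral band but its collocates pull beyond a
   margin from the midpoint.
2. **Embedding valence bias.** A word's (or group's) bias in a vector space
   is the Hedges-g standardized difference between its cosine similarities
   to 25 positive and 25 negative attribute words,
   `g = J·(m⁺ − m⁻)/s_pooled` with the small-sample correction
   `J = 1 − 3/(4(n₁+n₂−2)−1)` and a 95% normal-approximation CI. A seeded
   1,000-word random baseline checks the vector source for global bias.
3. **Evaluative-priming congruity analysis.** Trial-level reaction times are
   accuracy-filtered, log-transformed, winsorized at 2.5 SDs of the grand
   log-RT mean, aggregated to participant cell means, and analysed with a
   fully-within-subjects factorial repeated-measures ANOVA (each effect
   tested against its own effect × subject term; `ηp² = SS_eff/(SS_eff+SS_err)`)
   plus paired simple effects with `dz` effect sizes.
4. **Effect-size conversion and sensitivity power analysis.** `η² = f²/(1+f²)`,
   `ηp² = F·df1/(F·df1+df2)`, `r = √(F/(F+df2))`, and the minimal detectable
   Cohen's f for a within-between interaction, solved by bisection on
   noncentral-F power with `λ = f²·N·m/(1−ρ)`, `df1 = (k−1)(m−1)`,
   `df2 = (N−k)(m−1)`.
5. **Synthetic-data generators** for all three inputs — corpora with planted
   node→collocate lifts (asymptotic MI exactly `log2(lift)`), embedding
   spaces with planted standardized bias, and lognormal trial data with
   participant random effects and planted congruity deltas — so every stage
   is testable against known ground truth without licensed corpora,
   pretrained vectors, or human participants.

The `analysis/` directory stages these steps as a numbered workflow
(`01_simulate_inputs.R` … `05_power_sensitivity.R`) writing its tables under
`results/`.

## Worked example

```r
library(semprosody)

## sensitivity of a 78-participant priming study whose repeated measures
## correlate at 0.83
spec <- power_spec(N = 78, k = 2, m = 2, rho = 0.83, alpha = 0.05, power = 0.80)
sensitivity_f(spec)
#> [1] 0.09367306
eta2_from_f(sensitivity_f(spec))
#> [1] 0.008698317
```

So a congruity interaction as small as f ≈ 0.094 (η² ≈ 0.0088) is detectable
at 80% power — anything the study misses is smaller than that.

```r
## semantic prosody from a synthetic corpus with planted collocations
corpus <- gen_corpus(default_synth_corpus_config(n_tokens = 1e5, seed = 20260925))
lex <- synth_valence_lexicon()
score_prosody(corpus$tokens, "cause", lex)
#> <prosody_score> node 'cause': weighted collocate valence 1.734
#>   (2 collocates, weight 869), explicit 5.10 -> negative_prosody
```

The node word rates as neutral (5.10 on the 1–9 scale) but its
high-MI collocates average 1.73 — strongly negative company, hence
`negative_prosody`.

```r
## embedding bias of the same word in a space with a planted gap
emb <- gen_embeddings(synth_embedding_config(
  targets = list(cause = list(forms = verb_forms("cause"), bias = -1.05)),
  n_filler = 1500, seed = 20260925))
word_bias("cause", emb$space, emb$sets)
#> <bias_result> cause: g = -1.051, 95% CI [-1.347, -0.756] (n_pos = 100, n_neg = 100)
```

The planted standardized bias of −1.05 is recovered as g = −1.05: the word
sits much closer to the negative attribute set than to the positive one.

## Scope notes

The package does not bundle or download any licensed resources (corpora,
picture norms, rating norms, or pretrained vectors); readers for the
standard exchange formats (`word2vec` text vectors, valence-norm CSV,
trial-level CSV, plain-text corpora) let you point the same pipeline at
real data. The binary `word2vec` format is out of scope — convert to the
text format with any standard tool. The packaged 25+25 valence attribute
lists are a reconstruction of the lists commonly used in the
implicit-association literature, not verified against any particular
study's materials.
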