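#!/usr/bin/env Rscript
# Step 3: embedding-based valence bias. For each target word, pool the
# cosine similarities of its verb forms to the 25 positive and 25 negative
# attribute words and summarize the gap as Hedges g with a 95% CI; then a
# 1,000-word random baseline as a robustness check of the vector source.

suppressPackageStartupMessages(library(semprosody))

in_dir <- "results/inputs"
out_dir <- "results/embedding"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

space <- read_embeddings(file.path(in_dir, "vectors.vec"))
truth <- read.csv(file.path(in_dir, "embedding_ground_truth.csv"))
# the attribute sets actually placed in this space
sets <- attribute_sets(
  intersect(default_attribute_sets()$positive, space$vocab),
  intersect(default_attribute_sets()$negative, space$vocab)
)

rows <- list()
for (w in unique(truth$word)) {
  res <- word_bias(w, space, sets)
  print(res)
  rows[[w]] <- data.frame(
    word = w, g = res$g, ci_low = res$ci_low, ci_high = res$ci_high,
    n_pos = res$n_pos, n_neg = res$n_neg,
    planted_bias = truth$planted_bias[match(w, truth$word)],
    stringsAsFactors = FALSE
  )
}

base <- random_baseline(space, n_words = 1000, seed = 20260925, sets = sets)
message(sprintf("random 1,000-word baseline: g = %.3f, 95%% CI [%.3f, %.3f]",
                base$g, base$ci_low, base$ci_high))
rows$baseline <- data.frame(
  word = "random_baseline_1000", g = base$g, ci_low = base$ci_low,
  ci_high = base$ci_high, n_pos = base$n_pos, n_neg = base$n_neg,
  planted_bias = 0, stringsAsFactors = FALSE
)

out <- do.call(rbind, rows)
write.csv(out, file.path(out_dir, "bias_results.csv"), row.names = FALSE)
message(sprintf("wrote %s", file.path(out_dir, "bias_results.csv")))
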