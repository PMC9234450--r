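#!/usr/bin/env Rscript
# Step 2: semantic-prosody scoring from the corpus. For each node word:
# right-window collocates (span 4), mutual-information filter (> 3 bits),
# top-100 by co-occurrence frequency, frequency-weighted average collocate
# valence, and the prosody classification.

suppressPackageStartupMessages(library(semprosody))

in_dir <- "results/inputs"
out_dir <- "results/collocation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

tokens <- read_corpus_tokens(file.path(in_dir, "corpus.txt"))
lex <- read_valence_norms(file.path(in_dir, "valence_norms.csv"))
truth <- read.csv(file.path(in_dir, "corpus_ground_truth.csv"))
config <- collocation_config()  # span 4, top 100, MI > 3, packaged stoplist
n_words <- sum(tokens != EOS_TOKEN)

summaries <- list()
for (node in unique(truth$node)) {
  recs <- count_collocates(tokens, node, config)
  recs <- add_mutual_information(recs, n_words, config$span)
  ranked <- top_collocates(recs, config)
  ranked$valence <- unname(valence_of(lex, ranked$collocate))
  write.table(ranked, file.path(out_dir, sprintf("collocates_%s.tsv", node)),
              sep = "\t", row.names = FALSE, quote = FALSE)
  score <- weighted_collocate_valence(ranked, lex,
                                      explicit_valence = unname(valence_of(lex, node)))
  print(score)
  planted <- truth[truth$node == node, ]
  est_mi <- ranked$mi[match(planted$collocate, ranked$collocate)]
  message(sprintf("  planted MI recovery: %s",
                  paste(sprintf("%s %.2f (expected %.2f)", planted$collocate,
                                est_mi, planted$expected_mi), collapse = "; ")))
  summaries[[node]] <- list(
    node = node,
    n_collocates_used = score$n_collocates_used,
    total_weight = score$total_weight,
    weighted_valence = score$weighted_valence,
    explicit_valence = score$explicit_valence,
    label = score$label
  )
}

jsonlite::write_json(summaries, file.path(out_dir, "prosody_scores.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message(sprintf("wrote %s", file.path(out_dir, "prosody_scores.json")))
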