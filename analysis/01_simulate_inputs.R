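#!/usr/bin/env Rscript
# Step 1: generate every synthetic input the downstream analyses consume --
# a corpus with planted collocations, an embedding space with planted
# valence bias, trial-level priming data for both study designs, and the
# valence-norm lexicon -- and write them in the pipeline's exchange formats.

suppressPackageStartupMessages(library(semprosody))

out_dir <- "results/inputs"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260925L

message("-- corpus with planted collocations --")
corpus <- gen_corpus(default_synth_corpus_config(n_tokens = 1e5, seed = seed))
tokens_to_text(corpus$tokens, file.path(out_dir, "corpus.txt"))
write.csv(corpus$truth, file.path(out_dir, "corpus_ground_truth.csv"), row.names = FALSE)
message(sprintf("  %d word tokens; %d plants, asymptotic MI %.1f bits each",
                sum(corpus$tokens != EOS_TOKEN), nrow(corpus$truth),
                corpus$truth$mi_asymptotic[1]))

message("-- embedding space with planted bias --")
emb <- gen_embeddings(synth_embedding_config(
  targets = list(
    cause = list(forms = verb_forms("cause"), bias = -1.05),
    restore = list(forms = verb_forms("restore"), bias = 0.44),
    reply = list(forms = verb_forms("reply"), bias = 0)
  ),
  n_filler = 1500, seed = seed
))
write_embeddings(emb$space, file.path(out_dir, "vectors.vec"))
write.csv(emb$truth, file.path(out_dir, "embedding_ground_truth.csv"), row.names = FALSE)
message(sprintf("  %d words x %d dims; planted word biases: %s",
                length(emb$space$vocab), emb$space$dimension,
                paste(sprintf("%s=%.2f", unique(emb$truth$word),
                              emb$truth$planted_bias[!duplicated(emb$truth$word)]),
                      collapse = ", ")))

message("-- trial-level priming data --")
for (study in c("study1", "study2")) {
  g <- gen_trials(synth_trial_config(study, seed = seed))
  write_trials(g$trials, file.path(out_dir, sprintf("trials_%s.csv", study)))
  message(sprintf("  %s: %d participants, %d experimental trials each (delta: %s)",
                  study, length(unique(g$trials$participant_id)),
                  g$truth$n_experimental_per_participant,
                  paste(sprintf("%s=%.3f", names(g$truth$delta), g$truth$delta),
                        collapse = ", ")))
}

message("-- valence norms --")
lex <- synth_valence_lexicon()
write_valence_norms(lex, file.path(out_dir, "valence_norms.csv"))
message(sprintf("  %d words on the 1-9 pleasantness scale", length(lex)))
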