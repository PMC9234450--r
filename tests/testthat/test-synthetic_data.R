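test_that("corpus generation is a pure function of config and seed", {
  cfg <- default_synth_corpus_config(n_tokens = 5000, seed = 77)
  g1 <- gen_corpus(cfg)
  g2 <- gen_corpus(cfg)
  expect_identical(g1$tokens, g2$tokens)
  g3 <- gen_corpus(default_synth_corpus_config(n_tokens = 5000, seed = 78))
  expect_false(identical(g1$tokens, g3$tokens))
})

test_that("generated text round-trips through the tokenizer", {
  g <- gen_corpus(default_synth_corpus_config(n_tokens = 2000, seed = 3))
  txt <- tokens_to_text(g$tokens)
  expect_identical(tokenize(txt), g$tokens)
  f <- tempfile(fileext = ".txt")
  tokens_to_text(g$tokens, f)
  expect_identical(read_corpus_tokens(f), g$tokens)
})

test_that("a unit lift plants nothing: estimated MI stays near zero", {
  cfg <- default_synth_corpus_config(n_tokens = 8e4, lift = 1, seed = 19)
  g <- gen_corpus(cfg)
  recs <- count_collocates(g$tokens, "cause",
                           collocation_config(stoplist = character(0)))
  recs <- add_mutual_information(recs, sum(g$tokens != EOS_TOKEN), 4)
  recs2 <- count_collocates(g$tokens, "restore",
                            collocation_config(stoplist = character(0)))
  recs2 <- add_mutual_information(recs2, sum(g$tokens != EOS_TOKEN), 4)
  mi <- c(
    recs$mi[match(c("death", "pain"), recs$collocate)],
    recs2$mi[match(c("order", "health"), recs2$collocate)]
  )
  # co-occurrence counts are small under the null, so individual MI
  # estimates are noisy; their average should sit near zero
  expect_lt(abs(mean(mi)), 0.5)
  expect_true(all(abs(mi) < 1.5))
  expect_equal(g$truth$mi_asymptotic, rep(0, 4))
})

test_that("infeasible plants are rejected with a config error", {
  cfg <- default_synth_corpus_config(n_tokens = 2000)
  bad <- cfg
  bad$plants$lift <- 500  # window probability mass would exceed 1
  expect_error(gen_corpus(bad), ">= 1|infeasible")
  expect_error(
    synth_corpus_config(data.frame(word = "a", prob = 1),
                        data.frame(node = "a", collocate = "b", lift = 2, valence = 5)),
    "absent from vocab"
  )
  expect_error(
    synth_corpus_config(data.frame(word = c("a", "b"), prob = c(0.6, 0.6)),
                        data.frame(node = "a", collocate = "b", lift = 2, valence = 5)),
    "sum to 1"
  )
})

test_that("embedding generation is deterministic and validates planted bias", {
  cfg <- synth_embedding_config(targets = data.frame(word = "t", bias = 0.5), seed = 5)
  e1 <- gen_embeddings(cfg)
  e2 <- gen_embeddings(cfg)
  expect_identical(e1$space$vectors, e2$space$vectors)
  expect_error(
    synth_embedding_config(targets = data.frame(word = "t", bias = 20),
                           attr_sep = 1, noise_sd = 0.1),
    "infeasible"
  )
})

test_that("trial generation matches the two study shapes exactly", {
  g1 <- gen_trials(synth_trial_config("study1", n_participants = 5, seed = 1))
  per <- table(g1$trials$participant_id[g1$trials$phase == "experimental"])
  expect_true(all(per == 64))
  expect_true(all(table(g1$trials$participant_id[g1$trials$phase == "practice"]) == 16))
  # each prime appears 4 times: twice per target valence
  one <- g1$trials[g1$trials$participant_id == "p001" & g1$trials$phase == "experimental", ]
  counts <- table(one$prime, one$target_valence)
  expect_true(all(counts == 2))
  expect_setequal(unique(one$prime_type), c("prosodic", "control"))

  g2 <- gen_trials(synth_trial_config("study2", n_participants = 3, seed = 1))
  per2 <- table(g2$trials$participant_id[g2$trials$phase == "experimental"])
  expect_true(all(per2 == 96))
  expect_setequal(unique(g2$trials$prime_type), c("valenced", "prosodic", "control"))

  # pure function of seed
  g1b <- gen_trials(synth_trial_config("study1", n_participants = 5, seed = 1))
  expect_identical(g1$trials, g1b$trials)
})

test_that("generated trials satisfy downstream preconditions", {
  g <- gen_trials(synth_trial_config("study1", n_participants = 6, seed = 44))
  tr <- g$trials
  expect_true(all(tr$rt_ms > 0))
  expect_true(all(tr$accurate == (tr$response == tr$target_valence)))
  # balanced cells for every participant after typical accuracy filtering
  pre <- preprocess(tr)
  tab <- cell_means(pre)
  expect_equal(length(tab$participants) + length(tab$excluded), 6)
  expect_error(rm_anova(tab), NA)
})

test_that("a large sample recovers the planted congruity delta", {
  cfg <- synth_trial_config(
    "study1", n_participants = 5000,
    delta = c(prosodic = -0.06, control = 0, valenced = 0),
    n_practice = 0L, seed = 99
  )
  g <- gen_trials(cfg)
  # wide winsorization band isolates the generator-estimator consistency
  # check from outlier treatment
  pre <- preprocess(g$trials, preprocess_config(sd_mult = 100))
  tab <- cell_means(pre)
  congruity <- function(pt) {
    neg <- simple_effect(
      tab,
      c(prime_type = pt, prime_valence = "positive", target_valence = "negative"),
      c(prime_type = pt, prime_valence = "negative", target_valence = "negative")
    )
    pos <- simple_effect(
      tab,
      c(prime_type = pt, prime_valence = "negative", target_valence = "positive"),
      c(prime_type = pt, prime_valence = "positive", target_valence = "positive")
    )
    (neg$mean_diff + pos$mean_diff) / 2  # incongruent minus congruent
  }
  expect_lt(abs(congruity("prosodic") - 0.06), 0.003)
  expect_lt(abs(congruity("control")), 0.003)
})

test_that("the fixture lexicon is deterministic and in range", {
  l1 <- synth_valence_lexicon()
  l2 <- synth_valence_lexicon()
  expect_identical(l1$valence_mean, l2$valence_mean)
  expect_true(all(l1$valence_mean >= 1 & l1$valence_mean <= 9))
  expect_equal(unname(valence_of(l1, c("cause", "restore"))), c(5.1, 5.9))
})
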