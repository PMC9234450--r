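no_stop <- function(span = 4L, ...) collocation_config(span = span, stoplist = character(0), ...)

test_that("tokenizer strips punctuation, case-folds, and marks sentence ends", {
  expect_equal(tokenize("Cause great pain."), c("cause", "great", "pain", EOS_TOKEN))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("don't stop"), c("don't", "stop", EOS_TOKEN))
  expect_equal(tokenize("One. Two!"), c("one", EOS_TOKEN, "two", EOS_TOKEN))
  expect_equal(tokenize("Keep Case", lowercase = FALSE)[1:2], c("Keep", "Case"))
})

test_that("right-window counts respect span and sentence boundaries", {
  toks <- c("a", "x", "b", EOS_TOKEN, "a", "y", EOS_TOKEN)
  r2 <- count_collocates(toks, "a", no_stop(span = 2))
  expect_setequal(r2$collocate, c("x", "b", "y"))
  expect_true(all(r2$co_freq == 1L))
  expect_true(all(r2$node_freq == 2L))
  r1 <- count_collocates(toks, "a", no_stop(span = 1))
  expect_setequal(r1$collocate, c("x", "y"))
  # absent node: empty result, not an error
  expect_message(r0 <- count_collocates(toks, "zzz", no_stop()), "absent")
  expect_equal(nrow(r0), 0)
})

test_that("streaming counts equal the quadratic brute-force oracle", {
  set.seed(101)
  vocab <- c(sprintf("w%02d", 1:30), "node")
  for (span in c(2L, 4L)) {
    toks <- sample(vocab, 5000, replace = TRUE,
                   prob = c(rep(1, 30), 5) / 35)
    # sprinkle sentence boundaries
    toks[sample(5000, 250)] <- EOS_TOKEN
    got <- count_collocates(toks, "node", no_stop(span = span))
    want <- brute_force_collocates(toks, "node", span)
    expect_equal(stats::setNames(got$co_freq, got$collocate)[order(got$collocate)],
                 want)
    expect_true(all(got$node_freq == sum(toks == "node")))
    expect_equal(got$coll_freq,
                 as.integer(table(toks[toks != EOS_TOKEN])[got$collocate]))
  }
})

test_that("shrinking the span never increases any co-occurrence count", {
  set.seed(7)
  toks <- sample(c(sprintf("w%02d", 1:20), "node", EOS_TOKEN), 3000,
                 replace = TRUE, prob = c(rep(1, 20), 4, 1.5) / 25.5)
  wide <- count_collocates(toks, "node", no_stop(span = 4))
  narrow <- count_collocates(toks, "node", no_stop(span = 2))
  merged <- merge(wide, narrow, by = "collocate", all.x = TRUE)
  merged$co_freq.y[is.na(merged$co_freq.y)] <- 0L
  expect_true(all(merged$co_freq.y <= merged$co_freq.x))
})

test_that("mutual information follows the span-normalized log2 convention", {
  # direct arithmetic: log2(4 * 10000 / (10 * 20 * 4)) = log2(50)
  expect_equal(mutual_information(4, 10, 20, 10000, 4), log2(50))
  # independence point
  expect_equal(mutual_information(8, 10, 20, 100, 4), 0)
  # doubling co_freq adds exactly one bit
  base <- mutual_information(5, 30, 40, 5000, 4)
  expect_equal(mutual_information(10, 30, 40, 5000, 4), base + 1)
  expect_error(mutual_information(1, 1, 1, 0, 4), "corpus_size")
  expect_error(mutual_information(0, 1, 1, 100, 4), ">= 1")
})

test_that("ranking applies a strict MI threshold, the cap, and deterministic ties", {
  recs <- data.frame(
    node = "n", collocate = c("a1", "a2", "a3"),
    co_freq = c(5L, 5L, 5L), node_freq = 50L, coll_freq = 10L,
    mi = c(2.9, 3.0, 3.1), stringsAsFactors = FALSE
  )
  out <- top_collocates(recs, no_stop(), quiet = TRUE)
  expect_equal(out$collocate, "a3")

  set.seed(21)
  big <- data.frame(
    node = "n", collocate = sprintf("c%03d", 1:150),
    co_freq = sample(1:40, 150, replace = TRUE),
    node_freq = 500L, coll_freq = sample(5:50, 150, replace = TRUE),
    mi = runif(150, 3.01, 8), stringsAsFactors = FALSE
  )
  out <- top_collocates(big, no_stop(), quiet = TRUE)
  expect_equal(nrow(out), 100)
  expect_true(all(diff(out$co_freq) <= 0))
  # full-sort oracle under the documented tie-break
  oracle <- big[order(-big$co_freq, -big$mi, big$collocate), ][1:100, ]
  expect_equal(out$collocate, oracle$collocate)

  # stoplist members are dropped even if they qualify on MI
  cfg <- collocation_config(stoplist = "c001")
  expect_false("c001" %in% top_collocates(big, cfg, quiet = TRUE)$collocate)
})

test_that("weighted collocate valence averages by co-occurrence weight", {
  lex <- valence_lexicon(c("good", "bad", "high", "low"), c(7, 2, 6, 2))
  mk <- function(coll, freq) data.frame(
    node = "n", collocate = coll, co_freq = freq, node_freq = 100L,
    coll_freq = 50L, mi = 4, stringsAsFactors = FALSE
  )
  expect_equal(weighted_collocate_valence(mk("good", 3L), lex, quiet = TRUE)$weighted_valence, 7)
  expect_equal(
    weighted_collocate_valence(mk(c("bad", "high"), c(2L, 2L)), lex,
                               quiet = TRUE)$weighted_valence,
    4  # (2 + 6) / 2
  )
  s <- weighted_collocate_valence(mk(c("high", "low"), c(3L, 1L)), lex, quiet = TRUE)
  expect_equal(s$weighted_valence, 5)  # (3*6 + 1*2) / 4
  expect_equal(s$n_collocates_used, 2)
  expect_equal(s$total_weight, 4)

  # order invariance and uniform-scaling invariance
  shuffled <- mk(c("low", "high"), c(1L, 3L))
  scaled <- mk(c("high", "low"), c(30L, 10L))
  expect_equal(weighted_collocate_valence(shuffled, lex, quiet = TRUE)$weighted_valence, 5)
  expect_equal(weighted_collocate_valence(scaled, lex, quiet = TRUE)$weighted_valence, 5)

  # collocates missing from the lexicon drop out of both sums
  s2 <- weighted_collocate_valence(mk(c("high", "unknown"), c(1L, 99L)), lex, quiet = TRUE)
  expect_equal(s2$weighted_valence, 6)
  expect_equal(s2$n_collocates_used, 1)

  s3 <- weighted_collocate_valence(mk("unknown", 5L), lex, quiet = TRUE)
  expect_equal(s3$label, "indeterminate")
  expect_true(is.na(s3$weighted_valence))

  # corpus-frequency weighting available behind the flag
  alt <- mk(c("high", "low"), c(3L, 1L))
  alt$coll_freq <- c(10L, 30L)
  s4 <- weighted_collocate_valence(alt, lex, weight = "coll_freq", quiet = TRUE)
  expect_equal(s4$weighted_valence, (10 * 6 + 30 * 2) / 40)
})

test_that("prosody classification follows the neutral band and margin", {
  mk_score <- function(explicit, weighted) {
    structure(
      list(node = "n", n_collocates_used = 10L, total_weight = 100L,
           weighted_valence = weighted, explicit_valence = explicit,
           label = "indeterminate"),
      class = "prosody_score"
    )
  }
  expect_equal(classify_prosody(mk_score(5.1, 3.90), c(4.5, 6), 0.5)$label,
               "negative_prosody")
  expect_equal(classify_prosody(mk_score(5.9, 6.10), c(4.5, 6), 0.5)$label,
               "positive_prosody")
  expect_equal(classify_prosody(mk_score(8.2, 2.0), c(4.5, 6), 0.5)$label,
               "valenced")
  expect_equal(classify_prosody(mk_score(5.0, 5.2), c(4.5, 6), 0.5)$label,
               "non_prosodic")
  expect_equal(classify_prosody(mk_score(NA_real_, 3.0))$label, "indeterminate")
})

test_that("planted prosody is recovered end-to-end from a synthetic corpus", {
  gc1 <- gen_corpus(default_synth_corpus_config(n_tokens = 4e4, seed = 2))
  lex <- synth_valence_lexicon()
  neg <- score_prosody(gc1$tokens, "cause", lex)
  pos <- score_prosody(gc1$tokens, "restore", lex)
  expect_equal(neg$label, "negative_prosody")
  expect_equal(pos$label, "positive_prosody")
  expect_lt(neg$weighted_valence, 4.5)
  expect_gt(pos$weighted_valence, 5.5)
})
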