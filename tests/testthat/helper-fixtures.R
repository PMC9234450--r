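# Shared fixture builders. Everything is generated in code; no binary data.

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

toy_norms_file <- function() {
  write_tmp(c("word,valence_mean", "cause,5.1", "restore,5.9"))
}

toy_trials <- function() {
  data.frame(
    participant_id = c("p1", "p1", "p2", "p2"),
    trial_index = c(0L, 1L, 0L, 1L),
    phase = "experimental",
    prime = c("cause", "restore", "cause", "restore"),
    prime_type = "prosodic",
    prime_valence = c("negative", "positive", "negative", "positive"),
    target = c("racism", "joy", "greed", "comedy"),
    target_valence = c("negative", "positive", "negative", "positive"),
    response = c("negative", "positive", "positive", "positive"),
    accurate = c(TRUE, TRUE, FALSE, TRUE),
    rt_ms = c(640.125, 702.5, 598, 655.25),
    stringsAsFactors = FALSE
  )
}

# balanced one-value-per-cell table for ANOVA tests: n_sub participants,
# factors given as named list of level vectors, values ~ N(0, 1) plus
# optional planted effects
random_cell_table <- function(n_sub, factors, seed) {
  set.seed(seed)
  grid <- expand.grid(
    c(list(participant_id = sprintf("s%02d", seq_len(n_sub))), factors),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid$value <- rnorm(nrow(grid))
  structure(
    list(
      data = grid,
      participants = sprintf("s%02d", seq_len(n_sub)),
      factors = factors,
      excluded = character(0)
    ),
    class = "cell_means_table"
  )
}

# independent quadratic-scan collocation oracle: walks every (node position,
# offset) pair explicitly
brute_force_collocates <- function(tokens, node, span, stoplist = character(0)) {
  counts <- new.env(parent = emptyenv())
  n <- length(tokens)
  for (p in which(tokens == node)) {
    for (off in seq_len(span)) {
      q <- p + off
      if (q > n) break
      tok <- tokens[q]
      if (tok == EOS_TOKEN) break
      if (tok %in% stoplist) next
      counts[[tok]] <- (counts[[tok]] %||% 0L) + 1L
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) integer(0) else out[order(names(out))]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# one simulated priming experiment reduced to the prosodic congruity simple
# effect on negative targets; returns the estimated difference and p-value
sim_congruity <- function(seed, n_sub, delta_prosodic, sd_mult = 2.5) {
  cfg <- synth_trial_config(
    "study1", n_participants = n_sub,
    delta = c(prosodic = delta_prosodic, control = 0, valenced = 0),
    n_practice = 0L, seed = seed
  )
  g <- gen_trials(cfg)
  pre <- preprocess(g$trials, preprocess_config(sd_mult = sd_mult))
  tab <- cell_means(pre)
  se <- simple_effect(
    tab,
    c(prime_type = "prosodic", prime_valence = "positive", target_valence = "negative"),
    c(prime_type = "prosodic", prime_valence = "negative", target_valence = "negative")
  )
  c(diff = se$mean_diff, p = se$p)
}
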