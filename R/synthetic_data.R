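# Synthetic-data generators: corpora with planted collocation structure,
# embedding spaces with planted valence-bias geometry, and trial-level
# priming data with planted congruity effects. Each generator is a pure
# function of its config + seed and returns the generated object together
# with its ground truth. They exist so the full pipeline is testable without
# the licensed corpus, the pretrained vectors, or human participants.

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(expr)
}

#' Synthetic-corpus configuration
#'
#' @param vocab data frame `word, prob`: the unigram model. Probabilities
#'   must sum to 1. Words used as plant nodes or collocates must appear here.
#' @param plants data frame `node, collocate, lift, valence`: each row plants
#'   an elevated node-to-collocate co-occurrence. Within the `span` tokens
#'   after a node occurrence, the planted collocate is drawn at `lift` times
#'   its base rate (the remaining probability mass is renormalized across
#'   non-planted words); outside those windows its rate is lowered so that
#'   its corpus marginal stays at the nominal unigram rate. Under that
#'   marginal-preserving construction the plant's asymptotic mutual
#'   information is exactly `log2(lift)`.
#' @param n_tokens number of word tokens to generate.
#' @param sentence_len fixed sentence length in tokens (boundary markers are
#'   emitted between sentences and not counted).
#' @param span collocation window the plants are aimed at (default 4).
#' @param seed integer seed.
#' @return List of class `synth_corpus_config`.
#' @export
synth_corpus_config <- function(vocab, plants, n_tokens = 1e5, sentence_len = 50L,
                                span = 4L, seed = 1L) {
  stopifnot(is.data.frame(vocab), all(c("word", "prob") %in% names(vocab)),
            is.data.frame(plants),
            all(c("node", "collocate", "lift", "valence") %in% names(plants)))
  if (abs(sum(vocab$prob) - 1) > 1e-8) stop("vocab probabilities must sum to 1", call. = FALSE)
  if (any(vocab$prob < 0)) stop("vocab probabilities must be nonnegative", call. = FALSE)
  if (anyDuplicated(vocab$word)) stop("duplicate vocab words", call. = FALSE)
  if (any(plants$lift < 0)) stop("lift must be nonnegative", call. = FALSE)
  missing <- setdiff(unique(c(plants$node, plants$collocate)), vocab$word)
  if (length(missing)) {
    stop(sprintf("plant word(s) absent from vocab: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  if (any(plants$node == plants$collocate)) {
    stop("a word cannot be planted as its own collocate", call. = FALSE)
  }
  structure(
    list(vocab = vocab, plants = plants, n_tokens = as.integer(n_tokens),
         sentence_len = as.integer(sentence_len), span = as.integer(span),
         seed = as.integer(seed)),
    class = "synth_corpus_config"
  )
}

#' Default synthetic-corpus configuration
#'
#' A ~130-word vocabulary with a Zipf-like filler tail and frequent function
#' words, and two plants echoing the canonical semantic-prosody examples: a
#' neutral node keeping negative company and one keeping positive company.
#'
#' @param n_tokens corpus size (default 1e5 word tokens).
#' @param lift co-occurrence boost for both plants (default 32, i.e., 5 bits).
#' @param seed integer seed.
#' @return A [synth_corpus_config()].
#' @export
default_synth_corpus_config <- function(n_tokens = 1e5, lift = 32, seed = 1L) {
  function_words <- data.frame(
    word = c("the", "of", "and", "to", "a", "in", "is", "was", "for", "that"),
    prob = c(0.060, 0.030, 0.028, 0.026, 0.023, 0.021, 0.012, 0.010, 0.009, 0.008),
    stringsAsFactors = FALSE
  )
  special <- data.frame(
    word = c("cause", "restore", "death", "order", "pain", "health"),
    prob = c(0.0050, 0.0050, 0.0080, 0.0080, 0.0050, 0.0050),
    stringsAsFactors = FALSE
  )
  n_filler <- 120
  w <- 1 / (seq_len(n_filler) + 10)
  filler_mass <- 1 - sum(function_words$prob) - sum(special$prob)
  filler <- data.frame(
    word = sprintf("w%03d", seq_len(n_filler)),
    prob = filler_mass * w / sum(w),
    stringsAsFactors = FALSE
  )
  vocab <- rbind(function_words, special, filler)
  plants <- data.frame(
    node = c("cause", "cause", "restore", "restore"),
    collocate = c("death", "pain", "order", "health"),
    lift = lift,
    valence = c(1.54, 2.06, 5.48, 7.54),
    stringsAsFactors = FALSE
  )
  # long synthetic documents keep window truncation at sentence ends
  # negligible relative to log2(lift)
  synth_corpus_config(vocab, plants, n_tokens = n_tokens, sentence_len = 200L,
                      seed = seed)
}

#' Generate a synthetic corpus with planted collocations
#'
#' Node occurrences are drawn first (independently at each position at their
#' unigram rates); remaining positions draw from a window-boosted or
#' marginal-compensated distribution depending on whether they fall within
#' `span` tokens after a node in the same sentence. When windows of two
#' different nodes overlap, the closer node's boost applies. The ground-truth
#' table reports each plant's expected mutual information given the realized
#' node placement (accounting for sentence-end window truncation) alongside
#' the asymptotic value `log2(lift)`.
#'
#' @param config a [synth_corpus_config()].
#' @return List with `tokens` (including sentence-boundary markers), `truth`
#'   (one row per plant: expected and asymptotic MI), and `config`.
#' @export
gen_corpus <- function(config = default_synth_corpus_config()) {
  stopifnot(inherits(config, "synth_corpus_config"))
  with_seed(config$seed, {
    vocab <- config$vocab
    plants <- config$plants
    nodes <- unique(plants$node)
    N <- config$n_tokens
    L <- config$sentence_len
    span <- config$span
    p_node <- vocab$prob[match(nodes, vocab$word)]
    names(p_node) <- nodes

    # 1. place node occurrences
    u <- stats::runif(N)
    breaks <- c(0, cumsum(p_node))
    node_idx <- findInterval(u, breaks, left.open = TRUE)  # 1..K node, >K none
    node_idx[node_idx > length(nodes)] <- 0L
    is_node <- node_idx > 0L

    # 2. window membership: nearest preceding same-sentence node within span
    sent <- (seq_len(N) - 1L) %/% L
    owner <- integer(N)  # 0 = no window
    for (off in seq_len(span)) {
      p <- which(is_node)
      q <- p + off
      ok <- q <= N & !is_node[pmin(q, N)] & sent[pmin(q, N)] == sent[p]
      q <- q[ok]
      p <- p[ok]
      unclaimed <- owner[q] == 0L
      owner[q[unclaimed]] <- node_idx[p[unclaimed]]
    }

    non_node_words <- setdiff(vocab$word, nodes)
    b <- vocab$prob[match(non_node_words, vocab$word)]
    b <- b / sum(b)
    names(b) <- non_node_words

    planted_words <- unique(plants$collocate)
    S <- tabulate(owner[owner > 0L & !is_node], nbins = length(nodes))
    M <- sum(!is_node)
    S_out <- M - sum(S)

    # 3. per-node window distributions: planted collocates boosted lift-fold,
    #    remaining mass renormalized over non-planted words
    q_win <- lapply(seq_along(nodes), function(j) {
      pl <- plants[plants$node == nodes[j], , drop = FALSE]
      q <- b
      q[pl$collocate] <- pl$lift * b[pl$collocate]
      boost_mass <- sum(q[pl$collocate])
      if (boost_mass >= 1) {
        stop(sprintf("plant lifts for node '%s' push window probability to %.3f >= 1",
                     nodes[j], boost_mass), call. = FALSE)
      }
      others <- setdiff(non_node_words, pl$collocate)
      q[others] <- q[others] * (1 - boost_mass) / sum(b[others])
      q
    })

    # 4. out-of-window distribution preserving each planted word's marginal
    q_out <- b
    for (w in planted_words) {
      expected_in_windows <- sum(vapply(seq_along(nodes),
                                        function(j) S[j] * q_win[[j]][w], numeric(1)))
      q_out[w] <- (M * b[w] - expected_in_windows) / S_out
      if (q_out[w] < 0) {
        stop(sprintf(
          "plant on '%s' infeasible: windows alone exceed its nominal marginal", w
        ), call. = FALSE)
      }
    }
    others <- setdiff(non_node_words, planted_words)
    q_out[others] <- q_out[others] * (1 - sum(q_out[planted_words])) / sum(b[others])

    # 5. draw tokens
    tokens <- character(N)
    tokens[is_node] <- nodes[node_idx[is_node]]
    draw_slots <- which(!is_node)
    slot_owner <- owner[draw_slots]
    for (j in c(0L, seq_along(nodes))) {
      idx <- draw_slots[slot_owner == j]
      if (!length(idx)) next
      q <- if (j == 0L) q_out else q_win[[j]]
      tokens[idx] <- sample(non_node_words, length(idx), replace = TRUE, prob = q)
    }

    # 6. interleave sentence boundaries
    n_sent <- ceiling(N / L)
    out <- character(N + n_sent)
    word_pos <- seq_len(N) + (seq_len(N) - 1L) %/% L
    out[word_pos] <- tokens
    out[-word_pos] <- EOS_TOKEN

    node_freq <- tabulate(node_idx, nbins = length(nodes))
    truth <- plants
    truth$expected_mi <- vapply(seq_len(nrow(plants)), function(i) {
      j <- match(plants$node[i], nodes)
      w <- plants$collocate[i]
      log2((S[j] * q_win[[j]][w] * N) / (node_freq[j] * span * M * b[w]))
    }, numeric(1))
    truth$mi_asymptotic <- log2(truth$lift)
    list(tokens = out, truth = truth, config = config)
  })
}

#' Render generated tokens as corpus text
#'
#' Sentence-boundary markers become periods so that [tokenize()] recovers the
#' token stream exactly.
#'
#' @param tokens token vector from [gen_corpus()].
#' @param path optional file to write; when `NULL` the text is returned.
#' @return The text (invisibly when written to `path`).
#' @export
tokens_to_text <- function(tokens, path = NULL) {
  boundary <- tokens == EOS_TOKEN
  sent_id <- cumsum(c(0, utils::head(boundary, -1)))
  sentences <- vapply(
    split(tokens[!boundary], sent_id[!boundary]),
    paste, character(1), collapse = " "
  )
  text <- paste0(sentences, ".", collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

#' Synthetic-embedding configuration
#'
#' The space is built on a valence axis: positive attribute vectors scatter
#' around `+attr_sep/2` on the axis, negative ones around `-attr_sep/2`,
#' with isotropic within-cluster noise `noise_sd`. Each target form is
#' placed at an axis coordinate solved so that its expected standardized
#' similarity gap (positive minus negative attributes, in pooled-SD units)
#' equals its planted bias; a planted bias beyond `attr_sep / noise_sd` is
#' geometrically infeasible and rejected.
#'
#' @param targets data frame `word, bias` (surface forms only) or a named
#'   list `word -> list(forms, bias)`.
#' @param dimension embedding dimension (>= 2, default 50).
#' @param n_attr attribute words per set (default 25).
#' @param attr_sep distance between the two attribute centroids along the
#'   valence axis (default 1).
#' @param noise_sd within-cluster spread of attribute vectors (default 0.1).
#' @param n_filler unbiased filler words added to the vocabulary (for
#'   baseline sampling; default 0).
#' @param seed integer seed.
#' @return List of class `synth_embedding_config`.
#' @export
synth_embedding_config <- function(targets, dimension = 50L, n_attr = 25L,
                                   attr_sep = 1, noise_sd = 0.1,
                                   n_filler = 0L, seed = 1L) {
  if (is.data.frame(targets)) {
    stopifnot(all(c("word", "bias") %in% names(targets)))
    targets <- stats::setNames(
      lapply(seq_len(nrow(targets)), function(i) {
        list(forms = targets$word[i], bias = targets$bias[i])
      }),
      targets$word
    )
  }
  stopifnot(dimension >= 2, n_attr >= 2, attr_sep > 0, noise_sd > 0)
  feasible_max <- attr_sep / noise_sd
  for (w in names(targets)) {
    if (abs(targets[[w]]$bias) >= feasible_max) {
      stop(sprintf(
        "planted bias %.2f for '%s' infeasible: |bias| must be < attr_sep/noise_sd = %.2f",
        targets[[w]]$bias, w, feasible_max
      ), call. = FALSE)
    }
  }
  structure(
    list(targets = targets, dimension = as.integer(dimension),
         n_attr = as.integer(n_attr), attr_sep = attr_sep,
         noise_sd = noise_sd, n_filler = as.integer(n_filler),
         seed = as.integer(seed)),
    class = "synth_embedding_config"
  )
}

# random unit vector orthogonal to the first axis
.unit_orth <- function(d) {
  z <- c(0, stats::rnorm(d - 1))
  z / sqrt(sum(z^2))
}

#' Generate a synthetic embedding space with planted bias
#'
#' Attribute vectors: `centroid + noise_sd * N(0, I)`. Each target form is
#' `beta * axis + z` with `z` a random unit vector orthogonal to the valence
#' axis and `beta` solved from the planted standardized bias `g*`:
#' `beta = sign(g*) * sqrt(g*^2 s^2 / (sep^2 - g*^2 s^2))` with
#' `s = noise_sd`, `sep = attr_sep` (from equating the expected standardized
#' similarity gap `sep * beta / (s * |t|)` to `g*`). Attribute words take
#' the packaged valence attribute names; fillers are unbiased unit vectors
#' orthogonal to the axis.
#'
#' @param config a [synth_embedding_config()].
#' @return List with `space` (an [embedding_space()]), `truth` (word, form,
#'   planted bias, axis coordinate), `sets` (the [attribute_sets()] placed in
#'   the space), and `config`.
#' @export
gen_embeddings <- function(config) {
  stopifnot(inherits(config, "synth_embedding_config"))
  with_seed(config$seed, {
    d <- config$dimension
    a <- config$attr_sep / 2
    s <- config$noise_sd
    base_sets <- default_attribute_sets()
    pos_names <- utils::head(c(base_sets$positive,
                               sprintf("posattr%02d", seq_len(config$n_attr))),
                             config$n_attr)
    neg_names <- utils::head(c(base_sets$negative,
                               sprintf("negattr%02d", seq_len(config$n_attr))),
                             config$n_attr)
    axis <- c(1, rep(0, d - 1))
    pos_mat <- t(vapply(seq_len(config$n_attr),
                        function(i) a * axis + s * stats::rnorm(d), numeric(d)))
    neg_mat <- t(vapply(seq_len(config$n_attr),
                        function(i) -a * axis + s * stats::rnorm(d), numeric(d)))
    rownames(pos_mat) <- pos_names
    rownames(neg_mat) <- neg_names

    rows <- list(pos_mat, neg_mat)
    truth <- list()
    for (w in names(config$targets)) {
      tgt <- config$targets[[w]]
      gstar <- tgt$bias
      denom <- config$attr_sep^2 - gstar^2 * s^2
      beta <- sign(gstar) * sqrt(gstar^2 * s^2 / denom)
      for (f in tgt$forms) {
        v <- beta * axis + .unit_orth(d)
        rows[[length(rows) + 1]] <- matrix(v, 1, d, dimnames = list(f))
        truth[[length(truth) + 1]] <- data.frame(
          word = w, form = f, planted_bias = gstar, beta = beta,
          stringsAsFactors = FALSE
        )
      }
    }
    if (config$n_filler > 0) {
      fill <- t(vapply(seq_len(config$n_filler), function(i) .unit_orth(d), numeric(d)))
      rownames(fill) <- sprintf("filler%04d", seq_len(config$n_filler))
      rows[[length(rows) + 1]] <- fill
    }
    mat <- do.call(rbind, rows)
    list(
      space = embedding_space(mat),
      truth = do.call(rbind, truth),
      sets = attribute_sets(pos_names, neg_names),
      config = config
    )
  })
}

#' Synthetic evaluative-priming trial configuration
#'
#' Defaults mirror the canonical two-study design: `"study1"` has 8
#' semantically prosodic primes (4 positive, 4 negative) and 8 matched
#' controls, word targets, 78 participants, and 64 experimental trials per
#' participant (each prime four times: twice before a positive and twice
#' before a negative target); `"study2"` adds 8 strongly valenced primes,
#' uses picture-label targets, 89 participants, and 96 experimental trials.
#'
#' Reaction times follow a lognormal model: per-participant intercept
#' `b_i ~ N(0, tau_participant^2)`; trial log RT =
#' `mu_log + b_i + delta[prime_type]/2` for congruent prime-target pairings
#' and `- delta[prime_type]/2` for incongruent, plus `N(0, sigma_log^2)`
#' residual noise; `rt_ms = exp(log RT)`. `delta` is the congruent-minus-
#' incongruent log-RT effect, so negative values mean congruent facilitation;
#' defaults (valenced -0.075, prosodic -0.060, control 0) are fixtures
#' echoing the magnitude of a ~45 ms congruity spread around ~600 ms, not
#' estimates. Accuracy is Bernoulli(1 - error_rate), independent of
#' condition.
#'
#' @param study `"study1"` or `"study2"` preset (sets every default below).
#' @param n_participants number of participants.
#' @param primes data frame `prime, prime_type, prime_valence`.
#' @param targets data frame `target, target_valence`.
#' @param trials_per_prime presentations of each prime, split equally between
#'   target valences (must be even; default 4).
#' @param mu_log baseline log RT (default `log(640)` for study1,
#'   `log(590)` for study2).
#' @param sigma_log residual SD on the log scale (default 0.20).
#' @param tau_participant SD of participant random intercepts (default 0.15).
#' @param delta named congruity effects per prime type (log units,
#'   congruent minus incongruent).
#' @param error_rate probability of an inaccurate response (default 0.04).
#' @param n_practice practice trials per participant (default 16 for study1,
#'   12 for study2; drawn with valenced primes when available).
#' @param seed integer seed.
#' @return List of class `synth_trial_config`.
#' @export
synth_trial_config <- function(study = c("study1", "study2"),
                               n_participants = NULL,
                               primes = NULL, targets = NULL,
                               trials_per_prime = 4L,
                               mu_log = NULL, sigma_log = 0.20,
                               tau_participant = 0.15,
                               delta = c(valenced = -0.075, prosodic = -0.060,
                                         control = 0),
                               error_rate = 0.04,
                               n_practice = NULL,
                               seed = 1L) {
  study <- match.arg(study)
  prosodic <- data.frame(
    prime = c("gain", "guarantee", "restore", "provide",
              "cause", "commit", "ease", "peddle"),
    prime_type = "prosodic",
    prime_valence = rep(c("positive", "negative"), each = 4),
    stringsAsFactors = FALSE
  )
  control <- data.frame(
    prime = c("reply", "describe", "consider", "indicate",
              "refer", "relate", "convey", "denote"),
    prime_type = "control",
    prime_valence = rep(c("positive", "negative"), each = 4),
    stringsAsFactors = FALSE
  )
  valenced <- data.frame(
    prime = c("comfort", "cherish", "admire", "praise",
              "hate", "despise", "torture", "ruin"),
    prime_type = "valenced",
    prime_valence = rep(c("positive", "negative"), each = 4),
    stringsAsFactors = FALSE
  )
  if (is.null(primes)) {
    primes <- if (study == "study1") rbind(prosodic, control)
      else rbind(valenced, prosodic, control)
  }
  if (is.null(targets)) {
    targets <- if (study == "study1") {
      data.frame(
        target = c("comedy", "joy", "delight", "sunshine", "laughter", "creativity",
                   "rapist", "racism", "bigotry", "greed", "insult", "nightmares"),
        target_valence = rep(c("positive", "negative"), each = 6),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(
        target = c(sprintf("picture_pos_%02d", 1:12), sprintf("picture_neg_%02d", 1:12)),
        target_valence = rep(c("positive", "negative"), each = 12),
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(n_participants)) n_participants <- if (study == "study1") 78L else 89L
  if (is.null(mu_log)) mu_log <- if (study == "study1") log(640) else log(590)
  if (is.null(n_practice)) n_practice <- if (study == "study1") 16L else 12L
  trials_per_prime <- as.integer(trials_per_prime)
  stopifnot(trials_per_prime %% 2L == 0L, trials_per_prime >= 2L,
            sigma_log > 0, tau_participant > 0,
            error_rate >= 0, error_rate < 1,
            all(primes$prime_type %in% PRIME_TYPES),
            all(names(delta) %in% PRIME_TYPES),
            all(unique(primes$prime_type) %in% names(delta)),
            all(c("positive", "negative") %in% targets$target_valence))
  structure(
    list(study = study, n_participants = as.integer(n_participants),
         primes = primes, targets = targets,
         trials_per_prime = trials_per_prime,
         mu_log = mu_log, sigma_log = sigma_log,
         tau_participant = tau_participant, delta = delta,
         error_rate = error_rate, n_practice = as.integer(n_practice),
         seed = as.integer(seed)),
    class = "synth_trial_config"
  )
}

#' Generate synthetic evaluative-priming trials
#'
#' @param config a [synth_trial_config()].
#' @return List with `trials` (a validated trial data frame, experimental
#'   plus practice phases, trial order randomized within participant) and
#'   `truth` (the generating parameters).
#' @export
gen_trials <- function(config = synth_trial_config()) {
  stopifnot(inherits(config, "synth_trial_config"))
  with_seed(config$seed, {
    n_sub <- config$n_participants
    primes <- config$primes
    half <- config$trials_per_prime %/% 2L
    # per participant: every prime x (half positive-target, half negative-target)
    base <- primes[rep(seq_len(nrow(primes)), each = config$trials_per_prime), , drop = FALSE]
    base$target_valence <- rep(rep(c("positive", "negative"), each = half),
                               times = nrow(primes))
    n_exp <- nrow(base)

    pos_targets <- config$targets$target[config$targets$target_valence == "positive"]
    neg_targets <- config$targets$target[config$targets$target_valence == "negative"]

    one_participant <- function(pid, b_i) {
      df <- base
      df$target <- ifelse(df$target_valence == "positive",
                          sample(pos_targets, n_exp, replace = TRUE),
                          sample(neg_targets, n_exp, replace = TRUE))
      df$phase <- "experimental"
      if (config$n_practice > 0) {
        ptypes <- if ("valenced" %in% primes$prime_type) "valenced"
          else unique(primes$prime_type)[1]
        ppool <- primes[primes$prime_type %in% ptypes, , drop = FALSE]
        pr <- ppool[sample(nrow(ppool), config$n_practice, replace = TRUE), , drop = FALSE]
        pr$target_valence <- sample(c("positive", "negative"), config$n_practice,
                                    replace = TRUE)
        pr$target <- ifelse(pr$target_valence == "positive",
                            sample(pos_targets, config$n_practice, replace = TRUE),
                            sample(neg_targets, config$n_practice, replace = TRUE))
        pr$phase <- "practice"
        df <- rbind(pr, df)
      }
      # practice first, experimental order shuffled
      df[df$phase == "experimental", ] <-
        df[sample(which(df$phase == "experimental")), ]
      n <- nrow(df)
      congruent <- df$prime_valence == df$target_valence
      shift <- ifelse(congruent, 1, -1) * config$delta[df$prime_type] / 2
      log_rt <- config$mu_log + b_i + shift + stats::rnorm(n, 0, config$sigma_log)
      df$rt_ms <- exp(log_rt)
      df$accurate <- stats::runif(n) >= config$error_rate
      df$response <- ifelse(df$accurate, df$target_valence,
                            ifelse(df$target_valence == "positive", "negative", "positive"))
      df$participant_id <- pid
      df$trial_index <- seq_len(n) - 1L
      df
    }

    ids <- sprintf("p%03d", seq_len(n_sub))
    b <- stats::rnorm(n_sub, 0, config$tau_participant)
    trials <- do.call(rbind, Map(one_participant, ids, b))
    rownames(trials) <- NULL
    trials <- validate_trials(trials, context = "gen_trials")
    list(
      trials = trials,
      truth = list(
        delta = config$delta, mu_log = config$mu_log,
        sigma_log = config$sigma_log, tau_participant = config$tau_participant,
        error_rate = config$error_rate,
        n_experimental_per_participant = n_exp
      )
    )
  })
}

#' Synthetic valence lexicon
#'
#' A fixture lexicon covering the default generators' vocabulary: planted
#' collocates at their nominal valences, node words near the neutral
#' midpoint, targets at the extremes, and fillers near 5.
#'
#' @param seed seed for the filler jitter.
#' @return A [valence_lexicon()].
#' @export
synth_valence_lexicon <- function(seed = 1L) {
  with_seed(seed, {
    fixed <- data.frame(
      word = c("cause", "restore", "death", "pain", "order", "health",
               "gain", "guarantee", "provide", "commit", "ease", "peddle",
               "comedy", "joy", "delight", "sunshine", "laughter", "creativity",
               "rapist", "racism", "bigotry", "greed", "insult", "nightmares"),
      valence_mean = c(5.1, 5.9, 1.54, 2.06, 5.48, 7.54,
                       6.0, 5.7, 5.9, 4.9, 5.5, 4.7,
                       8.05, 8.21, 8.21, 8.14, 8.05, 7.73,
                       1.30, 1.48, 2.24, 2.48, 2.62, 1.79),
      stringsAsFactors = FALSE
    )
    filler <- data.frame(
      word = sprintf("w%03d", 1:120),
      valence_mean = pmin(9, pmax(1, stats::rnorm(120, 5, 0.6))),
      stringsAsFactors = FALSE
    )
    lex <- rbind(fixed, filler)
    valence_lexicon(lex$word, round(lex$valence_mean, 2))
  })
}
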