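# Embedding-based valence bias: the standardized difference (Hedges g)
# between a word's cosine similarities to a positive attribute set and to a
# negative attribute set. Positive g = positive-leaning. "Distance" in the
# distributional-semantics sense is read as cosine similarity (higher = more
# associated); that is the only reading under which a positive-leaning word
# gets a positive score.

#' Attribute word sets
#'
#' @param positive,negative character vectors of attribute words; both
#'   nonempty and disjoint. The conventional design uses 25 of each.
#' @return A list of class `attribute_sets`.
#' @export
attribute_sets <- function(positive, negative) {
  positive <- tolower(as.character(positive))
  negative <- tolower(as.character(negative))
  stopifnot(length(positive) >= 1, length(negative) >= 1)
  if (length(intersect(positive, negative))) {
    stop("attribute sets must be disjoint", call. = FALSE)
  }
  structure(list(positive = positive, negative = negative),
            class = "attribute_sets")
}

#' Packaged 25+25 valence attribute sets
#'
#' The standard pleasant/unpleasant attribute word lists used throughout the
#' implicit-association literature. This is a reconstruction of the common
#' published lists, not verified against any particular study's materials.
#'
#' @return An [attribute_sets()] with 25 positive and 25 negative words.
#' @export
default_attribute_sets <- function() {
  path <- system.file("extdata", "attribute_sets_valence.csv", package = "semprosody")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attribute_sets(df$word[df$set == "positive"], df$word[df$set == "negative"])
}

#' Cosine similarity
#'
#' @param u,v numeric vectors of equal dimension, both nonzero.
#' @return Cosine of the angle between `u` and `v`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector", call. = FALSE)
  sum(u * v) / (nu * nv)
}

# rows x rows cosine matrix between two word sets already known to be in the
# space (vectors validated nonzero at load).
cosine_matrix <- function(space, words_a, words_b) {
  a <- space$vectors[words_a, , drop = FALSE]
  b <- space$vectors[words_b, , drop = FALSE]
  a <- a / sqrt(rowSums(a^2))
  b <- b / sqrt(rowSums(b^2))
  tcrossprod(a, b)
}

#' Similarity samples of target forms to the attribute sets
#'
#' Builds the two similarity samples underlying the bias score: every pairing
#' of a found target form with a found positive attribute word, and likewise
#' for the negative set. Out-of-vocabulary forms or attributes are dropped
#' and reported, never imputed.
#'
#' @param forms character vector of target word forms (e.g., the verb tenses
#'   of one word, or all forms of a word group).
#' @param space an [embedding_space()].
#' @param sets an [attribute_sets()].
#' @return List with `pos_sample`, `neg_sample` (numeric vectors of cosines),
#'   `forms_found`, `oov` (forms not in the space), and the per-set attribute
#'   OOV lists.
#' @export
attribute_similarities <- function(forms, space, sets) {
  stopifnot(inherits(space, "embedding_space"), inherits(sets, "attribute_sets"))
  forms <- tolower(as.character(forms))
  found <- forms[forms %in% space$vocab]
  oov <- setdiff(forms, space$vocab)
  if (!length(found)) {
    stop(sprintf("no form of target found in the embedding space: %s",
                 paste(forms, collapse = ", ")), call. = FALSE)
  }
  pos_found <- intersect(sets$positive, space$vocab)
  neg_found <- intersect(sets$negative, space$vocab)
  if (!length(pos_found) || !length(neg_found)) {
    stop("at least one attribute word per set must be in the space", call. = FALSE)
  }
  list(
    pos_sample = as.vector(cosine_matrix(space, found, pos_found)),
    neg_sample = as.vector(cosine_matrix(space, found, neg_found)),
    forms_found = found,
    oov = oov,
    pos_attr_oov = setdiff(sets$positive, pos_found),
    neg_attr_oov = setdiff(sets$negative, neg_found)
  )
}

#' Hedges g with a 95% confidence interval
#'
#' Bias-corrected standardized mean difference between two independent
#' samples: `d = (mean1 - mean2) / s_pooled`, `g = J * d` with
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`, and a normal-approximation interval
#' `g +/- 1.96 * SE`, `SE = sqrt((n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2 - 2)))`.
#'
#' @param sample1,sample2 numeric vectors, each of length >= 2.
#' @return List with `g`, `ci_low`, `ci_high`, `n1`, `n2`, `mean1`, `mean2`,
#'   and a `degenerate` flag (zero pooled variance with unequal means).
#' @export
hedges_g <- function(sample1, sample2) {
  n1 <- length(sample1)
  n2 <- length(sample2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(sample1)
  m2 <- mean(sample2)
  df <- n1 + n2 - 2
  s_pooled <- sqrt(((n1 - 1) * stats::var(sample1) + (n2 - 1) * stats::var(sample2)) / df)
  degenerate <- FALSE
  if (s_pooled == 0) {
    if (m1 == m2) {
      g <- 0
    } else {
      g <- sign(m1 - m2) * Inf
      degenerate <- TRUE
    }
  } else {
    J <- 1 - 3 / (4 * df - 1)
    g <- J * (m1 - m2) / s_pooled
  }
  se <- sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df))
  list(
    g = g,
    ci_low = g - 1.96 * se,
    ci_high = g + 1.96 * se,
    n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
    degenerate = degenerate
  )
}

new_bias_result <- function(target_words, sims, gres) {
  structure(
    list(
      target_words = target_words,
      forms_found = sims$forms_found,
      n_pos = gres$n1, n_neg = gres$n2,
      mean_pos = gres$mean1, mean_neg = gres$mean2,
      g = gres$g, ci_low = gres$ci_low, ci_high = gres$ci_high,
      oov = sims$oov,
      degenerate = gres$degenerate
    ),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  words <- x$target_words
  label <- if (length(words) > 6) {
    sprintf("%s, ... (%d words)", paste(utils::head(words, 5), collapse = ", "),
            length(words))
  } else {
    paste(words, collapse = "+")
  }
  cat(sprintf(
    "<bias_result> %s: g = %.3f, 95%% CI [%.3f, %.3f] (n_pos = %d, n_neg = %d%s)\n",
    label, x$g, x$ci_low, x$ci_high, x$n_pos, x$n_neg,
    if (length(x$oov)) sprintf("; %d OOV", length(x$oov)) else ""
  ))
  invisible(x)
}

#' Valence bias of one word in an embedding space
#'
#' Pools the cosine similarities of each inflected form of `word` to the
#' positive attribute set and to the negative attribute set, and summarizes
#' the gap as Hedges g with a 95% CI. Positive g means the word inhabits
#' positive company.
#'
#' @param word the target word.
#' @param space an [embedding_space()].
#' @param sets an [attribute_sets()]; defaults to the packaged valence sets.
#' @param forms inflected forms to pool; defaults to [verb_forms]`(word)`.
#' @return A `bias_result`.
#' @export
word_bias <- function(word, space, sets = default_attribute_sets(),
                      forms = verb_forms(word)) {
  sims <- attribute_similarities(forms, space, sets)
  new_bias_result(word, sims, hedges_g(sims$pos_sample, sims$neg_sample))
}

#' Valence bias of a word group
#'
#' Pools all forms of all group members into the two similarity samples; a
#' one-member group reduces exactly to [word_bias()].
#'
#' @param words_with_forms named list: one character vector of forms per
#'   group member (or a bare character vector of words, expanded with
#'   [verb_forms()]).
#' @inheritParams word_bias
#' @return A `bias_result`.
#' @export
group_bias <- function(words_with_forms, space, sets = default_attribute_sets()) {
  if (is.character(words_with_forms)) {
    words_with_forms <- stats::setNames(
      lapply(words_with_forms, verb_forms), words_with_forms
    )
  }
  forms <- unique(unlist(words_with_forms, use.names = FALSE))
  sims <- attribute_similarities(forms, space, sets)
  new_bias_result(names(words_with_forms), sims,
                  hedges_g(sims$pos_sample, sims$neg_sample))
}

#' Random-word baseline bias
#'
#' Samples `n_words` vocabulary items uniformly without replacement (seeded),
#' treats them as one group (surface forms only), and scores the group. On an
#' unbiased space the result should hover near g = 0; a clearly nonzero
#' baseline flags a biased vector source.
#'
#' @param space an [embedding_space()].
#' @param n_words number of words to sample (conventionally 1,000).
#' @param seed integer seed for the sample.
#' @param sets an [attribute_sets()].
#' @return A `bias_result`.
#' @export
random_baseline <- function(space, n_words, seed,
                            sets = default_attribute_sets()) {
  stopifnot(n_words >= 1)
  vocab <- setdiff(space$vocab, c(sets$positive, sets$negative))
  if (n_words > length(vocab)) {
    stop(sprintf("n_words = %d exceeds usable vocabulary (%d)",
                 n_words, length(vocab)), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sample_words <- sample(vocab, n_words)
  forms <- stats::setNames(as.list(sample_words), sample_words)
  group_bias(forms, space, sets)
}

# Preserve the caller's RNG state around seeded operations.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Default inflected forms of a verb
#'
#' Four-form set {base, -s, -ed, -ing} with standard orthographic rules
#' (final-e drop, y -> ies/ied) and a small irregular table; overridable per
#' word via the `extra` argument or by passing explicit forms to
#' [word_bias()].
#'
#' @param word base verb form.
#' @param extra named list mapping words to explicit form vectors, consulted
#'   before the rules.
#' @return Character vector of unique surface forms.
#' @export
verb_forms <- function(word, extra = list()) {
  word <- tolower(word)
  if (word %in% names(extra)) return(unique(c(word, extra[[word]])))
  irregular <- list(
    cause = c("causes", "caused", "causing"),
    commit = c("commits", "committed", "committing"),
    peddle = c("peddles", "peddled", "peddling"),
    ease = c("eases", "eased", "easing"),
    gain = c("gains", "gained", "gaining"),
    guarantee = c("guarantees", "guaranteed", "guaranteeing"),
    restore = c("restores", "restored", "restoring"),
    provide = c("provides", "provided", "providing")
  )
  if (word %in% names(irregular)) return(unique(c(word, irregular[[word]])))
  ends_e <- grepl("e$", word)
  ends_cons_y <- grepl("[^aeiou]y$", word)
  s_form <- if (ends_cons_y) sub("y$", "ies", word) else paste0(word, "s")
  ed_form <- if (ends_e) paste0(word, "d")
    else if (ends_cons_y) sub("y$", "ied", word)
    else paste0(word, "ed")
  ing_form <- if (ends_e) paste0(sub("e$", "", word), "ing") else paste0(word, "ing")
  unique(c(word, s_form, ed_form, ing_form))
}
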