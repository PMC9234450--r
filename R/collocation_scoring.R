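# Collocation extraction and frequency-weighted collocate-valence scoring.
#
# A word has semantic prosody when human raters call it neutral (valence near
# 5 on the 1-9 scale) but its corpus collocates are predominantly valenced.
# The pipeline: tokenize -> count right-window collocates -> mutual
# information -> rank/filter -> frequency-weighted collocate valence ->
# prosody classification.

#' Sentence-boundary token
#'
#' Tokenized text uses this marker as a boundary token; collocation windows
#' never cross it and it is never counted as a word.
#' @export
EOS_TOKEN <- "</s>"

#' Collocation configuration
#'
#' @param span window of tokens to the right of the node (default 4).
#' @param top_k number of most frequent collocates to keep (default 100).
#' @param mi_min mutual-information threshold in bits; records must be
#'   strictly above it to survive (default 3).
#' @param stoplist character vector of words excluded as overly common;
#'   defaults to the packaged ~200-word function-word list.
#' @return A list of class `collocation_config`.
#' @export
collocation_config <- function(span = 4L, top_k = 100L, mi_min = 3,
                               stoplist = default_stoplist()) {
  span <- as.integer(span)
  top_k <- as.integer(top_k)
  stopifnot(span >= 1L, top_k >= 1L, is.numeric(mi_min))
  structure(
    list(span = span, top_k = top_k, mi_min = mi_min,
         stoplist = tolower(as.character(stoplist))),
    class = "collocation_config"
  )
}

#' Packaged function-word stoplist
#'
#' @return Character vector of ~200 common English function words.
#' @export
default_stoplist <- function() {
  path <- system.file("extdata", "stoplist_en.txt", package = "semprosody")
  readLines(path, encoding = "UTF-8")
}

#' Tokenize text
#'
#' Splits on Unicode whitespace, strips leading/trailing punctuation (keeping
#' word-internal apostrophes and hyphens), optionally lowercases, and emits
#' [EOS_TOKEN] boundary markers after sentence-terminal punctuation
#' (`.`, `!`, `?`) and at the end of each nonempty document. Abbreviation
#' periods are not special-cased.
#'
#' @param text character vector; each element is one document.
#' @param lowercase case-fold tokens (default `TRUE`).
#' @return Character vector of tokens with boundary markers.
#' @export
tokenize <- function(text, lowercase = TRUE) {
  out <- lapply(text, function(doc) {
    if (is.na(doc) || !nzchar(trimws(doc))) return(character(0))
    raw <- strsplit(trimws(doc), "[[:space:]]+")[[1]]
    trailing <- sub("^.*?([[:punct:]]*)$", "\\1", raw)
    is_break <- grepl("[.!?]", trailing)
    stripped <- sub("^[^[:alnum:]]+", "", raw)
    stripped <- sub("[^[:alnum:]]+$", "", stripped)
    if (lowercase) stripped <- tolower(stripped)
    toks <- Map(function(w, brk) {
      c(if (nzchar(w)) w, if (brk) EOS_TOKEN)
    }, stripped, is_break)
    toks <- unlist(toks, use.names = FALSE)
    if (!length(toks)) return(character(0))
    if (toks[length(toks)] != EOS_TOKEN) toks <- c(toks, EOS_TOKEN)
    toks
  })
  unlist(out, use.names = FALSE) %||% character(0)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read and tokenize a plain-text corpus
#'
#' @param paths one or more UTF-8 text files.
#' @param docs_per_line treat each line as its own document (default:
#'   each file is one document).
#' @param lowercase case-fold tokens.
#' @return Token vector (with sentence-boundary markers).
#' @export
read_corpus_tokens <- function(paths, docs_per_line = FALSE, lowercase = TRUE) {
  docs <- unlist(lapply(paths, function(p) {
    lines <- readLines(p, encoding = "UTF-8", warn = FALSE)
    if (docs_per_line) lines else paste(lines, collapse = "\n")
  }), use.names = FALSE)
  tokenize(docs, lowercase = lowercase)
}

#' Count right-window collocates of a node word
#'
#' For every occurrence of `node`, each of the next `span` tokens counts as a
#' co-occurrence, except that windows are truncated at sentence boundaries
#' and stoplist members are skipped (they consume a window slot but add no
#' record). Unigram frequencies are whole-corpus counts excluding boundary
#' markers.
#'
#' @param tokens token vector from [tokenize()].
#' @param node the node word (case-folded to match the tokens).
#' @param config a [collocation_config()].
#' @return Data frame with columns `node, collocate, co_freq, node_freq,
#'   coll_freq, mi` (`mi` is `NA` until [add_mutual_information()]).
#' @export
count_collocates <- function(tokens, node, config = collocation_config()) {
  stopifnot(inherits(config, "collocation_config"), nzchar(node))
  node <- tolower(node)
  n <- length(tokens)
  empty <- data.frame(
    node = character(0), collocate = character(0), co_freq = integer(0),
    node_freq = integer(0), coll_freq = integer(0), mi = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!n) return(empty)
  is_word <- tokens != EOS_TOKEN
  unigram <- table(tokens[is_word])
  node_freq <- as.integer(unigram[node])
  if (is.na(node_freq) || node_freq == 0L) {
    message(sprintf("count_collocates: node '%s' absent from corpus", node))
    return(empty)
  }
  pos <- which(tokens == node)
  # eos_before[i] = number of boundary markers in tokens[1..i]; a window slot
  # p+off is inside the node's sentence iff no marker lies in (p, p+off].
  eos_cum <- cumsum(tokens == EOS_TOKEN)
  cand <- character(0)
  for (off in seq_len(config$span)) {
    q <- pos + off
    ok <- q <= n
    q <- q[ok]
    p <- pos[ok]
    same_sentence <- eos_cum[q] == eos_cum[p]
    cand <- c(cand, tokens[q][same_sentence])
  }
  cand <- cand[!(cand %in% config$stoplist)]
  if (!length(cand)) return(empty)
  co <- table(cand)
  colls <- names(co)
  data.frame(
    node = node,
    collocate = colls,
    co_freq = as.integer(co),
    node_freq = node_freq,
    coll_freq = as.integer(unigram[colls]),
    mi = NA_real_,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Collocational mutual information (bits)
#'
#' The span-normalized convention used by the English-Corpora.org (COCA)
#' interface:
#' \deqn{MI = \log_2\frac{co\_freq \cdot N}{node\_freq \cdot coll\_freq \cdot span}}
#' Note other PMI conventions omit the span term and differ by `log2(span)`.
#'
#' @param co_freq,node_freq,coll_freq co-occurrence and unigram counts
#'   (vectorized; all must be >= 1).
#' @param corpus_size total word-token count of the corpus.
#' @param span window width used when counting.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(co_freq, node_freq, coll_freq, corpus_size, span) {
  if (any(corpus_size <= 0)) stop("corpus_size must be positive", call. = FALSE)
  if (any(co_freq < 1) || any(node_freq < 1) || any(coll_freq < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  log2((co_freq * corpus_size) / (node_freq * coll_freq * span))
}

#' Fill the MI column of a collocate table
#'
#' @param records output of [count_collocates()].
#' @param corpus_size total word-token count (boundary markers excluded).
#' @param span window width; defaults to the config default of 4.
#' @return `records` with `mi` populated.
#' @export
add_mutual_information <- function(records, corpus_size, span = 4L) {
  if (!nrow(records)) return(records)
  records$mi <- mutual_information(
    records$co_freq, records$node_freq, records$coll_freq, corpus_size, span
  )
  records
}

#' Filter and rank collocates
#'
#' Drops stoplist members and records at or below the MI threshold (the
#' threshold is strict: a record at exactly `mi_min` bits is excluded), ranks
#' by `co_freq` descending, and keeps the top `top_k`. Ties in `co_freq`
#' break by higher MI, then lexicographically, so output is deterministic.
#'
#' @param records collocate table with `mi` filled.
#' @param config a [collocation_config()].
#' @param quiet suppress the survivor-count message.
#' @return The filtered, ranked collocate table.
#' @export
top_collocates <- function(records, config = collocation_config(), quiet = FALSE) {
  if (anyNA(records$mi) && nrow(records)) {
    stop("MI not computed; call add_mutual_information() first", call. = FALSE)
  }
  keep <- records[!(records$collocate %in% config$stoplist) &
                    records$mi > config$mi_min, , drop = FALSE]
  ord <- order(-keep$co_freq, -keep$mi, keep$collocate)
  keep <- keep[ord, , drop = FALSE]
  out <- utils::head(keep, config$top_k)
  rownames(out) <- NULL
  if (!quiet && nrow(out) < config$top_k) {
    message(sprintf("top_collocates: %d of requested %d collocates qualify",
                    nrow(out), config$top_k))
  }
  out
}

#' Frequency-weighted average collocate valence
#'
#' Matches each ranked collocate to the valence lexicon and averages the
#' valences weighted by co-occurrence frequency (or, behind the `weight`
#' flag, by collocate corpus frequency). Collocates missing from the lexicon
#' are excluded from both numerator and denominator and counted in the
#' report.
#'
#' @param ranked output of [top_collocates()].
#' @param lexicon a [valence_lexicon()].
#' @param explicit_valence the node's own rated valence (optional; needed by
#'   [classify_prosody()]).
#' @param weight `"co_freq"` (default) or `"coll_freq"`.
#' @param quiet suppress the missing-collocate message.
#' @return An object of class `prosody_score`.
#' @export
weighted_collocate_valence <- function(ranked, lexicon, explicit_valence = NA_real_,
                                       weight = c("co_freq", "coll_freq"),
                                       quiet = FALSE) {
  weight <- match.arg(weight)
  node <- if (nrow(ranked)) ranked$node[[1]] else NA_character_
  v <- valence_of(lexicon, ranked$collocate)
  found <- !is.na(v)
  if (!quiet && any(!found)) {
    message(sprintf("weighted_collocate_valence: %d of %d collocates not in lexicon",
                    sum(!found), length(found)))
  }
  w <- ranked[[weight]][found]
  score <- structure(
    list(
      node = node,
      n_collocates_used = sum(found),
      total_weight = sum(w),
      weighted_valence = if (sum(found)) sum(w * v[found]) / sum(w) else NA_real_,
      explicit_valence = explicit_valence,
      label = "indeterminate"
    ),
    class = "prosody_score"
  )
  if (score$n_collocates_used > 0 && !is.na(explicit_valence)) {
    score <- classify_prosody(score)
  }
  score
}

#' @export
print.prosody_score <- function(x, ...) {
  cat(sprintf(
    "<prosody_score> node '%s': weighted collocate valence %.3f (%d collocates, weight %d), explicit %.2f -> %s\n",
    x$node, x$weighted_valence, x$n_collocates_used, x$total_weight,
    x$explicit_valence, x$label
  ))
  invisible(x)
}

#' Classify a word's prosody
#'
#' A word is semantically prosodic when its own rated valence sits in the
#' neutral band but its collocates pull clearly to one pole:
#' `positive_prosody` iff explicit valence is inside `neutral_band` and the
#' weighted collocate valence is at least `5 + prosody_margin`;
#' `negative_prosody` analogously below `5 - prosody_margin`; `valenced` iff
#' the explicit valence falls outside the band; otherwise `non_prosodic`.
#' Defaults: band `[4.5, 6]`, margin `0.5`.
#'
#' @param score a `prosody_score`.
#' @param neutral_band numeric length-2, explicit-valence range called neutral.
#' @param prosody_margin distance from the scale midpoint (5) that the
#'   weighted collocate valence must reach.
#' @return The score with `label` set (plus the thresholds used, as
#'   attributes `neutral_band` / `prosody_margin`).
#' @export
classify_prosody <- function(score, neutral_band = c(4.5, 6.0), prosody_margin = 0.5) {
  stopifnot(inherits(score, "prosody_score"),
            length(neutral_band) == 2, neutral_band[1] <= neutral_band[2],
            prosody_margin >= 0)
  ev <- score$explicit_valence
  wv <- score$weighted_valence
  label <- if (is.na(ev) || score$n_collocates_used == 0) {
    "indeterminate"
  } else if (ev < neutral_band[1] || ev > neutral_band[2]) {
    "valenced"
  } else if (wv >= 5 + prosody_margin) {
    "positive_prosody"
  } else if (wv <= 5 - prosody_margin) {
    "negative_prosody"
  } else {
    "non_prosodic"
  }
  score$label <- label
  attr(score, "neutral_band") <- neutral_band
  attr(score, "prosody_margin") <- prosody_margin
  score
}

#' End-to-end prosody score for one node word
#'
#' Convenience wrapper: counts collocates, computes MI, filters/ranks, and
#' returns the weighted-collocate-valence score with classification.
#'
#' @param tokens tokenized corpus.
#' @param node node word.
#' @param lexicon valence lexicon for the collocates.
#' @param explicit_valence the node's rated valence (looked up in `lexicon`
#'   when omitted).
#' @param config a [collocation_config()].
#' @param ... passed to [classify_prosody()].
#' @return A `prosody_score`.
#' @export
score_prosody <- function(tokens, node, lexicon, explicit_valence = NULL,
                          config = collocation_config(), ...) {
  if (is.null(explicit_valence)) {
    explicit_valence <- unname(valence_of(lexicon, node))
  }
  recs <- count_collocates(tokens, node, config)
  corpus_size <- sum(tokens != EOS_TOKEN)
  if (nrow(recs)) recs <- add_mutual_information(recs, corpus_size, config$span)
  ranked <- top_collocates(recs, config, quiet = TRUE)
  score <- weighted_collocate_valence(ranked, lexicon, explicit_valence, quiet = TRUE)
  classify_prosody(score, ...)
}
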