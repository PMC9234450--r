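#' @keywords internal
"_PACKAGE"

# Column order of the canonical trial-level CSV. Milliseconds are the native
# reaction-time unit throughout.
TRIAL_COLUMNS <- c(
  "participant_id", "trial_index", "phase", "prime", "prime_type",
  "prime_valence", "target", "target_valence", "response", "accurate", "rt_ms"
)

PHASE_LEVELS <- c("practice", "experimental")
PRIME_TYPES <- c("valenced", "prosodic", "control")
VALENCE_LEVELS <- c("positive", "negative")

#' Construct a valence lexicon
#'
#' A valence lexicon maps lowercased words to mean pleasantness ratings on a
#' 1 (unpleasant) -- 9 (pleasant) scale, with 5 the neutral midpoint, plus an
#' optional rating SD. Lookups of absent words return `NA`, never a default.
#'
#' @param word character vector of words (case-folded on construction).
#' @param valence_mean numeric vector of mean ratings, all in `[1, 9]`.
#' @param valence_sd optional numeric vector of nonnegative rating SDs.
#' @return An object of class `valence_lexicon`.
#' @export
valence_lexicon <- function(word, valence_mean, valence_sd = NULL) {
  word <- tolower(as.character(word))
  valence_mean <- as.numeric(valence_mean)
  if (length(word) != length(valence_mean)) {
    stop("`word` and `valence_mean` must have equal length", call. = FALSE)
  }
  bad <- which(!is.finite(valence_mean) | valence_mean < 1 | valence_mean > 9)
  if (length(bad)) {
    stop(sprintf(
      "valence_mean outside [1, 9] at row(s): %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  if (anyDuplicated(word)) {
    dup <- unique(word[duplicated(word)])
    stop(sprintf(
      "duplicate words after lowercasing: %s",
      paste(dup, collapse = ", ")
    ), call. = FALSE)
  }
  if (!is.null(valence_sd)) {
    valence_sd <- as.numeric(valence_sd)
    if (length(valence_sd) != length(word)) {
      stop("`valence_sd` must match `word` in length", call. = FALSE)
    }
    if (any(valence_sd < 0, na.rm = TRUE)) {
      stop("`valence_sd` must be nonnegative", call. = FALSE)
    }
  }
  structure(
    list(
      word = word,
      valence_mean = stats::setNames(valence_mean, word),
      valence_sd = if (is.null(valence_sd)) NULL else stats::setNames(valence_sd, word)
    ),
    class = "valence_lexicon"
  )
}

#' @export
print.valence_lexicon <- function(x, ...) {
  cat(sprintf("<valence_lexicon> %d words (1-9 scale, 5 = neutral)\n", length(x$word)))
  invisible(x)
}

#' @export
length.valence_lexicon <- function(x) length(x$word)

#' Look up valence ratings
#'
#' @param lexicon a [valence_lexicon()].
#' @param words character vector; case-folded before lookup.
#' @return Named numeric vector of valence means; `NA` marks a miss.
#' @export
valence_of <- function(lexicon, words) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  words <- tolower(as.character(words))
  out <- lexicon$valence_mean[words]
  names(out) <- words
  out
}

#' Read valence norms from CSV
#'
#' Expects a UTF-8 CSV with header `word,valence_mean` and an optional
#' `valence_sd` column, emulating published word-norm tables.
#'
#' @param path path to the CSV file.
#' @param quiet suppress the row-count message.
#' @return A [valence_lexicon()].
#' @export
read_valence_norms <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("word", "valence_mean") %in% names(df))) {
    stop(sprintf(
      "valence norms file '%s' must have header columns `word,valence_mean[,valence_sd]`",
      path
    ), call. = FALSE)
  }
  lex <- valence_lexicon(
    df$word, df$valence_mean,
    valence_sd = if ("valence_sd" %in% names(df)) df$valence_sd else NULL
  )
  if (!quiet) message(sprintf("read_valence_norms: %d words from %s", nrow(df), path))
  lex
}

#' Construct an embedding space
#'
#' @param vectors numeric matrix, one row per word, words as rownames.
#' @return An object of class `embedding_space` with elements `dimension`,
#'   `vocab`, and `vectors`.
#' @export
embedding_space <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), !is.null(rownames(vectors)))
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) {
    stop(sprintf(
      "zero vector(s) for word(s): %s (cosine undefined)",
      paste(rownames(vectors)[norms == 0], collapse = ", ")
    ), call. = FALSE)
  }
  structure(
    list(dimension = ncol(vectors), vocab = rownames(vectors), vectors = vectors),
    class = "embedding_space"
  )
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d words x %d dimensions\n",
              length(x$vocab), x$dimension))
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' The text dialect: a header line `<vocab_count> <dimension>`, then one line
#' per word, `word v1 ... vdim`, space-separated. The binary word2vec format
#' is not supported; convert with any standard tool first. Duplicate words
#' keep the last occurrence (with a warning); zero vectors are rejected
#' because cosine similarity is undefined for them.
#'
#' @param path path to the text-format vector file.
#' @param quiet suppress the load message.
#' @return An [embedding_space()].
#' @export
read_embeddings <- function(path, quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty embeddings file", call. = FALSE)
  hdr <- strsplit(trimws(lines[[1]]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("embeddings header must be `<vocab_count> <dimension>`", call. = FALSE)
  }
  n_declared <- as.integer(hdr[[1]])
  dim_declared <- as.integer(hdr[[2]])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_declared) {
    warning(sprintf(
      "embeddings header declares %d words but file has %d rows",
      n_declared, length(body)
    ))
  }
  parts <- strsplit(trimws(body), "[[:space:]]+")
  nfield <- lengths(parts)
  bad <- which(nfield != dim_declared + 1L)
  if (length(bad)) {
    stop(sprintf(
      "embeddings line %d: expected %d values for word '%s', found %d",
      bad[[1]] + 1L, dim_declared, parts[[bad[[1]]]][[1]], nfield[[bad[[1]]]] - 1L
    ), call. = FALSE)
  }
  words <- vapply(parts, `[[`, character(1), 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.numeric(p[-1L]), numeric(dim_declared))
  )
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))[[1]]
    stop(sprintf("embeddings line %d: non-numeric value", bad + 1L), call. = FALSE)
  }
  mat <- t(vals)
  rownames(mat) <- words
  if (anyDuplicated(words)) {
    dup <- unique(words[duplicated(words)])
    warning(sprintf(
      "duplicate word(s) in embeddings (last occurrence kept): %s",
      paste(dup, collapse = ", ")
    ))
    keep <- !duplicated(words, fromLast = TRUE)
    mat <- mat[keep, , drop = FALSE]
  }
  space <- embedding_space(mat)
  if (!quiet) {
    message(sprintf("read_embeddings: %d words, dimension %d from %s",
                    length(space$vocab), space$dimension, path))
  }
  space
}

validate_trials <- function(df, context = "trials") {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", context,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.logical(df$accurate)) df$accurate <- as.logical(df$accurate)
  checks <- list(
    "phase not in {practice, experimental}" = !df$phase %in% PHASE_LEVELS,
    "prime_type not in {valenced, prosodic, control}" = !df$prime_type %in% PRIME_TYPES,
    "prime_valence not positive/negative" = !df$prime_valence %in% VALENCE_LEVELS,
    "target_valence not positive/negative" = !df$target_valence %in% VALENCE_LEVELS,
    "response not positive/negative" = !df$response %in% VALENCE_LEVELS,
    "rt_ms not a positive number" = !is.finite(df$rt_ms) | df$rt_ms <= 0,
    "accurate inconsistent with response == target_valence" =
      df$accurate != (df$response == df$target_valence)
  )
  for (what in names(checks)) {
    bad <- which(checks[[what]])
    if (length(bad)) {
      stop(sprintf("%s: %s at row(s): %s", context, what,
                   paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
    }
  }
  df[TRIAL_COLUMNS]
}

#' Read trial-level evaluative-priming data
#'
#' The canonical trial CSV has columns
#' `participant_id,trial_index,phase,prime,prime_type,prime_valence,target,
#' target_valence,response,accurate,rt_ms`, with reaction times in
#' milliseconds. Every row is validated: `accurate` must equal
#' `response == target_valence` and `rt_ms` must be positive.
#'
#' @param path path to the trials CSV.
#' @param quiet suppress the row-count message.
#' @return A data frame of validated trial records.
#' @export
read_trials <- function(path, quiet = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df <- validate_trials(df, context = sprintf("read_trials('%s')", path))
  df$participant_id <- as.character(df$participant_id)
  df$trial_index <- as.integer(df$trial_index)
  df$rt_ms <- as.numeric(df$rt_ms)
  if (!quiet) message(sprintf("read_trials: %d trials from %s", nrow(df), path))
  df
}

#' Write trial-level data
#'
#' Serializes with `rt_ms` at millisecond resolution to at least three
#' decimal places so that `read_trials(write_trials(x))` round-trips exactly.
#'
#' @param trials data frame of trial records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials, context = "write_trials")
  out <- trials
  out$accurate <- tolower(as.character(out$accurate))
  out$rt_ms <- sprintf("%.6f", out$rt_ms)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write valence norms to CSV
#'
#' @param lexicon a [valence_lexicon()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_valence_norms <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  df <- data.frame(
    word = lexicon$word,
    valence_mean = unname(lexicon$valence_mean),
    stringsAsFactors = FALSE
  )
  if (!is.null(lexicon$valence_sd)) df$valence_sd <- unname(lexicon$valence_sd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an embedding space in word2vec text format
#'
#' Values are serialized with full `%.17g` precision so that
#' `read_embeddings(write_embeddings(x))` round-trips exactly.
#'
#' @param space an [embedding_space()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(space$vocab), space$dimension), con)
  vals <- apply(space$vectors, 1, function(v) paste(sprintf("%.17g", v), collapse = " "))
  writeLines(paste(space$vocab, vals), con)
  invisible(path)
}

#' Read a flat key/value configuration file
#'
#' Accepts a flat YAML-style document (`key: value` per line, `#` comments).
#' Values are parsed as numbers where possible, otherwise kept as strings.
#'
#' @param path path to the config file.
#' @param quiet suppress the echo of the resolved configuration.
#' @return Named list of configuration values.
#' @export
read_config <- function(path, quiet = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.-]+)[[:space:]]*:[[:space:]]*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    stop(sprintf("config line not `key: value`: '%s'", lines[[bad[[1]]]]), call. = FALSE)
  }
  keys <- vapply(kv, `[[`, character(1), 2L)
  vals <- vapply(kv, `[[`, character(1), 3L)
  parsed <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(parsed) <- keys
  if (!quiet) {
    message("resolved config: ",
            paste(sprintf("%s=%s", keys, vals), collapse = ", "))
  }
  parsed
}
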