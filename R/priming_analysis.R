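# Inferential pipeline for evaluative-priming reaction times: accuracy
# filtering, log transform, grand-mean winsorization, fully-within-subjects
# factorial ANOVA, paired simple effects, and stimulus-property checks.

PRIMING_FACTORS <- c("prime_type", "prime_valence", "target_valence")

#' Preprocessing configuration for reaction times
#'
#' @param sd_mult winsorization cutoff in grand-SD units (default 2.5).
#' @param log_base `"natural"` or `"base10"`. The choice rescales log-RT
#'   units (hence CIs) but provably leaves F, t, p, dz and partial eta
#'   squared unchanged.
#' @param exclude_inaccurate drop inaccurate trials first (default `TRUE`).
#' @param practice_excluded drop practice-phase trials (default `TRUE`).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(sd_mult = 2.5, log_base = c("natural", "base10"),
                              exclude_inaccurate = TRUE, practice_excluded = TRUE) {
  log_base <- match.arg(log_base)
  stopifnot(sd_mult > 0)
  structure(
    list(sd_mult = sd_mult, log_base = log_base,
         exclude_inaccurate = exclude_inaccurate,
         practice_excluded = practice_excluded),
    class = "preprocess_config"
  )
}

#' Preprocess trial-level reaction times
#'
#' In order: (1) drop practice-phase trials; (2) drop inaccurate trials,
#' reporting the proportion removed; (3) log-transform reaction times; (4)
#' winsorize - replace log RTs beyond `sd_mult` SDs of the grand (pooled
#' across participants and conditions) log-RT mean with the cutoff value
#' itself, never dropping the trial. Pass `cutoffs` (from a previous run's
#' report) to freeze step-4 statistics, under which preprocessing is
#' idempotent.
#'
#' @param trials trial data frame (see [read_trials()]).
#' @param config a [preprocess_config()].
#' @param cutoffs optional numeric length-2 `c(lo, hi)` frozen log-RT
#'   cutoffs; when `NULL` they are computed from the data.
#' @return List with `trials` (with a `log_rt` column, winsorized) and
#'   `report` (counts at every step, the grand mean/SD, and cutoffs used).
#' @export
preprocess <- function(trials, config = preprocess_config(), cutoffs = NULL) {
  stopifnot(inherits(config, "preprocess_config"))
  trials <- validate_trials(trials, context = "preprocess")
  n_input <- nrow(trials)
  if (config$practice_excluded) trials <- trials[trials$phase == "experimental", , drop = FALSE]
  n_experimental <- nrow(trials)
  if (!n_experimental) stop("no experimental-phase trials", call. = FALSE)
  n_inaccurate <- sum(!trials$accurate)
  if (config$exclude_inaccurate) trials <- trials[trials$accurate, , drop = FALSE]
  if (!nrow(trials)) stop("no trials remain after accuracy filtering", call. = FALSE)
  logf <- if (config$log_base == "natural") log else log10
  trials$log_rt <- logf(trials$rt_ms)
  grand_mean <- mean(trials$log_rt)
  grand_sd <- stats::sd(trials$log_rt)
  if (is.null(cutoffs)) {
    cutoffs <- grand_mean + c(-1, 1) * config$sd_mult * grand_sd
  } else {
    stopifnot(length(cutoffs) == 2, cutoffs[1] <= cutoffs[2])
  }
  n_low <- sum(trials$log_rt < cutoffs[1])
  n_high <- sum(trials$log_rt > cutoffs[2])
  trials$log_rt <- pmin(pmax(trials$log_rt, cutoffs[1]), cutoffs[2])
  list(
    trials = trials,
    report = list(
      n_input = n_input,
      n_practice_removed = n_input - n_experimental,
      n_inaccurate = n_inaccurate,
      prop_inaccurate = n_inaccurate / n_experimental,
      grand_mean_log = grand_mean,
      grand_sd_log = grand_sd,
      cutoffs = cutoffs,
      n_winsorized_low = n_low,
      n_winsorized_high = n_high,
      log_base = config$log_base
    )
  )
}

#' Per-participant cell means
#'
#' Averages log RT per participant and factor-level combination. Participants
#' with any empty cell are flagged, listed in the report, and excluded (they
#' cannot enter a fully-within-subjects ANOVA).
#'
#' @param processed preprocessed trials (must carry `log_rt`).
#' @param factors character vector of factor columns (default: prime type,
#'   prime valence, target valence).
#' @return List of class `cell_means_table` with `data` (long data frame:
#'   participant, factors, `value`), `participants`, `factors` (named list of
#'   levels), and `excluded` (participants dropped for empty cells).
#' @export
cell_means <- function(processed, factors = PRIMING_FACTORS) {
  if (is.list(processed) && !is.data.frame(processed) && "trials" %in% names(processed)) {
    processed <- processed$trials
  }
  stopifnot(is.data.frame(processed), "log_rt" %in% names(processed),
            all(factors %in% names(processed)))
  levs <- lapply(processed[factors], function(x) sort(unique(as.character(x))))
  names(levs) <- factors
  key <- interaction(processed[c("participant_id", factors)], drop = FALSE, sep = "\r")
  agg <- tapply(processed$log_rt, key, mean)
  full <- expand.grid(
    c(list(participant_id = sort(unique(processed$participant_id))), levs),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  full_key <- do.call(paste, c(full, sep = "\r"))
  full$value <- as.numeric(agg[full_key])
  incomplete <- unique(full$participant_id[is.na(full$value)])
  if (length(incomplete)) {
    warning(sprintf(
      "cell_means: participant(s) with empty cell(s) excluded: %s",
      paste(incomplete, collapse = ", ")
    ))
    full <- full[!full$participant_id %in% incomplete, , drop = FALSE]
  }
  rownames(full) <- NULL
  structure(
    list(
      data = full,
      participants = sort(unique(full$participant_id)),
      factors = levs,
      excluded = incomplete
    ),
    class = "cell_means_table"
  )
}

#' @export
print.cell_means_table <- function(x, ...) {
  cat(sprintf("<cell_means_table> %d participants x %s design (%d cells)%s\n",
              length(x$participants),
              paste(lengths(x$factors), collapse = "x"),
              prod(lengths(x$factors)),
              if (length(x$excluded)) sprintf("; %d excluded", length(x$excluded)) else ""))
  invisible(x)
}

# Sum over the cells of the column subset `by` of (cell total)^2 / cell size.
# The inclusion-exclusion of these "uncorrected" sums yields every balanced
# factorial SS term (Yates' method).
.u_term <- function(df, by) {
  if (!length(by)) return(sum(df$value)^2 / nrow(df))
  key <- do.call(paste, c(df[by], sep = "\r"))
  sums <- tapply(df$value, key, sum)
  counts <- tapply(df$value, key, length)
  sum(sums^2 / counts)
}

.subsets <- function(x) {
  out <- list(character(0))
  for (el in x) out <- c(out, lapply(out, c, el))
  out[-1]
}

.term_ss <- function(df, term) {
  ss <- 0
  for (s in c(list(character(0)), .subsets(term))) {
    ss <- ss + (-1)^(length(term) - length(s)) * .u_term(df, s)
  }
  ss
}

#' Fully-within-subjects repeated-measures ANOVA
#'
#' Classical univariate decomposition on per-participant cell means: every
#' main effect and interaction is tested against its own effect-by-subject
#' interaction (`F = MS_effect / MS_effect_x_subject`), with
#' `df1 = prod(levels - 1)` and `df2 = df1 * (n_participants - 1)`, and
#' `partial_eta_sq = SS_effect / (SS_effect + SS_error)`. No sphericity
#' correction is applied (two-level factors are exempt by construction).
#'
#' @param table a [cell_means()] table (balanced; participants with empty
#'   cells must already have been excluded).
#' @return Data frame of class `rm_anova_table`: one row per effect with
#'   `effect, df1, df2, ss_effect, ss_error, F, p, partial_eta_sq`.
#' @export
rm_anova <- function(table) {
  stopifnot(inherits(table, "cell_means_table"))
  df <- table$data
  if (anyNA(df$value)) {
    stop("unbalanced table: see the cell_means() exclusion report", call. = FALSE)
  }
  n_cells <- prod(lengths(table$factors))
  if (nrow(df) != length(table$participants) * n_cells) {
    stop("unbalanced table: see the cell_means() exclusion report", call. = FALSE)
  }
  factors <- names(table$factors)
  n_sub <- length(table$participants)
  effects <- .subsets(factors)
  out <- lapply(effects, function(eff) {
    ss_eff <- .term_ss(df, eff)
    ss_err <- .term_ss(df, c("participant_id", eff))
    df1 <- prod(lengths(table$factors)[eff] - 1L)
    df2 <- df1 * (n_sub - 1L)
    ms_eff <- ss_eff / df1
    ms_err <- ss_err / df2
    Fval <- if (ms_err > 0) ms_eff / ms_err else ifelse(ms_eff > 0, Inf, 0)
    data.frame(
      effect = paste(eff, collapse = ":"),
      df1 = df1, df2 = df2,
      ss_effect = ss_eff, ss_error = ss_err,
      F = Fval,
      p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
      partial_eta_sq = if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rm_anova_table", "data.frame")
  attr(res, "n_participants") <- n_sub
  attr(res, "ss_subject") <- .term_ss(df, "participant_id")
  res
}

#' @export
print.rm_anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- round(y$F, 2)
  y$p <- format.pval(round(y$p, 3), digits = 3, eps = 0.001)
  y$partial_eta_sq <- round(y$partial_eta_sq, 3)
  y$ss_effect <- signif(y$ss_effect, 4)
  y$ss_error <- signif(y$ss_error, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

match_cell <- function(table, cell) {
  df <- table$data
  keep <- rep(TRUE, nrow(df))
  stopifnot(length(names(cell)) == length(cell),
            all(names(cell) %in% names(table$factors)))
  for (f in names(cell)) keep <- keep & df[[f]] == cell[[f]]
  sub <- df[keep, , drop = FALSE]
  if (!nrow(sub)) stop("cell specification matches no data", call. = FALSE)
  # average over any factors the cell spec leaves free
  means <- tapply(sub$value, sub$participant_id, mean)
  means[table$participants]
}

#' Paired simple effect between two design cells
#'
#' A paired t test on participant cell means: mean difference (A minus B)
#' with its 95% CI in log-RT units, t, df = n - 1, two-sided p, and the
#' within-subjects effect size `dz = mean_diff / SD(differences)`. A
#' zero-variance difference with a nonzero mean is flagged degenerate
#' (infinite t), not an error.
#'
#' @param table a [cell_means()] table.
#' @param cell_a,cell_b named lists/vectors of factor levels, e.g.
#'   `c(prime_type = "prosodic", prime_valence = "negative",
#'   target_valence = "negative")`. Factors left unspecified are averaged
#'   over within participant.
#' @return List of class `simple_effect_result`.
#' @export
simple_effect <- function(table, cell_a, cell_b) {
  stopifnot(inherits(table, "cell_means_table"))
  a <- match_cell(table, cell_a)
  b <- match_cell(table, cell_b)
  n <- length(a)
  if (n < 3) stop("simple_effect needs at least 3 participants", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    t_val <- if (md == 0) 0 else sign(md) * Inf
    res <- list(t = t_val, df = n - 1,
                p = if (md == 0) 1 else 0,
                ci = c(md, md), degenerate = md != 0)
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, ci = as.numeric(tt$conf.int), degenerate = FALSE)
  }
  structure(
    list(
      contrast = list(a = cell_a, b = cell_b),
      n = n,
      mean_diff = md,
      ci_low = res$ci[1], ci_high = res$ci[2],
      t = res$t, df = res$df, p = res$p,
      dz = if (sd_d == 0) {
        if (md == 0) 0 else sign(md) * Inf
      } else md / sd_d,
      degenerate = res$degenerate
    ),
    class = "simple_effect_result"
  )
}

#' @export
print.simple_effect_result <- function(x, ...) {
  cat(sprintf(
    "<simple_effect> diff = %.4f, 95%% CI [%.4f, %.4f], t(%d) = %.2f, p = %.3f, dz = %.2f%s\n",
    x$mean_diff, x$ci_low, x$ci_high, x$df, x$t, x$p, x$dz,
    if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' One-way between-groups ANOVA
#'
#' Used for stimulus-property checks (e.g., whether target words differ in
#' length or valence extremity across groups).
#'
#' @param values numeric vector.
#' @param groups grouping labels, same length as `values`; at least two
#'   groups with at least two values each.
#' @return One-row data frame with `effect, df1, df2, ss_effect, ss_error, F,
#'   p, partial_eta_sq`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  data.frame(
    effect = "group",
    df1 = fit$Df[1], df2 = fit$Df[2],
    ss_effect = fit$`Sum Sq`[1], ss_error = fit$`Sum Sq`[2],
    F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
    partial_eta_sq = fit$`Sum Sq`[1] / sum(fit$`Sum Sq`),
    stringsAsFactors = FALSE
  )
}

congruity_cells <- function(prime_type) {
  # within each target valence: incongruent-prime minus congruent-prime,
  # so a positive difference = congruity facilitation.
  lapply(c("negative", "positive"), function(tv) {
    congruent <- tv
    incongruent <- setdiff(c("positive", "negative"), tv)
    list(
      label = sprintf("%s primes, %s targets: incongruent - congruent prime", prime_type, tv),
      a = c(prime_type = prime_type, prime_valence = incongruent, target_valence = tv),
      b = c(prime_type = prime_type, prime_valence = congruent, target_valence = tv)
    )
  })
}

#' Full congruity analysis of one experiment
#'
#' Assembles, deterministically: the preprocessing report; raw-millisecond
#' cell means and SDs per prime type, prime valence and target valence
#' (computed from accurate, non-winsorized raw RTs; a winsorized-scale
#' alternative is included); the complete repeated-measures ANOVA table; the
#' per-prime-type simple effects (incongruent minus congruent prime, within
#' each target valence); and the per-prime-type simple prime-valence by
#' target-valence interaction.
#'
#' @param trials trial data frame.
#' @param config a [preprocess_config()].
#' @return List of class `congruity_report`.
#' @export
congruity_report <- function(trials, config = preprocess_config()) {
  pre <- preprocess(trials, config)
  tab <- cell_means(pre, PRIMING_FACTORS)

  # Table-style ms summaries from accurate raw RTs (no winsorization):
  # per-participant cell means first, then mean and SD across participants
  raw <- validate_trials(trials, context = "congruity_report")
  raw <- raw[raw$phase == "experimental" & raw$accurate, , drop = FALSE]
  pkey <- interaction(raw[c("participant_id", PRIMING_FACTORS)], drop = TRUE, sep = "\r")
  pmeans <- tapply(raw$rt_ms, pkey, mean)
  pcell <- sub("^[^\r]*\r", "", names(pmeans))
  pcell <- gsub("\r", " / ", pcell)
  ms_cells <- data.frame(
    cell = sort(unique(pcell)),
    mean_ms = as.numeric(tapply(pmeans, pcell, mean)),
    sd_ms = as.numeric(tapply(pmeans, pcell, stats::sd)),
    n_participants = as.integer(tapply(pmeans, pcell, length)),
    stringsAsFactors = FALSE
  )
  wins_ms <- exp_scale_means(pre)

  anova_tab <- rm_anova(tab)

  prime_types <- tab$factors$prime_type
  simple <- list()
  simple_interactions <- list()
  for (pt in prime_types) {
    for (cc in congruity_cells(pt)) {
      simple[[cc$label]] <- simple_effect(tab, cc$a, cc$b)
    }
    sub <- pre$trials[pre$trials$prime_type == pt, , drop = FALSE]
    sub_tab <- cell_means(sub, c("prime_valence", "target_valence"))
    sub_anova <- rm_anova(sub_tab)
    simple_interactions[[pt]] <-
      sub_anova[sub_anova$effect == "prime_valence:target_valence", , drop = FALSE]
  }

  structure(
    list(
      preprocessing = pre$report,
      ms_cell_means = ms_cells,
      ms_cell_means_winsorized = wins_ms,
      anova = anova_tab,
      simple_effects = simple,
      simple_interactions = simple_interactions,
      n_participants = length(tab$participants),
      excluded_participants = tab$excluded
    ),
    class = "congruity_report"
  )
}

# back-transformed cell means from winsorized log RTs (the alternative
# table-style summary)
exp_scale_means <- function(pre) {
  inv <- if (pre$report$log_base == "natural") exp else function(x) 10^x
  key <- interaction(pre$trials[PRIMING_FACTORS], drop = FALSE, sep = " / ")
  data.frame(
    cell = levels(key),
    mean_ms = as.numeric(tapply(inv(pre$trials$log_rt), key, mean)),
    stringsAsFactors = FALSE
  )
}

#' @export
print.congruity_report <- function(x, ...) {
  cat(sprintf("<congruity_report> %d participants; %.1f%% inaccurate trials removed\n",
              x$n_participants, 100 * x$preprocessing$prop_inaccurate))
  cat("\nCell means, ms (accurate raw RTs):\n")
  y <- x$ms_cell_means
  y$mean_ms <- round(y$mean_ms)
  y$sd_ms <- round(y$sd_ms)
  print(y, row.names = FALSE)
  cat("\nRepeated-measures ANOVA (log RT):\n")
  print(x$anova)
  cat("\nSimple effects (incongruent - congruent prime):\n")
  for (nm in names(x$simple_effects)) {
    s <- x$simple_effects[[nm]]
    cat(sprintf("  %s: diff = %.4f [%.4f, %.4f], t(%d) = %.2f, p = %.3f, dz = %.2f\n",
                nm, s$mean_diff, s$ci_low, s$ci_high, s$df, s$t, s$p, s$dz))
  }
  invisible(x)
}
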