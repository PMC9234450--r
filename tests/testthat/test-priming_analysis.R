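test_that("preprocessing logs, filters, and winsorizes as specified", {
  tr <- toy_trials()
  tr$accurate <- TRUE
  tr$response <- tr$target_valence
  pre <- preprocess(tr)
  expect_equal(pre$trials$log_rt, log(tr$rt_ms))
  expect_equal(pre$report$n_winsorized_low + pre$report$n_winsorized_high, 0)
  expect_equal(pre$report$prop_inaccurate, 0)

  # inaccurate and practice trials are removed and reported
  tr2 <- toy_trials()
  tr2$phase[4] <- "practice"
  pre2 <- preprocess(tr2)
  expect_equal(pre2$report$n_practice_removed, 1)
  expect_equal(pre2$report$n_inaccurate, 1)
  expect_equal(pre2$report$prop_inaccurate, 1 / 3)
  expect_equal(nrow(pre2$trials), 2)
})

test_that("a planted outlier is replaced by the recomputed log cutoff", {
  set.seed(31)
  n <- 1000
  tr <- data.frame(
    participant_id = "p1", trial_index = seq_len(n) - 1L, phase = "experimental",
    prime = "cause", prime_type = "prosodic", prime_valence = "negative",
    target = "racism", target_valence = "negative", response = "negative",
    accurate = TRUE, rt_ms = exp(rnorm(n, log(640), 0.15)),
    stringsAsFactors = FALSE
  )
  tr$rt_ms[500] <- 50000  # extreme slow response
  pre <- preprocess(tr)
  # independent recomputation of the cutoff
  lr <- log(tr$rt_ms)
  hi <- mean(lr) + 2.5 * sd(lr)
  expect_equal(pre$trials$log_rt[500], hi)
  expect_equal(pre$report$n_winsorized_high, sum(lr > hi))
  expect_true(all(pre$trials$log_rt <= hi))
})

test_that("preprocessing is idempotent under frozen cutoffs", {
  g <- gen_trials(synth_trial_config("study1", n_participants = 8, seed = 3))
  p1 <- preprocess(g$trials)
  frozen <- p1$report$cutoffs
  tr2 <- p1$trials
  tr2$rt_ms <- exp(tr2$log_rt)  # feed winsorized RTs back through
  p2 <- preprocess(tr2, cutoffs = frozen)
  expect_equal(p2$trials$log_rt, p1$trials$log_rt, tolerance = 1e-12)
  expect_equal(p2$report$n_winsorized_low + p2$report$n_winsorized_high, 0)
})

test_that("log base changes units but not F, t, p, dz or partial eta squared", {
  g <- gen_trials(synth_trial_config("study1", n_participants = 12, seed = 8))
  rep_e <- congruity_report(g$trials, preprocess_config(log_base = "natural"))
  rep_10 <- congruity_report(g$trials, preprocess_config(log_base = "base10"))
  expect_equal(rep_10$anova$F, rep_e$anova$F, tolerance = 1e-9)
  expect_equal(rep_10$anova$partial_eta_sq, rep_e$anova$partial_eta_sq, tolerance = 1e-9)
  s_e <- rep_e$simple_effects[[3]]
  s_10 <- rep_10$simple_effects[[3]]
  expect_equal(s_10$t, s_e$t, tolerance = 1e-9)
  expect_equal(s_10$dz, s_e$dz, tolerance = 1e-9)
  # CIs differ by exactly the log-base change of units
  expect_equal(s_10$mean_diff, s_e$mean_diff / log(10), tolerance = 1e-9)
})

test_that("cell means equal a naive group-by oracle and ignore trial order", {
  g <- gen_trials(synth_trial_config("study1", n_participants = 78, seed = 5))
  pre <- preprocess(g$trials)
  tab <- cell_means(pre)
  expect_equal(nrow(tab$data), 78 * 8)

  oracle <- aggregate(
    log_rt ~ participant_id + prime_type + prime_valence + target_valence,
    data = pre$trials, FUN = mean
  )
  key <- function(d) paste(d$participant_id, d$prime_type, d$prime_valence, d$target_valence)
  m <- match(key(tab$data), key(oracle))
  expect_false(anyNA(m))
  expect_equal(tab$data$value, oracle$log_rt[m], tolerance = 1e-12)

  shuffled <- pre$trials[sample(nrow(pre$trials)), ]
  tab2 <- cell_means(list(trials = shuffled))
  expect_equal(tab2$data, tab$data)

  # participants with an empty cell are flagged and excluded
  drop <- pre$trials
  drop <- drop[!(drop$participant_id == "p001" & drop$prime_type == "prosodic" &
                   drop$prime_valence == "negative" & drop$target_valence == "negative"), ]
  expect_warning(tab3 <- cell_means(list(trials = drop)), "p001")
  expect_equal(tab3$excluded, "p001")
  expect_equal(length(tab3$participants), 77)
})

test_that("null tables give zero effect SS and F", {
  tab <- random_cell_table(6, list(a = c("x", "y"), b = c("u", "v")), seed = 1)
  tab$data$value <- 1.5
  res <- rm_anova(tab)
  expect_true(all(res$ss_effect == 0))
  expect_true(all(res$F == 0))
})

test_that("two-level within factors satisfy F = t^2 exactly", {
  tab <- random_cell_table(15, list(cond = c("a", "b")), seed = 22)
  res <- rm_anova(tab)
  wide <- reshape(tab$data, idvar = "participant_id", timevar = "cond",
                  direction = "wide")
  tt <- t.test(wide$value.a, wide$value.b, paired = TRUE)
  expect_equal(res$F[res$effect == "cond"], unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(res$p[res$effect == "cond"], tt$p.value, tolerance = 1e-9)
})

test_that("the SS decomposition matches aov and conserves total SS", {
  factors <- list(a = c("a1", "a2"), b = c("b1", "b2"), c = c("c1", "c2"))
  for (seed in c(4, 17)) {
    tab <- random_cell_table(20, factors, seed = seed)
    res <- rm_anova(tab)
    d <- tab$data
    d[] <- lapply(d, function(x) if (is.character(x)) factor(x) else x)
    fit <- summary(aov(value ~ a * b * c + Error(participant_id / (a * b * c)), data = d))
    for (i in seq_len(nrow(res))) {
      eff <- res$effect[i]
      stratum <- fit[[sprintf("Error: participant_id:%s", eff)]][[1]]
      expect_equal(res$ss_effect[i], stratum$`Sum Sq`[1], tolerance = 1e-9)
      expect_equal(res$ss_error[i], stratum$`Sum Sq`[2], tolerance = 1e-9)
      expect_equal(res$F[i], stratum$`F value`[1], tolerance = 1e-9)
    }
    # conservation: total SS = subject SS + all effect and error terms
    ss_total <- sum((d$value - mean(d$value))^2)
    expect_equal(sum(res$ss_effect) + sum(res$ss_error) + attr(res, "ss_subject"),
                 ss_total, tolerance = 1e-9 * ss_total)
  }
})

test_that("ANOVA results are invariant to factor-level relabeling", {
  factors <- list(a = c("a1", "a2"), b = c("b1", "b2"))
  tab <- random_cell_table(10, factors, seed = 6)
  res <- rm_anova(tab)
  swapped <- tab
  swapped$data$a <- ifelse(swapped$data$a == "a1", "z2", "z1")
  swapped$factors$a <- c("z1", "z2")
  res2 <- rm_anova(swapped)
  expect_equal(res2$F, res$F, tolerance = 1e-12)
  expect_equal(res2$ss_effect, res$ss_effect, tolerance = 1e-12)
})

test_that("simple effects handle null, degenerate, and standard cases", {
  factors <- list(cond = c("a", "b"))
  tab <- random_cell_table(12, factors, seed = 2)
  # A == B per participant
  same <- tab
  per_sub <- rnorm(12)
  same$data$value <- per_sub[match(same$data$participant_id, same$participants)]
  s0 <- simple_effect(same, c(cond = "a"), c(cond = "b"))
  expect_equal(s0$t, 0)
  expect_equal(s0$dz, 0)
  expect_lt(s0$ci_low, 0 + 1e-12)

  # constant difference, zero variance -> degenerate flag, no crash
  const <- tab
  const$data$value <- ifelse(const$data$cond == "a", 1.05, 1.00)
  sd_ <- simple_effect(const, c(cond = "a"), c(cond = "b"))
  expect_true(sd_$degenerate)
  expect_true(is.infinite(sd_$t))
  expect_equal(sd_$mean_diff, 0.05)

  # standard case: matches t.test directly and CI straddles 0 iff |t| < crit
  s <- simple_effect(tab, c(cond = "a"), c(cond = "b"))
  wide <- reshape(tab$data, idvar = "participant_id", timevar = "cond",
                  direction = "wide")
  tt <- t.test(wide$value.a, wide$value.b, paired = TRUE)
  expect_equal(s$t, unname(tt$statistic))
  expect_equal(c(s$ci_low, s$ci_high), as.numeric(tt$conf.int))
  straddles <- s$ci_low < 0 && s$ci_high > 0
  expect_equal(straddles, abs(s$t) < qt(0.975, s$df))
  expect_error(simple_effect(random_cell_table(2, factors, 1), c(cond = "a"), c(cond = "b")),
               "3 participants")
})

test_that("the stimulus extremity check reproduces a sub-unity F", {
  pos <- c(8.05, 8.21, 8.21, 8.14, 8.05, 7.73)
  neg <- c(1.30, 1.48, 2.24, 2.48, 2.62, 1.79)
  extremity <- abs(c(pos, neg) - 5)
  groups <- rep(c("positive", "negative"), each = 6)
  res <- oneway_anova(extremity, groups)
  expect_lt(res$F, 1)
  # brute-force oracle from the definition of between/within SS
  gm <- mean(extremity)
  mpos <- mean(extremity[1:6]); mneg <- mean(extremity[7:12])
  ss_b <- 6 * (mpos - gm)^2 + 6 * (mneg - gm)^2
  ss_w <- sum((extremity[1:6] - mpos)^2) + sum((extremity[7:12] - mneg)^2)
  expect_equal(res$F, (ss_b / 1) / (ss_w / 10), tolerance = 1e-12)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 10)

  expect_equal(oneway_anova(c(1, 2, 3, 1, 2, 3), rep(c("g1", "g2"), each = 3))$F, 0)
  expect_error(oneway_anova(1:3, c("a", "a", "a")), "2 groups")
})

test_that("the congruity report has the full structure and is deterministic", {
  g <- gen_trials(synth_trial_config("study1", n_participants = 14, seed = 12))
  rep1 <- congruity_report(g$trials)
  expect_equal(nrow(rep1$ms_cell_means), 8)
  expect_equal(nrow(rep1$anova), 7)
  expect_length(rep1$simple_effects, 4)
  expect_length(rep1$simple_interactions, 2)
  rep2 <- congruity_report(g$trials)
  expect_identical(rep1, rep2)

  g2 <- gen_trials(synth_trial_config("study2", n_participants = 10, seed = 12))
  rep3 <- congruity_report(g2$trials)
  expect_equal(nrow(rep3$ms_cell_means), 12)
  expect_equal(nrow(rep3$anova), 7)
  expect_length(rep3$simple_effects, 6)
})
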