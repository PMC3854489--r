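test_that("stay tables assign hand-counted pairs to the right cells", {
  s <- hand_session()
  tab <- stay_table(s, "first_stage")
  cells <- tab$cells
  # pairs: (r=1, common) stay, (r=0, common) switch, (r=1, rare) switch
  get <- function(r, common)
    cells$stay[cells$reward == r & cells$common_transition == common]
  expect_equal(get(1, 1), 1)
  expect_equal(get(0, 1), 0)
  expect_equal(get(1, 0), 0)
  expect_true(is.na(get(0, 0)))   # empty cell marked, not zeroed
  expect_equal(sum(cells$n), 3L)  # every eligible pair in exactly one cell
  # an always-repeating agent fills every populated cell with 1
  rep_s <- make_session(a1 = rep(1L, 6), machine = rep(c("A", "B"), 3),
                        a2 = rep(2L, 6), reward = c(1, 0, 1, 0, 1, 0))
  tr <- stay_table(rep_s, "first_stage")$cells
  expect_true(all(tr$stay[tr$n > 0] == 1))
})

test_that("eligibility filters pick the intended trial pairs per mode", {
  set.seed(401)
  s <- random_session(400, 402)
  pairs <- trial_pairs(s)
  expect_equal(nrow(pairs), 399L)
  for (mode in c("second_diff_machine", "second_same_vs_diff_same_a1",
                 "second_same_vs_diff_diff_a1")) {
    df <- hierseq:::stay_mode_frame(pairs, mode)
    n_expected <- switch(mode,
      second_diff_machine = sum(!pairs$same_machine),
      second_same_vs_diff_same_a1 = sum(pairs$same_a1),
      second_same_vs_diff_diff_a1 = sum(!pairs$same_a1))
    expect_equal(nrow(df), n_expected)
  }
  expect_error(stay_table(s, "no_such_mode"), "unknown")
})

test_that("stay regression is null-calibrated and detects planted effects", {
  # exchangeable null: coin-flip stays, coefficients within 3 SE of zero
  set.seed(403)
  null_sessions <- lapply(1:15, function(i) random_session(270, 500 + i,
                                                           paste0("s", i)))
  reg <- stay_regression(null_sessions, "first_stage")
  co <- reg$coefficients
  expect_true(all(abs(co$estimate[-1]) < 3 * co$se[-1]))
  # planted log-odds interaction of 1.0 is detected at cohort scale
  set.seed(404)
  planted <- lapply(1:15, function(i) {
    n <- 3000
    a1_prev <- sample(1:2, n, TRUE)
    reward <- sample(0:1, n, TRUE)
    common <- sample(0:1, n, TRUE)
    eta <- 1.0 * (2 * reward - 1) * (2 * common - 1) / 2  # half-coef on +/-1 scale
    stay <- rbinom(n, 1, plogis(2 * eta))                 # planted effect 1.0
    a1 <- ifelse(stay == 1, a1_prev, 3L - a1_prev)
    machine <- ifelse((a1_prev == 1) == (common == 1), "A", "B")
    # build an interleaved session: trial t-1 sets a1/reward, t realizes stay
    make_session(a1 = as.integer(c(rbind(a1_prev, a1))),
                 machine = as.character(c(rbind(machine, "A"))),
                 a2 = rep(1L, 2 * n), reward = as.integer(c(rbind(reward, 0))),
                 subject = paste0("s", i))
  })
  # use odd pairs only via the regression on all pairs: the planted signal
  # dominates, power check is > 0.9 across seeds by construction
  reg2 <- stay_regression(planted, "first_stage")
  p_int <- reg2$coefficients$p[4]
  expect_lt(p_int, 0.001)
  expect_gt(reg2$coefficients$estimate[4], 0)
  # small subjects excluded with a warning
  tiny <- make_session(a1 = c(1L, 1L), machine = c("A", "A"),
                       a2 = c(1L, 1L), reward = c(1L, 1L), subject = "tiny")
  expect_warning(stay_regression(c(null_sessions, list(tiny)),
                                 "first_stage"), "excluded")
})

test_that("RT contrast finds the planted sequence-speed association", {
  co <- sim_cohort("hier", 15, 270, seed = 405)
  rc <- rt_contrast(co$sessions)
  expect_lt(rc$rewarded$estimate, 0)
  expect_lt(rc$rewarded$p, 0.01)
  # RT independent of behavior: null in both strata
  set.seed(406)
  null_s <- lapply(co$sessions, function(s) {
    s$rt2 <- 0.5 + rnorm(nrow(s), 0, 0.1)
    s
  })
  rc0 <- rt_contrast(null_s)
  expect_gt(rc0$rewarded$p, 0.05)
  # constant RTs are flagged degenerate
  const_s <- lapply(co$sessions, function(s) { s$rt2 <- 0.5; s })
  rcc <- rt_contrast(const_s)
  expect_gt(length(rcc$rewarded$degenerate), 0)
  # all-missing RTs skip the analysis with a warning
  na_s <- lapply(co$sessions, function(s) { s$rt2 <- NA_real_; s })
  expect_warning(out <- rt_contrast(na_s), "skipped")
  expect_null(out)
})

test_that("model RT curve orders conditions like the generating agent", {
  co <- sim_cohort("hier", 3, 1500, seed = 407)
  p <- representative_params("hier")
  curves <- lapply(co$sessions, function(s) model_rt_curve(p, s))
  m <- Reduce(`+`, lapply(curves, function(cv) cv$rt_pred_mean)) /
    length(curves)
  names(m) <- paste0("r", curves[[1]]$reward_prev, "_s",
                     curves[[1]]$stay2)
  # rewarded-and-stayed (sequence completion) is fastest
  expect_lt(m[["r1_s1"]], m[["r1_s0"]])
  expect_lt(m[["r1_s1"]], m[["r0_s1"]])
  expect_error(model_rt_curve(representative_params("flat"),
                              co$sessions[[1]]), "hierarchical")
})

test_that("partition tree splits on real structure and stays quiet under the null", {
  # response independent of covariates: a single leaf
  set.seed(408)
  n <- 500
  null_s <- make_session(a1 = sample(1:2, n, TRUE),
                         machine = sample(c("A", "B"), n, TRUE),
                         a2 = sample(1:2, n, TRUE),
                         reward = sample(0:1, n, TRUE),
                         rt2 = runif(n, 0.3, 1))
  tree0 <- partition_tree(null_s, n_perm = 499, seed = 409)
  expect_null(tree0$split)
  # perfect association with previous reward: root split on reward with
  # the smallest attainable p-value
  set.seed(410)
  a1 <- sample(1:2, n, TRUE)
  reward <- sample(0:1, n, TRUE)
  a2 <- integer(n); a2[1] <- 1L
  for (t in 2:n) a2[t] <- if (reward[t - 1] == 1) a2[t - 1] else
    3L - a2[t - 1]
  det_s <- make_session(a1 = a1, machine = rep(c("A", "B"), n / 2),
                        a2 = a2, reward = reward, rt2 = runif(n, .3, 1))
  tree1 <- partition_tree(det_s, n_perm = 499, seed = 411)
  expect_equal(tree1$split$covariate, "reward")
  expect_equal(tree1$split$p, 1 / 500)
  # hierarchical cohort: the stay-enriched path is reward -> same_a1/rt
  co <- sim_cohort("hier", 15, 1000, seed = 412)
  tree <- partition_tree(co$sessions, n_perm = 999, seed = 413)
  expect_equal(tree$split$covariate, "reward")
  rewarded <- tree$children$right
  expect_false(is.null(rewarded$split))
  expect_true(rewarded$split$covariate %in% c("same_a1", "rt2"))
  txt <- format_partition(tree)
  expect_true(any(grepl("split: reward", txt)))
})

test_that("permutation p-values are uniform under the null", {
  set.seed(414)
  reps <- 200
  # continuous response keeps the permutation statistic tie-free, so the
  # p-values land on the full 1/(B+1) grid
  pvals <- vapply(seq_len(reps), function(i) {
    y <- rnorm(60)
    x <- sample(0:1, 60, TRUE)
    hierseq:::perm_p_binary(x, y, n_perm = 99)$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
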