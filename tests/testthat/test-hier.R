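test_that("option values combine sequence, single and backup values", {
  st <- hier_init()
  ov <- option_values(st)
  expect_true(all(ov$options == 0.5))
  # a sequence's value is its own reward probability, independent of others
  st$T_seq["12"] <- 0.9
  ov <- option_values(st)
  expect_equal(unname(ov$options["12"]), 0.9)
  expect_equal(unname(ov$options["1"]), 0.5)
  # single-action backup through the fixed transitions
  st2 <- hier_init()
  st2$T_a2["A", "1"] <- 0.8
  st2$T_a2["B", ] <- 0.2
  expect_equal(unname(option_values(st2)$options["1"]),
               0.7 * 0.8 + 0.3 * 0.2)
})

test_that("stage-1 option probabilities respect kappa and perseveration", {
  st <- hier_init()
  p0 <- hier_params(beta1 = 0, kappa = 0, persev = 0)
  expect_equal(unname(hier_choice_probs_stage1(st, p0)), rep(1 / 6, 6))
  # strong single-action preference concentrates mass on the singles
  pk <- hier_params(beta1 = 0, kappa = 30)
  pr <- hier_choice_probs_stage1(st, pk)
  expect_gt(pr[["1"]] + pr[["2"]], 0.999)
  # perseveration of log(2) doubles the odds of options repeating the key
  st$prev_a1 <- 1L
  pp <- hier_params(beta1 = 0, kappa = 0, persev = log(2))
  pr <- hier_choice_probs_stage1(st, pp)
  expect_equal(pr[["1"]] / pr[["2"]], 2)
  expect_equal(pr[["11"]] / pr[["21"]], 2)
  expect_equal(sum(pr), 1)
})

test_that("sequence posterior renormalizes the consistent options", {
  st <- hier_init()
  p0 <- hier_params(beta1 = 0, kappa = 0, persev = 0)
  post <- seq_posterior(hier_choice_probs_stage1(st, p0), 1L)
  expect_equal(unname(post), rep(1 / 3, 3))
  expect_equal(sum(post), 1)
  # direct normalization of a hand-built distribution
  pr <- c(`1` = 0.25, `2` = 0, `11` = 0.25, `12` = 0.5, `21` = 0,
          `22` = 0)
  post <- seq_posterior(pr, 1L)
  expect_equal(unname(post), c(0.25, 0.5, 0.25))
  # kappa -> +inf: the single action explains the observation
  post <- seq_posterior(hier_choice_probs_stage1(
    st, hier_params(beta1 = 0, kappa = 30)), 2L)
  expect_gt(post[["single"]], 0.999)
  expect_error(seq_posterior(pr, 3L), "invalid")
})

test_that("stage-2 mixture reduces to the lesioned softmax when singles dominate", {
  st <- hier_init()
  st$T_a2["A", ] <- c(0.8, 0.3)
  # beta2 = 0 with a uniform posterior: each key gets 1/3 + 1/3 * 1/2
  p0 <- hier_params(beta1 = 0, beta2 = 0, kappa = 0)
  expect_equal(unname(hier_choice_probs_stage2(st, p0, 1L, "A")),
               c(0.5, 0.5))
  # P_single -> 1 limit equals the lesioned model exactly
  pk <- hier_params(beta1 = 2, beta2 = 3, kappa = 40)
  expect_equal(hier_choice_probs_stage2(st, pk, 1L, "A"),
               hier_choice_probs_stage2_lesioned(st, pk, "A"),
               tolerance = 1e-12)
  # two-action softmax closed form in the lesioned model
  st$T_a2["A", ] <- c(1, 0)
  pl <- hier_params(beta2 = 2.5)
  expect_equal(unname(hier_choice_probs_stage2_lesioned(st, pl, "A")[1]),
               plogis(2.5))
  # open-loop execution: a certain sequence dictates the second press
  pr <- c(`1` = 0, `2` = 0, `11` = 1, `12` = 0, `21` = 0, `22` = 0)
  post <- seq_posterior(pr, 1L)
  expect_equal(unname(post["seq_to_1"]), 1)
})

test_that("RT prediction is one minus the sequence posterior and monotone", {
  st <- hier_init()
  p0 <- hier_params(beta1 = 0, kappa = 0, persev = 0)
  expect_equal(rt_prediction(st, p0, 1L, 2L), 2 / 3)
  # raising the containing sequence's value strictly lowers the prediction
  p <- hier_params(beta1 = 3, kappa = 0.3, persev = 0.2)
  vals <- seq(0.05, 0.95, by = 0.1)
  preds <- vapply(vals, function(v) {
    s <- hier_init(); s$T_seq["12"] <- v
    rt_prediction(s, p, 1L, 2L)
  }, numeric(1))
  expect_true(all(diff(preds) < 0))
})

test_that("hierarchical updates are local and use the right rates", {
  st <- hier_init()
  p <- hier_params(alpha_a = 0.3, alpha_s = 0.4)
  st2 <- hier_update(st, p, list(a1 = 1L, machine = "B", a2 = 2L,
                                 reward = 1L))
  expect_equal(unname(st2$T_seq["12"]), 0.5 + 0.4 * 0.5)
  expect_equal(unname(st2$T_a2["B", "2"]), 0.5 + 0.3 * 0.5)
  expect_equal(unname(st2$T_seq[c("11", "21", "22")]), rep(0.5, 3))
  expect_equal(st2$prev_a1, 1L)
  # alpha_a = 0 freezes the single-action model
  p0 <- hier_params(alpha_a = 0, alpha_s = 0.4)
  st3 <- hier_update(st, p0, list(a1 = 1L, machine = "B", a2 = 2L,
                                  reward = 1L))
  expect_equal(st3$T_a2, st$T_a2)
})

test_that("compiled hierarchical likelihood equals the R replay", {
  set.seed(301)
  p <- hier_params(beta1 = 4, beta2 = 2, alpha_a = .4, alpha_s = .5,
                   kappa = .3, persev = .3)
  s <- hier_simulate(p, task_config(n_trials = 150))
  for (les in c(FALSE, TRUE)) {
    a <- hier_loglik(p, s, lesioned = les)
    b <- hier_replay_r(p, s, lesioned = les)
    expect_equal(a$loglik, b$loglik)
    expect_equal(a$p1, b$p1)
    expect_equal(a$p2, b$p2)
  }
  expect_equal(hier_loglik(p, s)$rt_pred, hier_replay_r(p, s)$rt_pred)
  # flat-prior agent: exactly 2 log 2 per trial
  p0 <- hier_params(beta1 = 0, beta2 = 0, kappa = 0, persev = 0)
  expect_equal(hier_loglik(p0, s)$loglik, -nrow(s) * 2 * log(2))
  # stage-2 probabilities normalize trial-by-trial
  ll1 <- hier_loglik(p, s)
  s_flip <- s; s_flip$a2 <- 3L - s$a2
  ll2 <- hier_loglik(p, s_flip)
  # flipping a2 changes the replayed updates, so only the first trial's
  # probabilities are guaranteed complementary
  expect_equal(ll1$p2[1] + ll2$p2[1], 1)
  # a generating agent beats its own label-shuffled data
  set.seed(302)
  s_shuf <- s; s_shuf$a2 <- sample(s$a2)
  expect_gt(hier_loglik(p, s)$loglik, hier_loglik(p, s_shuf)$loglik)
})

test_that("simulated sequences are open-loop and families have 8 members", {
  # all-sequence agent: second press never consults the machine
  set.seed(303)
  s <- hier_simulate(hier_params(beta1 = 0, beta2 = 0, kappa = -30),
                     task_config(n_trials = 400))
  expect_true(all(nchar(s$latent_option) == 2L))
  expect_equal(s$a2, as.integer(substr(s$latent_option, 2, 2)))
  fam <- build_hier_family()
  les <- build_hier_family(lesioned = TRUE)
  expect_length(fam, 8L)
  expect_length(les, 8L)
  expect_true(all(vapply(les, function(sp) sp$lesioned, logical(1))))
  expect_false(any(vapply(fam, function(sp) sp$lesioned, logical(1))))
  n_free <- vapply(fam, function(sp) length(sp$free), integer(1))
  expect_equal(sum(n_free == 6L), 1L)   # the full model
  expect_equal(min(n_free), 3L)         # all toggles off
})

test_that("pure-sequence and pure-single hierarchical agents reproduce the first-stage signatures", {
  cfg <- task_config(n_trials = 4000)
  sim <- function(kappa, seed) {
    set.seed(seed)
    lapply(1:4, function(i)
      hier_simulate(hier_params(beta1 = 5, beta2 = 5, alpha_a = .4,
                                alpha_s = .4, kappa = kappa, persev = 0),
                    cfg, paste0("s", i)))
  }
  seqs <- stay_regression(sim(-8, 304), "first_stage")$coefficients
  expect_gt(seqs$estimate[seqs$term == "reward"], 0.3)
  expect_lt(abs(seqs$estimate[seqs$term == "reward:common_transition"]),
            0.15)
  singles <- stay_regression(sim(8, 305), "first_stage")$coefficients
  expect_gt(singles$estimate[singles$term == "reward:common_transition"],
            0.25)
  expect_lt(abs(singles$estimate[singles$term == "reward"]), 0.15)
})
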