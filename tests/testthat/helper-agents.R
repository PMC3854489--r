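# shared fixtures: small hand-built sessions and simulated cohorts

make_session <- function(a1, machine, a2, reward, subject = "s1",
                         rt2 = NULL) {
  hierseq:::new_session(subject, a1, machine, a2, reward, rt2 = rt2)
}

# four-trial session used in the hand-counted stay-table examples
hand_session <- function() {
  # a1: 1,1,2,1; transitions C,C,R,C; rewards 1,0,1,1
  make_session(a1 = c(1L, 1L, 2L, 1L),
               machine = c("A", "A", "A", "A"),
               a2 = c(1L, 2L, 1L, 1L),
               reward = c(1L, 0L, 1L, 1L))
}

sim_cohort <- function(family, n_subjects, n_trials, seed,
                       params = "fixed") {
  generate_cohort(cohort_spec(family = family, params = params,
                              n_subjects = n_subjects,
                              n_trials = n_trials, seed = seed))
}

random_session <- function(n, seed, subject = "s1") {
  set.seed(seed)
  make_session(a1 = sample(1:2, n, TRUE),
               machine = sample(c("A", "B"), n, TRUE),
               a2 = sample(1:2, n, TRUE),
               reward = sample(0:1, n, TRUE),
               subject = subject)
}
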