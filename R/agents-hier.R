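#' Parameters of the hierarchical sequence-option agent
#'
#' A goal-directed controller chooses at stage 1 among six options: the two
#' single key presses and the four two-press sequences (11, 12, 21, 22).
#' Sequences execute open-loop: their second press ignores which machine
#' appears.
#'
#' @param beta1,beta2 inverse temperatures (>= 0) for stage-1 option choice
#'   and stage-2 goal-directed choice.
#' @param alpha_a learning rate in \[0, 1\] for single-action transition
#'   (reward) models.
#' @param alpha_s learning rate in \[0, 1\] for sequence transition models.
#' @param kappa additive preference for single actions over sequences.
#' @param persev perseveration bonus for options whose first key repeats the
#'   previously observed first-stage key.
#' @return An object of class `hier_params`.
#' @export
hier_params <- function(beta1 = 2, beta2 = 2, alpha_a = 0.5,
                        alpha_s = alpha_a, kappa = 0, persev = 0) {
  p <- list(beta1 = beta1, beta2 = beta2, alpha_a = alpha_a,
            alpha_s = alpha_s, kappa = kappa, persev = persev)
  for (nm in c("alpha_a", "alpha_s"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stopf("%s must be in [0, 1]", nm)
  if (p$beta1 < 0 || p$beta2 < 0) stopf("inverse temperatures must be >= 0")
  structure(p, class = "hier_params")
}

# option labels: singles "1","2"; sequences "11","12","21","22"
hier_options <- c("1", "2", "11", "12", "21", "22")

#' Fresh learning state of the hierarchical agent
#'
#' All learnable reward models start uniform (0.5); the first-stage
#' transition matrix for single actions is fixed at the true contingencies.
#'
#' @param cfg a [task_config()].
#' @return An object of class `hier_state` with `T_seq` (reward probability
#'   per sequence), `T_a2` (per machine and key), `T1`, and `prev_a1`.
#' @export
hier_init <- function(cfg = task_config()) {
  t_seq <- stats::setNames(rep(0.5, 4), c("11", "12", "21", "22"))
  t_a2 <- matrix(0.5, 2, 2, dimnames = list(c("A", "B"), c("1", "2")))
  t1 <- matrix(c(cfg$p_common, 1 - cfg$p_common,
                 1 - cfg$p_common, cfg$p_common),
               2, 2, byrow = TRUE,
               dimnames = list(c("1", "2"), c("A", "B")))
  structure(list(T_seq = t_seq, T_a2 = t_a2, T1 = t1,
                 prev_a1 = NA_integer_),
            class = "hier_state")
}

#' Goal-directed values of all options and second-stage actions
#'
#' Sequence value is its learned reward probability; a second-stage key's
#' value is its learned reward probability at that machine; a single
#' first-stage action's value backs up through the fixed transitions:
#' `Q(a) = sum_m T1(m | a) * max_k T_a2(reward | m, k)`.
#'
#' @param state a [hier_init()] state.
#' @return list with `options` (named length-6 vector over
#'   \{1, 2, 11, 12, 21, 22\}) and `stage2` (2x2 machine-by-key table).
#' @export
option_values <- function(state) {
  best <- apply(state$T_a2, 1, max)
  singles <- as.vector(state$T1 %*% best)
  opts <- c(singles, state$T_seq)
  names(opts) <- hier_options
  list(options = opts, stage2 = state$T_a2)
}

#' Stage-1 option choice probabilities
#'
#' `P(o) propto exp(beta1 * Q(o) + kappa * is_single(o) + persev * rep(o))`
#' where `rep(o)` marks options whose first key equals the previously
#' observed first-stage key.
#'
#' @param state a `hier_state`.
#' @param params a [hier_params()].
#' @return Named probability vector over the six options.
#' @export
hier_choice_probs_stage1 <- function(state, params) {
  q <- option_values(state)$options
  is_single <- c(1, 1, 0, 0, 0, 0)
  first_key <- c(1L, 2L, 1L, 1L, 2L, 2L)
  rep_bonus <- if (is.na(state$prev_a1)) rep(0, 6) else
    as.numeric(first_key == state$prev_a1)
  p <- softmax(params$beta1 * q + params$kappa * is_single +
                 params$persev * rep_bonus)
  names(p) <- hier_options
  p
}

#' Posterior over latent options given the observed first-stage key
#'
#' Three options are consistent with observing key `a1`: the single action
#' `a1` and the two sequences starting with `a1`. Their stage-1
#' probabilities are renormalized.
#'
#' @param stage1_probs output of [hier_choice_probs_stage1()].
#' @param a1 observed first-stage action, 1 or 2.
#' @return Named vector `c(seq_to_1, seq_to_2, single)`: probabilities that
#'   the ongoing option is the sequence whose second press is key 1, key 2,
#'   or the single action.
#' @export
seq_posterior <- function(stage1_probs, a1) {
  if (!a1 %in% c(1L, 2L)) stopf("invalid first-stage action: %s", a1)
  sa <- as.character(a1)
  mass <- c(stage1_probs[[paste0(sa, "1")]],
            stage1_probs[[paste0(sa, "2")]],
            stage1_probs[[sa]])
  tot <- sum(mass)
  if (tot <= 0 || !is.finite(tot))
    stopf("degenerate stage-1 distribution: zero mass on observed action")
  stats::setNames(mass / tot, c("seq_to_1", "seq_to_2", "single"))
}

#' Stage-2 choice probabilities of the hierarchical agent
#'
#' Mixture of open-loop sequence execution and goal-directed choice:
#' `P(x | m, a1) = P_seq(a1 -> x) + P_single * softmax(beta2 * Q(m, .))(x)`.
#'
#' @param state a `hier_state`.
#' @param params a [hier_params()].
#' @param a1 observed first-stage action.
#' @param machine realized machine, `"A"` or `"B"`.
#' @return Named probability vector over keys 1 and 2.
#' @export
hier_choice_probs_stage2 <- function(state, params, a1, machine) {
  post <- seq_posterior(hier_choice_probs_stage1(state, params), a1)
  gd <- softmax(params$beta2 * state$T_a2[machine, ])
  p <- c(post[["seq_to_1"]], post[["seq_to_2"]]) + post[["single"]] * gd
  names(p) <- c("1", "2")
  p
}

#' Stage-2 choice of the lesioned hierarchical agent
#'
#' The sequence contribution is removed: choice is a plain softmax over the
#' machine's learned reward probabilities.
#'
#' @inheritParams hier_choice_probs_stage2
#' @return Named probability vector over keys 1 and 2.
#' @export
hier_choice_probs_stage2_lesioned <- function(state, params, machine) {
  p <- softmax(params$beta2 * state$T_a2[machine, ])
  names(p) <- c("1", "2")
  p
}

#' Model-predicted second-stage reaction time (arbitrary units)
#'
#' One minus the posterior probability that the observed key pair was an
#' ongoing sequence: when the containing sequence was almost certainly
#' selected at stage 1, the second press is pre-programmed and fast.
#'
#' @param state a `hier_state`.
#' @param params a [hier_params()].
#' @param a1,a2 observed first- and second-stage actions.
#' @return A value in \[0, 1\]; smaller is faster.
#' @export
rt_prediction <- function(state, params, a1, a2) {
  post <- seq_posterior(hier_choice_probs_stage1(state, params), a1)
  1 - post[[paste0("seq_to_", a2)]]
}

#' One learning step of the hierarchical agent
#'
#' The executed sequence's reward model moves toward the outcome with rate
#' `alpha_s`; the visited (machine, key) model with rate `alpha_a`; other
#' rows are untouched; the previous first-stage key is stored.
#'
#' @param state a `hier_state`.
#' @param params a [hier_params()].
#' @param trial list or one-row data.frame with `a1`, `machine`, `a2`,
#'   `reward`.
#' @return The updated `hier_state`.
#' @export
hier_update <- function(state, params, trial) {
  sq <- paste0(trial$a1, trial$a2)
  m <- trial$machine; a2 <- as.character(trial$a2); r <- trial$reward
  state$T_seq[sq] <- (1 - params$alpha_s) * state$T_seq[sq] +
    params$alpha_s * r
  state$T_a2[m, a2] <- (1 - params$alpha_a) * state$T_a2[m, a2] +
    params$alpha_a * r
  state$prev_a1 <- as.integer(trial$a1)
  state
}

#' Session log-likelihood under the hierarchical model
#'
#' Per trial, `P(a1)` is the summed stage-1 probability of the three options
#' beginning with the observed key, and `P(a2 | a1, machine)` comes from the
#' sequence/goal-directed mixture (or the lesioned softmax). The inner loop
#' runs in compiled code; [hier_replay_r()] is the plain-R reference.
#'
#' @param params a [hier_params()] (or named list with its fields).
#' @param session a session data.frame.
#' @param lesioned use the lesioned stage-2 likelihood.
#' @param cfg a [task_config()].
#' @return list with `loglik`, per-trial `p1`, `p2`, and `rt_pred` (the
#'   reaction-time predictor of each observed second press).
#' @export
hier_loglik <- function(params, session, lesioned = FALSE,
                        cfg = task_config()) {
  validate_session(session)
  if (nrow(session) == 0L)
    return(list(loglik = 0, p1 = numeric(0), p2 = numeric(0),
                rt_pred = numeric(0)))
  pv <- unlist(params[c("beta1", "beta2", "alpha_a", "alpha_s", "kappa",
                        "persev")])
  res <- hier_loglik_cpp(pv,
                         as.integer(session$a1),
                         as.integer(session$machine == "B"),
                         as.integer(session$a2),
                         as.integer(session$reward),
                         cfg$p_common, as.logical(lesioned))
  list(loglik = res$loglik, p1 = res$p1, p2 = res$p2, rt_pred = res$rt_pred)
}

#' Pure-R replay of the hierarchical likelihood (reference implementation)
#'
#' @inheritParams hier_loglik
#' @return As [hier_loglik()].
#' @export
hier_replay_r <- function(params, session, lesioned = FALSE,
                          cfg = task_config()) {
  state <- hier_init(cfg)
  n <- nrow(session)
  p1 <- numeric(n); p2 <- numeric(n); rtp <- numeric(n)
  for (t in seq_len(n)) {
    tr <- session[t, ]
    s1 <- hier_choice_probs_stage1(state, params)
    sa <- as.character(tr$a1)
    p1[t] <- s1[[sa]] + s1[[paste0(sa, "1")]] + s1[[paste0(sa, "2")]]
    p2[t] <- if (lesioned)
      hier_choice_probs_stage2_lesioned(state, params,
                                        tr$machine)[[as.character(tr$a2)]]
    else
      hier_choice_probs_stage2(state, params, tr$a1,
                               tr$machine)[[as.character(tr$a2)]]
    rtp[t] <- rt_prediction(state, params, tr$a1, tr$a2)
    state <- hier_update(state, params, tr)
  }
  list(loglik = sum(log(p1)) + sum(log(p2)), p1 = p1, p2 = p2,
       rt_pred = rtp)
}

#' Simulate a session from the hierarchical agent
#'
#' A stage-1 option is sampled from [hier_choice_probs_stage1()]. If it is a
#' sequence, both presses are emitted open-loop (the machine is still drawn
#' by the task from the first press); if a single action, the second press
#' is sampled from the goal-directed softmax at the realized machine. The
#' latent option is stored in column `latent_option`.
#'
#' @param params a [hier_params()].
#' @param cfg a [task_config()].
#' @param subject_id identifier for the generated session.
#' @return A session data.frame with `latent_option` and attribute
#'   `provenance`.
#' @export
hier_simulate <- function(params, cfg = task_config(), subject_id = "s1") {
  state <- hier_init(cfg)
  sched <- init_schedule(cfg)
  n <- cfg$n_trials
  a1 <- integer(n); machine <- character(n); a2 <- integer(n)
  reward <- integer(n); reset <- logical(n); latent <- character(n)
  for (t in seq_len(n)) {
    if (t > 1L) {
      st <- step_schedule(sched, cfg)
      sched <- st$schedule; reset[t] <- st$reset
    }
    p_opt <- hier_choice_probs_stage1(state, params)
    opt <- sample(hier_options, 1L, prob = p_opt)
    act1 <- as.integer(substr(opt, 1L, 1L))
    m <- draw_transition(act1, cfg)
    act2 <- if (nchar(opt) == 2L) {
      as.integer(substr(opt, 2L, 2L))          # open-loop second press
    } else {
      sample(1:2, 1L,
             prob = hier_choice_probs_stage2_lesioned(state, params, m))
    }
    r <- rbinom(1L, 1L, sched[paste0(m, act2)])
    a1[t] <- act1; machine[t] <- m; a2[t] <- act2
    reward[t] <- r; latent[t] <- opt
    state <- hier_update(state, params,
                         list(a1 = act1, machine = m, a2 = act2, reward = r))
  }
  out <- new_session(subject_id, a1, machine, a2, reward, reset = reset,
                     latent_option = latent)
  attr(out, "provenance") <- list(family = "hier", params = unclass(params))
  out
}

#' The hierarchical model family and its lesioned counterpart
#'
#' Eight specifications per family: the full model \{beta1, beta2, alpha_a,
#' alpha_s, kappa, persev\} and the 2^3 combinations of the toggles
#' \{kappa fixed to 0, persev fixed to 0, alpha_s tied to alpha_a\}. The
#' lesioned family is identical except that the stage-2 likelihood drops the
#' sequence contribution.
#'
#' @param lesioned build the lesioned counterparts instead.
#' @return List of 8 `model_spec` objects.
#' @export
build_hier_family <- function(lesioned = FALSE) {
  fam <- if (lesioned) "hier_lesioned" else "hier"
  toggles <- expand.grid(kappa = c(TRUE, FALSE), persev = c(TRUE, FALSE),
                         alpha_s = c(TRUE, FALSE))
  specs <- vector("list", nrow(toggles))
  for (i in seq_len(nrow(toggles))) {
    tg <- toggles[i, ]
    free <- c("beta1", "beta2", "alpha_a",
              names(tg)[unlist(tg)])
    fixed_names <- setdiff(c("kappa", "persev"), free)
    # alpha_s absent from both free and fixed means tied to alpha_a
    specs[[i]] <- model_spec(fam, free = free,
                             fixed = stats::setNames(
                               rep(0, length(fixed_names)), fixed_names))
  }
  specs
}
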