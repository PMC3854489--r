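#' Parameters of the flat hybrid model-based/model-free agent
#'
#' @param beta1,beta2 inverse temperatures (>= 0) for first- and second-stage
#'   softmax choice.
#' @param alpha1,alpha2 model-free learning rates in \[0, 1\] for the first
#'   and second stage.
#' @param alpha_T learning rate for the second-stage transition (reward)
#'   model; defaults to `alpha2`, the tie used in the default model family.
#' @param lam eligibility: how strongly the terminal outcome updates the
#'   first-stage model-free value directly.
#' @param w weight of the model-based value in the net value (0 = pure
#'   model-free, 1 = pure model-based).
#' @param persev perseveration bonus added to the logit of repeating the
#'   previous first-stage action.
#' @return An object of class `flat_params` (named list).
#' @export
flat_params <- function(beta1 = 2, beta2 = 2, alpha1 = 0.5, alpha2 = 0.5,
                        alpha_T = alpha2, lam = 0.5, w = 0.5, persev = 0) {
  p <- list(beta1 = beta1, beta2 = beta2, alpha1 = alpha1, alpha2 = alpha2,
            alpha_T = alpha_T, lam = lam, w = w, persev = persev)
  unit <- c("alpha1", "alpha2", "alpha_T", "lam", "w")
  for (nm in unit)
    if (p[[nm]] < 0 || p[[nm]] > 1) stopf("%s must be in [0, 1]", nm)
  if (p$beta1 < 0 || p$beta2 < 0) stopf("inverse temperatures must be >= 0")
  structure(p, class = "flat_params")
}

#' Fresh learning state of the flat agent
#'
#' Model-free Q values start at 0; the second-stage reward model starts
#' uniform (each machine/key pays with believed probability 0.5); the
#' first-stage transition model is fixed at the true 0.7/0.3 contingencies.
#'
#' @param cfg a [task_config()], source of the fixed first-stage transitions.
#' @return An object of class `flat_state`.
#' @export
flat_init <- function(cfg = task_config()) {
  q <- matrix(0, 3, 2, dimnames = list(c("s0", "A", "B"), c("1", "2")))
  t2 <- matrix(0.5, 2, 2, dimnames = list(c("A", "B"), c("1", "2")))
  t1 <- matrix(c(cfg$p_common, 1 - cfg$p_common,
                 1 - cfg$p_common, cfg$p_common),
               2, 2, byrow = TRUE,
               dimnames = list(c("1", "2"), c("A", "B")))
  structure(list(Q_mf = q, T2 = t2, T1 = t1, prev_a1 = NA_integer_),
            class = "flat_state")
}

#' Model-based values of the flat agent
#'
#' Second-stage values are the learned reward probabilities; first-stage
#' values back them up through the fixed transition matrix:
#' `Q_mb(s0, a) = sum_m T1(m | a) * max_a' T2(reward | m, a')`.
#'
#' @param state a [flat_init()] state.
#' @return list with `stage1` (length-2) and `stage2` (2x2 machine-by-action)
#'   value tables.
#' @export
mb_q <- function(state) {
  best <- apply(state$T2, 1, max)
  stage1 <- as.vector(state$T1 %*% best)
  names(stage1) <- c("1", "2")
  list(stage1 = stage1, stage2 = state$T2)
}

#' Choice probabilities of the flat agent
#'
#' Net values mix model-based and model-free components,
#' `Q_net = w * Q_mb + (1 - w) * Q_mf`, at both stages; choice follows a
#' softmax with the stage's inverse temperature. At stage 1 a perseveration
#' bonus `persev` is added to the logit of the previously chosen action.
#'
#' @param state a `flat_state`.
#' @param params a [flat_params()].
#' @param stage 1 or 2.
#' @param machine required for stage 2: `"A"` or `"B"`.
#' @return Named probability vector over actions `1` and `2`.
#' @export
flat_choice_probs <- function(state, params, stage, machine = NULL) {
  mb <- mb_q(state)
  if (stage == 1L) {
    qnet <- params$w * mb$stage1 + (1 - params$w) * state$Q_mf["s0", ]
    rep_bonus <- numeric(2)
    if (!is.na(state$prev_a1)) rep_bonus[state$prev_a1] <- params$persev
    p <- softmax(params$beta1 * qnet + rep_bonus)
  } else {
    if (is.null(machine)) stopf("stage 2 requires a machine")
    qnet <- params$w * mb$stage2[machine, ] +
      (1 - params$w) * state$Q_mf[machine, ]
    p <- softmax(params$beta2 * qnet)
  }
  names(p) <- c("1", "2")
  p
}

#' One learning step of the flat agent
#'
#' In order: (i) the reward model row for the visited (machine, key) moves
#' toward the observed outcome with rate `alpha_T`; (ii) the first-stage
#' model-free value bootstraps from the pre-update second-stage value with
#' rate `alpha1`; (iii) the second-stage value moves toward the reward with
#' rate `alpha2`; (iv) the eligibility term adds `alpha1 * lam * delta2`
#' (with `delta2` from the pre-update value) to the first-stage value;
#' (v) the previous action memory is set.
#'
#' @param state a `flat_state`.
#' @param params a [flat_params()].
#' @param trial list or one-row data.frame with `a1`, `machine`, `a2`,
#'   `reward`.
#' @return The updated `flat_state`.
#' @export
flat_update <- function(state, params, trial) {
  a1 <- as.character(trial$a1); a2 <- as.character(trial$a2)
  m <- trial$machine; r <- trial$reward
  state$T2[m, a2] <- (1 - params$alpha_T) * state$T2[m, a2] +
    params$alpha_T * r
  q2 <- state$Q_mf[m, a2]                       # pre-update stage-2 value
  state$Q_mf["s0", a1] <- state$Q_mf["s0", a1] +
    params$alpha1 * (q2 - state$Q_mf["s0", a1])
  delta2 <- r - q2
  state$Q_mf[m, a2] <- q2 + params$alpha2 * delta2
  state$Q_mf["s0", a1] <- state$Q_mf["s0", a1] +
    params$alpha1 * params$lam * delta2
  state$prev_a1 <- as.integer(trial$a1)
  state
}

#' Session log-likelihood under the flat model
#'
#' Replays the session in order, accumulating the log probabilities of both
#' observed choices per trial and applying the learning update after each
#' trial. The inner loop runs in compiled code; [flat_replay_r()] is the
#' plain-R reference replay.
#'
#' @param params a [flat_params()] (or named list/vector with its fields).
#' @param session a session data.frame.
#' @param cfg a [task_config()] (fixed first-stage transitions).
#' @return list with `loglik`, and per-trial probability vectors `p1`, `p2`.
#' @export
flat_loglik <- function(params, session, cfg = task_config()) {
  validate_session(session)
  if (nrow(session) == 0L)
    return(list(loglik = 0, p1 = numeric(0), p2 = numeric(0)))
  pv <- unlist(params[c("beta1", "beta2", "alpha1", "alpha2", "alpha_T",
                        "lam", "w", "persev")])
  res <- flat_loglik_cpp(pv,
                         as.integer(session$a1),
                         as.integer(session$machine == "B"),
                         as.integer(session$a2),
                         as.integer(session$reward),
                         cfg$p_common)
  list(loglik = res$loglik, p1 = res$p1, p2 = res$p2)
}

#' Pure-R replay of the flat likelihood (reference implementation)
#'
#' Step-by-step replay built from [flat_choice_probs()] and [flat_update()];
#' used as the independent oracle for the compiled likelihood.
#'
#' @inheritParams flat_loglik
#' @return As [flat_loglik()].
#' @export
flat_replay_r <- function(params, session, cfg = task_config()) {
  state <- flat_init(cfg)
  n <- nrow(session)
  p1 <- numeric(n); p2 <- numeric(n)
  for (t in seq_len(n)) {
    tr <- session[t, ]
    p1[t] <- flat_choice_probs(state, params, 1L)[[as.character(tr$a1)]]
    p2[t] <- flat_choice_probs(state, params, 2L,
                               tr$machine)[[as.character(tr$a2)]]
    state <- flat_update(state, params, tr)
  }
  list(loglik = sum(log(p1)) + sum(log(p2)), p1 = p1, p2 = p2)
}

#' Simulate a session from the flat agent
#'
#' @param params a [flat_params()].
#' @param cfg a [task_config()].
#' @param subject_id identifier for the generated session.
#' @return A session data.frame; attribute `provenance` records the
#'   generating family and parameters.
#' @export
flat_simulate <- function(params, cfg = task_config(), subject_id = "s1") {
  state <- flat_init(cfg)
  sched <- init_schedule(cfg)
  n <- cfg$n_trials
  a1 <- integer(n); machine <- character(n); a2 <- integer(n)
  reward <- integer(n); reset <- logical(n)
  for (t in seq_len(n)) {
    if (t > 1L) {
      st <- step_schedule(sched, cfg)
      sched <- st$schedule; reset[t] <- st$reset
    }
    p1 <- flat_choice_probs(state, params, 1L)
    act1 <- sample(1:2, 1L, prob = p1)
    m <- draw_transition(act1, cfg)
    p2 <- flat_choice_probs(state, params, 2L, m)
    act2 <- sample(1:2, 1L, prob = p2)
    r <- rbinom(1L, 1L, sched[paste0(m, act2)])
    a1[t] <- act1; machine[t] <- m; a2[t] <- act2; reward[t] <- r
    state <- flat_update(state, params,
                         list(a1 = act1, machine = m, a2 = act2, reward = r))
  }
  out <- new_session(subject_id, a1, machine, a2, reward, reset = reset)
  attr(out, "provenance") <- list(family = "flat", params = unclass(params))
  out
}

#' The flat model family: the full model and its nested variants
#'
#' Eight specifications: the full model \{beta1, beta2, alpha1, alpha2
#' (= alpha_T), lam, w, persev\} and the 2^3 combinations of fixing `lam`,
#' `w`, and `persev` to 0. With all three fixed, four parameters remain free.
#'
#' @return List of 8 `model_spec` objects.
#' @export
build_flat_family <- function() {
  toggles <- expand.grid(lam = c(TRUE, FALSE), w = c(TRUE, FALSE),
                         persev = c(TRUE, FALSE))
  specs <- vector("list", nrow(toggles))
  for (i in seq_len(nrow(toggles))) {
    tg <- toggles[i, ]
    free <- c("beta1", "beta2", "alpha1", "alpha2",
              names(tg)[unlist(tg)])
    fixed <- setdiff(c("lam", "w", "persev"), free)
    specs[[i]] <- model_spec("flat", free = free,
                             fixed = stats::setNames(rep(0, length(fixed)),
                                                     fixed))
  }
  specs
}

#' Construct a model specification
#'
#' A `model_spec` names a family, which parameters are free, and the values
#' of fixed parameters. Ties (`alpha_T = alpha2` in the flat family,
#' `alpha_s = alpha_a` when the sequence learning rate is not free) are
#' resolved by [spec_params()].
#'
#' @param family `"flat"`, `"hier"`, or `"hier_lesioned"`.
#' @param free character vector of free parameter names.
#' @param fixed named numeric vector of fixed parameter values.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("flat", "hier", "hier_lesioned"),
                       free, fixed = numeric(0)) {
  family <- match.arg(family)
  all_par <- if (family == "flat")
    c("beta1", "beta2", "alpha1", "alpha2", "lam", "w", "persev")
  else
    c("beta1", "beta2", "alpha_a", "alpha_s", "kappa", "persev")
  if (!all(free %in% all_par))
    stopf("unknown free parameters: %s",
          paste(setdiff(free, all_par), collapse = ", "))
  free <- intersect(all_par, free)         # canonical order
  label <- paste0(family, "[", paste(free, collapse = ","), "]")
  structure(list(family = family, free = free, fixed = fixed,
                 lesioned = identical(family, "hier_lesioned"),
                 name = label),
            class = "model_spec")
}

#' Assemble a full parameter object from a spec and free-parameter values
#'
#' @param spec a [model_spec()].
#' @param theta named numeric vector of values for `spec$free`.
#' @return A [flat_params()] or [hier_params()] object.
#' @export
spec_params <- function(spec, theta) {
  vals <- c(as.list(theta[spec$free]), as.list(spec$fixed))
  if (spec$family == "flat") {
    do.call(flat_params, c(vals, list(alpha_T = vals$alpha2)))
  } else {
    if (is.null(vals$alpha_s)) vals$alpha_s <- vals$alpha_a  # tied
    do.call(hier_params, vals)
  }
}
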