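#' Task configuration for the two-stage decision task
#'
#' The task has two first-stage keys, each commonly (probability `p_common`)
#' leading to one of two slot machines; at each machine two keys pay a
#' monetary reward with probability `p_high` or `p_low`. On every trial,
#' with probability `p_reset`, all four reward probabilities are re-drawn
#' independently and uniformly from \{`p_low`, `p_high`\}.
#'
#' @param p_common probability a first-stage key leads to its common machine
#'   (default 0.7).
#' @param p_high,p_low the two possible reward probabilities (0.7, 0.2).
#' @param p_reset per-trial probability that the whole reward schedule is
#'   resampled (default 1/7).
#' @param n_trials number of trials per session (default 270).
#' @param break_after trial count before the mid-session break (metadata
#'   only; the schedule is treated as contiguous across the break).
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(p_common = 0.7, p_high = 0.7, p_low = 0.2,
                        p_reset = 1 / 7, n_trials = 270L,
                        break_after = 120L) {
  probs <- c(p_common = p_common, p_high = p_high, p_low = p_low,
             p_reset = p_reset)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stopf("all task probabilities must lie in [0, 1]")
  if (p_high < p_low) stopf("p_high must be at least p_low")
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 0L) stopf("n_trials must be >= 0")
  structure(list(p_common = p_common, p_high = p_high, p_low = p_low,
                 p_reset = p_reset, n_trials = n_trials,
                 break_after = as.integer(break_after),
                 n_first_actions = 2L, n_machines = 2L),
            class = "task_config")
}

#' Draw the second-stage machine reached by a first-stage action
#'
#' Action 1 commonly leads to machine "A", action 2 to machine "B".
#'
#' @param a1 first-stage action, 1 or 2.
#' @param cfg a [task_config()].
#' @return `"A"` or `"B"`.
#' @export
draw_transition <- function(a1, cfg = task_config()) {
  if (!a1 %in% c(1L, 2L)) stopf("invalid first-stage action: %s", a1)
  common <- c("A", "B")[a1]
  other <- c("B", "A")[a1]
  if (runif(1) < cfg$p_common) common else other
}

#' Create a fresh reward schedule
#'
#' Four entries, one per (machine, second-stage key), each drawn uniformly
#' from \{`p_low`, `p_high`\}.
#'
#' @param cfg a [task_config()].
#' @return Named numeric vector `c(A1, A2, B1, B2)` of reward probabilities.
#' @export
init_schedule <- function(cfg = task_config()) {
  s <- sample(c(cfg$p_low, cfg$p_high), 4L, replace = TRUE)
  names(s) <- c("A1", "A2", "B1", "B2")
  s
}

#' Advance the reward schedule by one trial
#'
#' With probability `p_reset` all four entries are independently resampled
#' from \{`p_low`, `p_high`\}; otherwise the schedule is unchanged.
#'
#' @param sched current schedule (from [init_schedule()]).
#' @param cfg a [task_config()].
#' @return list with `schedule` and logical `reset`.
#' @export
step_schedule <- function(sched, cfg = task_config()) {
  stopifnot(length(sched) == 4L, all(sched %in% c(cfg$p_low, cfg$p_high)))
  reset <- runif(1) < cfg$p_reset
  if (reset) sched[] <- sample(c(cfg$p_low, cfg$p_high), 4L, replace = TRUE)
  list(schedule = sched, reset = reset)
}

#' Probability that the best first-stage action stays best across a reset
#'
#' A first-stage action is "best" when the maximum reward probability among
#' the two keys of its common machine strictly exceeds the maximum on the
#' other machine. After a reset all four entries are re-drawn uniformly from
#' \{`p_low`, `p_high`\}; this enumerates all 2^4 equally likely outcomes and
#' returns the fraction in which a given action is strictly best. Ties count
#' as not-best.
#'
#' @param cfg a [task_config()].
#' @return A probability; 3/16 under the default configuration.
#' @export
prob_remain_best <- function(cfg = task_config()) {
  vals <- c(cfg$p_low, cfg$p_high)
  hits <- 0L
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    own <- max(vals[i], vals[j])
    other <- max(vals[k], vals[l])
    if (own > other) hits <- hits + 1L
  }
  hits / 16
}

#' Expected number of trials a first-stage action remains best
#'
#' Remaining best ends when a reset occurs after which the action is no
#' longer strictly best, an event of per-trial probability
#' `p_reset * (1 - prob_remain_best(cfg))`; the duration is geometric with
#' mean the reciprocal of that rate.
#'
#' @param cfg a [task_config()].
#' @return Expected duration in trials (112/13, about 8.6, under the default
#'   configuration); `Inf` when `p_reset` is 0.
#' @export
expected_best_duration <- function(cfg = task_config()) {
  if (cfg$p_reset == 0) return(Inf)
  rate <- cfg$p_reset * (1 - prob_remain_best(cfg))
  if (rate == 0) return(Inf)
  1 / rate
}

#' Run one session of the task under an arbitrary policy
#'
#' @param policy list of two functions: `choose1()` returning a first-stage
#'   action in \{1, 2\}, and `choose2(a1, machine)` returning a second-stage
#'   action in \{1, 2\}. Optional `observe(trial)` is called with each
#'   completed trial record so the policy can learn.
#' @param cfg a [task_config()].
#' @param subject_id identifier stored on every trial record.
#' @return A `session` data.frame with columns `subject`, `trial`, `a1`,
#'   `machine`, `a2`, `reward`, `rt2`, `transition`, `reset`.
#' @export
run_session <- function(policy, cfg = task_config(), subject_id = "s1") {
  sched <- init_schedule(cfg)
  n <- cfg$n_trials
  a1 <- integer(n); machine <- character(n); a2 <- integer(n)
  reward <- integer(n); reset <- logical(n)
  for (t in seq_len(n)) {
    if (t > 1L) {
      st <- step_schedule(sched, cfg)
      sched <- st$schedule
      reset[t] <- st$reset
    }
    act1 <- policy$choose1()
    if (!isTRUE(act1 %in% c(1L, 2L))) stopf("policy returned invalid a1")
    m <- draw_transition(act1, cfg)
    act2 <- policy$choose2(act1, m)
    if (!isTRUE(act2 %in% c(1L, 2L))) stopf("policy returned invalid a2")
    r <- rbinom(1L, 1L, sched[paste0(m, act2)])
    a1[t] <- act1; machine[t] <- m; a2[t] <- act2; reward[t] <- r
    trial <- list(trial = t - 1L, a1 = act1, machine = m, a2 = act2,
                  reward = r)
    if (!is.null(policy$observe)) policy$observe(trial)
  }
  new_session(subject_id, a1, machine, a2, reward, rt2 = rep(NA_real_, n),
              reset = reset)
}

# construct a session data.frame with derived transition labels
new_session <- function(subject_id, a1, machine, a2, reward,
                        rt2 = NULL, reset = NULL, latent_option = NULL) {
  n <- length(a1)
  transition <- ifelse((a1 == 1L & machine == "A") |
                         (a1 == 2L & machine == "B"), "common", "rare")
  out <- data.frame(subject = rep(as.character(subject_id), n),
                    trial = seq_len(n) - 1L,
                    a1 = as.integer(a1), machine = as.character(machine),
                    a2 = as.integer(a2), reward = as.integer(reward),
                    rt2 = if (is.null(rt2)) rep(NA_real_, n) else rt2,
                    transition = transition,
                    stringsAsFactors = FALSE)
  if (!is.null(reset)) out$reset <- reset
  if (!is.null(latent_option)) out$latent_option <- latent_option
  class(out) <- c("session", "data.frame")
  out
}

# validate the invariant structure of a session data.frame
validate_session <- function(s) {
  need <- c("subject", "trial", "a1", "machine", "a2", "reward")
  miss <- setdiff(need, names(s))
  if (length(miss)) stopf("session lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(s) && !all(diff(s$trial) == 1L))
    stopf("trial index must increase by 1 from 0")
  if (!all(s$a1 %in% c(1L, 2L)) || !all(s$a2 %in% c(1L, 2L)))
    stopf("actions must be 1 or 2")
  if (!all(s$machine %in% c("A", "B"))) stopf("machine must be A or B")
  if (!all(s$reward %in% c(0L, 1L))) stopf("reward must be 0 or 1")
  invisible(s)
}
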