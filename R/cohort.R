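#' Representative agent parameters for cohort simulation
#'
#' Moderate mid-range values typical of human fits on this task: decisive
#' but stochastic choice, intermediate learning rates, a mild single-action
#' preference and perseveration for the hierarchical agent, and an even
#' model-based/model-free mixture for the flat agent.
#'
#' @param family `"flat"` or `"hier"`.
#' @return A [flat_params()] or [hier_params()] object.
#' @export
representative_params <- function(family = c("hier", "flat")) {
  family <- match.arg(family)
  if (family == "hier")
    hier_params(beta1 = 4, beta2 = 2, alpha_a = 0.4, alpha_s = 0.4,
                kappa = 0.3, persev = 0.3)
  else
    flat_params(beta1 = 2.5, beta2 = 2.5, alpha1 = 0.5, alpha2 = 0.5,
                lam = 0.6, w = 0.5, persev = 0.2)
}

#' Specification of a synthetic cohort
#'
#' Defaults emulate the study design this package targets: 15 subjects of
#' 270 trials each, with second-stage RTs built from the hierarchical RT
#' predictor (base 0.5 s, sequence effect 0.3 s, Gaussian noise SD 0.1 s,
#' truncated at 0.05 s).
#'
#' @param family generating family, `"hier"` or `"flat"`.
#' @param params `"fixed"` (every subject uses
#'   [representative_params()]), `"prior"` (per-subject draws from the
#'   fitting priors), or a params object used for all subjects.
#' @param n_subjects,n_trials cohort dimensions.
#' @param rt_base,rt_effect,rt_sd RT model coefficients in seconds.
#' @param seed master seed; per-subject substreams are derived from it.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(family = c("hier", "flat"), params = "fixed",
                        n_subjects = 15L, n_trials = 270L,
                        rt_base = 0.5, rt_effect = 0.3, rt_sd = 0.1,
                        seed = 1L) {
  family <- match.arg(family)
  if (n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (rt_sd <= 0) stopf("rt noise SD must be positive")
  if (rt_base <= 0) stopf("rt_base must be positive")
  structure(list(family = family, params = params,
                 n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials), rt_base = rt_base,
                 rt_effect = rt_effect, rt_sd = rt_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# draw one subject's parameters according to the cohort spec
draw_subject_params <- function(spec) {
  if (is.list(spec$params) && !identical(spec$params, "fixed"))
    return(spec$params)
  if (identical(spec$params, "fixed"))
    return(representative_params(spec$family))
  if (identical(spec$params, "prior")) {
    nms <- if (spec$family == "hier")
      c("beta1", "beta2", "alpha_a", "alpha_s", "kappa", "persev")
    else c("beta1", "beta2", "alpha1", "alpha2", "lam", "w", "persev")
    vals <- lapply(nms, function(nm) param_prior(nm)$sample(1L))
    names(vals) <- nms
    return(if (spec$family == "hier") do.call(hier_params, vals)
           else do.call(flat_params, vals))
  }
  stopf("params must be 'fixed', 'prior', or a parameter object")
}

#' Generate a synthetic cohort with ground truth
#'
#' Per subject: derive a sub-seed from the master seed, draw or copy
#' parameters, simulate a session from the named family, and attach
#' second-stage RTs. Deterministic given the master seed and independent of
#' subject execution order.
#'
#' @param spec a [cohort_spec()].
#' @return list with `sessions` (named list of session data.frames) and
#'   `truth` (per-subject parameters, family, seed; for hierarchical
#'   cohorts the latent options live in the sessions' `latent_option`
#'   column).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  if (!spec$family %in% c("hier", "flat")) stopf("invalid family")
  cfg <- task_config(n_trials = spec$n_trials)
  sessions <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  ids <- sprintf("s%02d", seq_len(spec$n_subjects))
  for (i in seq_len(spec$n_subjects)) {
    sd_i <- sub_seed(spec$seed, i)
    set.seed(sd_i)
    pars <- draw_subject_params(spec)
    s <- if (spec$family == "hier") hier_simulate(pars, cfg, ids[i])
         else flat_simulate(pars, cfg, ids[i])
    s <- attach_rts(s, pars, spec$family, spec$rt_base, spec$rt_effect,
                    spec$rt_sd, cfg)
    sessions[[i]] <- s
    truth[[i]] <- list(subject = ids[i], family = spec$family,
                       params = unclass(pars), seed = sd_i)
  }
  names(sessions) <- names(truth) <- ids
  list(sessions = sessions, truth = truth, spec = spec)
}

#' Attach second-stage reaction times to a session
#'
#' Hierarchical cohorts: `rt2 = base + effect * rt_prediction + noise`,
#' where the predictor is recomputed by replaying the session under the
#' generating parameters, so faster RTs mark likely sequence execution.
#' Flat cohorts: `rt2 = base + noise` (no sequence structure). RTs are
#' truncated below at 0.05 s.
#'
#' @param session a session data.frame.
#' @param params generating parameters.
#' @param family `"hier"` or `"flat"`.
#' @param base,effect,sd RT model coefficients in seconds.
#' @param cfg a [task_config()].
#' @return The session with `rt2` filled in.
#' @export
attach_rts <- function(session, params, family, base = 0.5, effect = 0.3,
                       sd = 0.1, cfg = task_config()) {
  n <- nrow(session)
  noise <- rnorm(n, 0, sd)
  rt <- if (family == "hier") {
    pred <- hier_loglik(params, session, cfg = cfg)$rt_pred
    base + effect * pred + noise
  } else {
    base + noise
  }
  session$rt2 <- pmax(rt, 0.05)
  session
}

session_columns <- c("subject", "trial", "a1", "machine", "a2", "reward",
                     "rt2", "transition")

#' Write sessions to the interchange CSV format
#'
#' Header `subject,trial,a1,machine,a2,reward,rt2,transition`; missing RTs
#' are written as empty fields; UTF-8, comma separator, `.` decimal.
#'
#' @param dataset sessions (data.frame or list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(dataset, path) {
  sessions <- as_dataset(dataset)
  flat <- do.call(rbind, lapply(sessions, function(s)
    as.data.frame(s)[, session_columns]))
  write.csv(flat, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sessions from the interchange CSV format
#'
#' @param path CSV written by [write_sessions()] (or conforming).
#' @return Named list of session data.frames, one per subject.
#' @export
read_sessions <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject = "character"),
                  fileEncoding = "UTF-8")
  miss <- setdiff(setdiff(session_columns, "rt2"), names(raw))
  if (length(miss))
    stopf("malformed session file: missing columns %s",
          paste(miss, collapse = ", "))
  if (nrow(raw) == 0L) return(list())
  bad <- which(!(raw$reward %in% c(0L, 1L)))
  if (length(bad))
    stopf("invalid reward value at line %d", bad[1] + 1L)
  bad <- which(!(raw$a1 %in% c(1L, 2L)) | !(raw$a2 %in% c(1L, 2L)))
  if (length(bad))
    stopf("invalid action value at line %d", bad[1] + 1L)
  if (!"rt2" %in% names(raw)) raw$rt2 <- NA_real_
  raw$rt2 <- as.numeric(raw$rt2)
  sessions <- lapply(split(raw, raw$subject), function(s) {
    s <- s[order(s$trial), ]
    rownames(s) <- NULL
    class(s) <- c("session", "data.frame")
    validate_session(s)
    s
  })
  sessions[unique(raw$subject)]
}
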