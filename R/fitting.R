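#' Prior specification for agent parameters
#'
#' Unit-interval parameters (learning rates, eligibility, model-based
#' weight) receive Beta(1.1, 1.1); inverse temperatures Gamma(shape 1.2,
#' scale 5); real-valued preferences (perseveration, single-action bonus)
#' Normal(0, 1).
#'
#' @param name parameter name.
#' @return list with `type` (`"unit"`, `"pos"`, `"real"`) and the log
#'   density, quantile-free sampler, and support check for that parameter.
#' @export
param_prior <- function(name) {
  type <- param_type(name)
  switch(type,
    unit = list(type = "unit",
                logd = function(x) dbeta(x, 1.1, 1.1, log = TRUE),
                sample = function(n) rbeta(n, 1.1, 1.1),
                in_support = function(x) x > 0 & x < 1),
    pos = list(type = "pos",
               logd = function(x) dgamma(x, shape = 1.2, scale = 5,
                                         log = TRUE),
               sample = function(n) rgamma(n, shape = 1.2, scale = 5),
               in_support = function(x) x > 0),
    real = list(type = "real",
                logd = function(x) dnorm(x, 0, 1, log = TRUE),
                sample = function(n) rnorm(n),
                in_support = function(x) is.finite(x)))
}

param_type <- function(name) {
  if (name %in% c("alpha1", "alpha2", "alpha_T", "alpha_a", "alpha_s",
                  "lam", "w")) return("unit")
  if (name %in% c("beta1", "beta2")) return("pos")
  if (name %in% c("persev", "kappa")) return("real")
  stopf("unknown parameter: %s", name)
}

# native <-> unconstrained transforms per parameter type
to_unconstrained <- function(theta, names) {
  vapply(seq_along(theta), function(i) {
    switch(param_type(names[i]), unit = logit(theta[i]),
           pos = log(theta[i]), real = theta[i])
  }, numeric(1))
}

to_native <- function(eta, names) {
  vapply(seq_along(eta), function(i) {
    switch(param_type(names[i]), unit = plogis(eta[i]),
           pos = exp(eta[i]), real = eta[i])
  }, numeric(1))
}

# log |d theta / d eta| per coordinate
log_jacobian <- function(eta, names) {
  sum(vapply(seq_along(eta), function(i) {
    switch(param_type(names[i]),
           unit = eta[i] - 2 * log1p(exp(eta[i])),  # log sigma'(eta)
           pos = eta[i],
           real = 0)
  }, numeric(1)))
}

# family-dispatched session log-likelihood for a model spec
spec_loglik <- function(spec, params, session, cfg = task_config()) {
  if (spec$family == "flat") flat_loglik(params, session, cfg)$loglik
  else hier_loglik(params, session, lesioned = spec$lesioned,
                   cfg = cfg)$loglik
}

#' Negative log posterior of a model spec on a session
#'
#' Negative log-likelihood minus the sum of log prior densities of the free
#' parameters, in native parameter space. Parameters outside their support
#' yield `+Inf`.
#'
#' @param spec a [model_spec()].
#' @param theta named numeric vector of free-parameter values.
#' @param session a session data.frame.
#' @param cfg a [task_config()].
#' @return Scalar negative log posterior (up to the evidence constant).
#' @export
neg_log_posterior <- function(spec, theta, session, cfg = task_config()) {
  lp <- 0
  for (nm in spec$free) {
    pr <- param_prior(nm)
    if (!pr$in_support(theta[[nm]])) return(Inf)
    lp <- lp + pr$logd(theta[[nm]])
  }
  params <- spec_params(spec, theta)
  ll <- spec_loglik(spec, params, session, cfg)
  if (!is.finite(ll)) return(Inf)
  -ll - lp
}

# objective in the unconstrained space, with the change-of-variables
# Jacobian folded in (the Laplace approximation is taken in this space)
make_objective <- function(spec, session, cfg) {
  nms <- spec$free
  function(eta) {
    theta <- to_native(eta, nms)
    names(theta) <- nms
    v <- neg_log_posterior(spec, theta, session, cfg) -
      log_jacobian(eta, nms)
    if (!is.finite(v)) 1e10 else v
  }
}

#' MAP fit of one model spec to one session
#'
#' Optimizes the negative log posterior in the unconstrained transformed
#' space (log-odds for unit-interval parameters, log for inverse
#' temperatures) with BFGS from `n_restarts` prior-drawn starting points,
#' and keeps the best converged solution. Deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param session a session data.frame.
#' @param n_restarts number of seeded restarts (default 10).
#' @param seed RNG seed for the starting points.
#' @param cfg a [task_config()].
#' @return An object of class `fit_result`: MAP parameters (native space),
#'   `loglik`, `log_prior`, `neg_log_post_trans` (objective value at the
#'   optimum, transformed space), `eta` (transformed MAP), optimizer
#'   diagnostics, and the inputs needed to evaluate evidence.
#' @export
map_fit <- function(spec, session, n_restarts = 10L, seed = 1L,
                    cfg = task_config()) {
  obj <- make_objective(spec, session, cfg)
  nms <- spec$free
  set.seed(seed)
  starts <- lapply(seq_len(n_restarts), function(i) {
    th <- vapply(nms, function(nm) param_prior(nm)$sample(1L), numeric(1))
    to_unconstrained(th, nms)
  })
  best <- NULL; n_ok <- 0L
  for (st in starts) {
    res <- tryCatch(optim(st, obj, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(res))
      res <- tryCatch(optim(st, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000)),
                      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stopf("all %d restarts failed for %s", n_restarts,
                           spec$name)
  theta <- to_native(best$par, nms)
  names(theta) <- nms
  params <- spec_params(spec, theta)
  ll <- spec_loglik(spec, params, session, cfg)
  lp <- sum(vapply(nms, function(nm) param_prior(nm)$logd(theta[[nm]]),
                   numeric(1)))
  structure(list(spec = spec, params = theta, full_params = params,
                 loglik = ll, log_prior = lp,
                 neg_log_post_trans = best$value, eta = best$par,
                 convergence = best$convergence, n_restarts = n_restarts,
                 n_converged = n_ok, seed = seed,
                 n_trials = nrow(session), session = session, cfg = cfg),
            class = "fit_result")
}

# central finite-difference Hessian; step scales with coordinate size
fd_hessian <- function(f, x, rel_step = 1e-4) {
  d <- length(x)
  h <- rel_step * (1 + abs(x))
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(rep(0, d), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < d) for (j in (i + 1):d) {
      ej <- replace(rep(0, d), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
           f(x - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Laplace approximation to the log model evidence
#'
#' `log P(D|M) ~ -nlp(MAP) + (d/2) log(2 pi) - (1/2) log det H`, with `nlp`
#' the negative log posterior (Jacobian-corrected) and `H` its
#' finite-difference Hessian at the MAP, both in the unconstrained space.
#' A non-positive-definite Hessian is repaired by clipping its eigenvalues,
#' with a warning; if the repair leaves the determinant degenerate the
#' result is flagged unreliable.
#'
#' @param fit a [map_fit()] result.
#' @param rel_step relative finite-difference step (default 1e-4).
#' @return The fit with `log_evidence`, `hessian`, `logdet_hessian`, and
#'   `evidence_reliable` added.
#' @export
laplace_evidence <- function(fit, rel_step = 1e-4) {
  obj <- make_objective(fit$spec, fit$session, fit$cfg)
  H <- fd_hessian(obj, fit$eta, rel_step)
  ev <- eigen(H, symmetric = TRUE)
  reliable <- TRUE
  if (any(ev$values <= 0)) {
    warnf("non-positive-definite Hessian for %s; eigenvalues clipped",
          fit$spec$name)
    ev$values <- pmax(ev$values, 1e-8)
    reliable <- all(ev$values > 1e-8)
  }
  logdet <- sum(log(ev$values))
  d <- length(fit$eta)
  fit$hessian <- H
  fit$logdet_hessian <- logdet
  fit$log_evidence <- -fit$neg_log_post_trans + d / 2 * log(2 * pi) -
    logdet / 2
  fit$evidence_reliable <- reliable
  fit
}

#' Pseudo-r-squared of a fit
#'
#' `1 - LL / LL_chance`, where the chance log-likelihood assumes a uniform
#' coin flip for each of the two recorded choices per trial.
#'
#' @param fit a [map_fit()] result (needs `loglik` and `n_trials`).
#' @return Scalar in (-Inf, 1]; 0 is chance, 1 perfect prediction.
#' @export
pseudo_r2 <- function(fit) {
  ll_chance <- 2 * fit$n_trials * log(0.5)
  1 - fit$loglik / ll_chance
}

#' Fit a set of model specs to every subject and collect log evidences
#'
#' @param dataset sessions (data.frame or list).
#' @param specs list of [model_spec()]s.
#' @param n_restarts,seed,cfg passed to [map_fit()].
#' @param verbose print progress.
#' @return list with `evidence` (subjects x models matrix of log
#'   evidences), `fits` (nested list), `pseudo_r2` matrix.
#' @export
fit_dataset <- function(dataset, specs, n_restarts = 10L, seed = 1L,
                        cfg = task_config(), verbose = FALSE) {
  sessions <- as_dataset(dataset)
  model_names <- vapply(specs, function(s) s$name, character(1))
  ev <- matrix(NA_real_, length(sessions), length(specs),
               dimnames = list(names(sessions), model_names))
  pr2 <- ev
  fits <- vector("list", length(sessions))
  names(fits) <- names(sessions)
  for (i in seq_along(sessions)) {
    fits[[i]] <- vector("list", length(specs))
    names(fits[[i]]) <- model_names
    for (k in seq_along(specs)) {
      f <- map_fit(specs[[k]], sessions[[i]], n_restarts = n_restarts,
                   seed = sub_seed(seed, i * 131L + k), cfg = cfg)
      f <- laplace_evidence(f)
      ev[i, k] <- f$log_evidence
      pr2[i, k] <- pseudo_r2(f)
      f$session <- NULL                 # drop data from the stored fit
      fits[[i]][[k]] <- f
      if (verbose)
        message(sprintf("subject %s model %s: logev %.1f",
                        names(sessions)[i], model_names[k], ev[i, k]))
    }
  }
  list(evidence = ev, fits = fits, pseudo_r2 = pr2)
}
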