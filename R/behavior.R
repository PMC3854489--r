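#' Lagged trial-pair table for stay analyses
#'
#' Pairs each trial with its predecessor within a subject (the first trial
#' of a session contributes only as a predecessor). The mid-session break is
#' treated as contiguous.
#'
#' @param dataset a session data.frame or a list of them.
#' @return data.frame with one row per (t-1, t) pair: `subject`,
#'   `reward_prev`, `transition_prev`, `same_a1`, `same_machine`, `stay1`,
#'   `stay2`, `rt2` (current-trial second-stage RT).
#' @export
trial_pairs <- function(dataset) {
  sessions <- as_dataset(dataset)
  out <- lapply(sessions, function(s) {
    n <- nrow(s)
    if (n < 2L) return(NULL)
    idx <- 2:n
    data.frame(subject = s$subject[idx],
               reward_prev = s$reward[idx - 1L],
               transition_prev = s$transition[idx - 1L],
               same_a1 = s$a1[idx] == s$a1[idx - 1L],
               same_machine = s$machine[idx] == s$machine[idx - 1L],
               stay1 = as.integer(s$a1[idx] == s$a1[idx - 1L]),
               stay2 = as.integer(s$a2[idx] == s$a2[idx - 1L]),
               rt2 = s$rt2[idx],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# normalize input to a list of validated sessions
as_dataset <- function(dataset) {
  if (is.data.frame(dataset)) {
    validate_session(dataset)
    split_df <- split(dataset, dataset$subject)
    return(split_df[unique(dataset$subject)])
  }
  lapply(dataset, validate_session)
  dataset
}

# eligible rows and analysis variables for each stay-analysis mode
stay_mode_frame <- function(pairs, mode) {
  switch(mode,
    first_stage = data.frame(
      subject = pairs$subject, y = pairs$stay1,
      x1 = pairs$reward_prev,
      x2 = as.integer(pairs$transition_prev == "common"),
      stringsAsFactors = FALSE),
    second_diff_machine = {
      el <- pairs[!pairs$same_machine, ]
      data.frame(subject = el$subject, y = el$stay2,
                 x1 = el$reward_prev, x2 = as.integer(el$same_a1),
                 stringsAsFactors = FALSE)
    },
    second_same_vs_diff_same_a1 = {
      el <- pairs[pairs$same_a1, ]
      data.frame(subject = el$subject, y = el$stay2,
                 x1 = el$reward_prev, x2 = as.integer(el$same_machine),
                 stringsAsFactors = FALSE)
    },
    second_same_vs_diff_diff_a1 = {
      el <- pairs[!pairs$same_a1, ]
      data.frame(subject = el$subject, y = el$stay2,
                 x1 = el$reward_prev, x2 = as.integer(el$same_machine),
                 stringsAsFactors = FALSE)
    },
    stopf("unknown stay-analysis mode: %s", mode))
}

stay_mode_labels <- function(mode) {
  switch(mode,
    first_stage = c(x1 = "reward", x2 = "common_transition"),
    second_diff_machine = c(x1 = "reward", x2 = "same_a1"),
    second_same_vs_diff_same_a1 = c(x1 = "reward", x2 = "same_machine"),
    second_same_vs_diff_diff_a1 = c(x1 = "reward", x2 = "same_machine"))
}

#' Stay-probability table
#'
#' Cell means of the stay indicator in the 2x2 design of the chosen
#' analysis mode, per subject and pooled (mean and SEM across subjects).
#'
#' @param dataset sessions (data.frame or list).
#' @param mode one of `"first_stage"` (stay on the first-stage key by
#'   previous reward x previous transition), `"second_diff_machine"` (stay
#'   on the second-stage key on different-machine trials, by previous reward
#'   x whether the first-stage key was repeated), and the two
#'   same-vs-different-machine variants restricted to repeated
#'   (`"second_same_vs_diff_same_a1"`) or switched
#'   (`"second_same_vs_diff_diff_a1"`) first-stage keys.
#' @return An object of class `stay_table`: `cells` (pooled means, SEM, n)
#'   and `per_subject` (one row per subject x cell; empty cells are `NA`).
#' @export
stay_table <- function(dataset, mode = "first_stage") {
  df <- stay_mode_frame(trial_pairs(dataset), mode)
  labs <- stay_mode_labels(mode)
  subjects <- unique(df$subject)
  grid <- expand.grid(x1 = c(0L, 1L), x2 = c(0L, 1L))
  per <- do.call(rbind, lapply(subjects, function(sj) {
    d <- df[df$subject == sj, ]
    means <- mapply(function(a, b) {
      sel <- d$y[d$x1 == a & d$x2 == b]
      if (length(sel) == 0L) NA_real_ else mean(sel)
    }, grid$x1, grid$x2)
    ns <- mapply(function(a, b) sum(d$x1 == a & d$x2 == b),
                 grid$x1, grid$x2)
    data.frame(subject = sj, x1 = grid$x1, x2 = grid$x2,
               stay = means, n = ns, stringsAsFactors = FALSE)
  }))
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    v <- per$stay[per$x1 == grid$x1[i] & per$x2 == grid$x2[i]]
    v <- v[!is.na(v)]
    data.frame(x1 = grid$x1[i], x2 = grid$x2[i],
               stay = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = sum(per$n[per$x1 == grid$x1[i] & per$x2 == grid$x2[i]]))
  }))
  names(cells)[1:2] <- labs
  names(per)[2:3] <- labs
  structure(list(mode = mode, cells = cells, per_subject = per),
            class = "stay_table")
}

# ridge-penalized logistic regression by Newton iterations; the penalty
# keeps coefficients finite under complete separation
penalized_logistic <- function(X, y, lambda = 0.05, max_iter = 50L,
                               tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-10)
    grad <- crossprod(X, y - mu) - 2 * lambda * beta
    H <- crossprod(X * wt, X) + diag(2 * lambda, ncol(X))
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.vector(beta)
}

#' Stay regression: per-subject logistic fits with a group-level t-test
#'
#' For each subject, a ridge-penalized logistic regression of the stay
#' indicator on the two +/-1-coded factors of the analysis mode and their
#' interaction (plus intercept); coefficients are then tested against zero
#' across subjects with two-sided one-sample t-tests. This is a
#' summary-statistics approximation to a mixed-effects logistic regression.
#'
#' @inheritParams stay_table
#' @param min_trials subjects with fewer eligible trial pairs are dropped
#'   with a warning (default 10).
#' @return An object of class `stay_regression`: `coefficients` (term,
#'   group mean, SE, t, p, df), `per_subject` coefficient matrix, `mode`,
#'   `n_subjects`.
#' @export
stay_regression <- function(dataset, mode = "first_stage",
                            min_trials = 10L) {
  df <- stay_mode_frame(trial_pairs(dataset), mode)
  labs <- stay_mode_labels(mode)
  terms <- c("intercept", labs[["x1"]], labs[["x2"]],
             paste0(labs[["x1"]], ":", labs[["x2"]]))
  subjects <- unique(df$subject)
  coefs <- matrix(NA_real_, length(subjects), 4L,
                  dimnames = list(subjects, terms))
  for (sj in subjects) {
    d <- df[df$subject == sj, ]
    if (nrow(d) < min_trials) {
      warnf("subject %s excluded: only %d eligible trials", sj, nrow(d))
      next
    }
    s1 <- 2 * d$x1 - 1; s2 <- 2 * d$x2 - 1
    X <- cbind(1, s1, s2, s1 * s2)
    coefs[sj, ] <- penalized_logistic(X, d$y)
  }
  coefs <- coefs[stats::complete.cases(coefs), , drop = FALSE]
  summ <- do.call(rbind, lapply(seq_len(ncol(coefs)), function(j) {
    v <- coefs[, j]
    tt <- t.test(v)
    data.frame(term = terms[j], estimate = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               t = unname(tt$statistic), p = tt$p.value,
               df = unname(tt$parameter), stringsAsFactors = FALSE)
  }))
  structure(list(mode = mode, coefficients = summ, per_subject = coefs,
                 n_subjects = nrow(coefs)),
            class = "stay_regression")
}

#' Reaction-time contrast for second-stage stays
#'
#' On trials whose machine differs from the previous trial and whose
#' first-stage key repeats, regresses the second-stage stay indicator on
#' the (within-subject standardized) second-stage RT, separately within the
#' previously-rewarded and previously-unrewarded strata, with group-level
#' t-tests on the per-subject slopes. A negative rewarded-stratum slope is
#' the sequence-execution signature: fast second presses go with repeating
#' the previous second-stage key.
#'
#' @inheritParams stay_regression
#' @return list of two `stay_regression`-like summaries (`rewarded`,
#'   `unrewarded`), each with per-subject slopes; degenerate subjects
#'   (constant RT) are flagged and excluded.
#' @export
rt_contrast <- function(dataset, min_trials = 10L) {
  pairs <- trial_pairs(dataset)
  el <- pairs[pairs$same_a1 & !pairs$same_machine, ]
  if (all(is.na(el$rt2))) {
    warnf("no second-stage RTs available; RT contrast skipped")
    return(NULL)
  }
  el <- el[!is.na(el$rt2), ]
  fit_stratum <- function(d) {
    subjects <- unique(d$subject)
    slopes <- rep(NA_real_, length(subjects))
    names(slopes) <- subjects
    degenerate <- character(0)
    for (sj in subjects) {
      di <- d[d$subject == sj, ]
      if (nrow(di) < min_trials) next
      if (stats::sd(di$rt2) == 0) { degenerate <- c(degenerate, sj); next }
      z <- (di$rt2 - mean(di$rt2)) / stats::sd(di$rt2)
      cf <- penalized_logistic(cbind(1, z), di$stay2)
      slopes[sj] <- cf[2]
    }
    v <- slopes[!is.na(slopes)]
    if (length(v) < 3L)
      return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                  slopes = slopes, degenerate = degenerate,
                  n_subjects = length(v)))
    tt <- t.test(v)
    list(estimate = mean(v), se = stats::sd(v) / sqrt(length(v)),
         t = unname(tt$statistic), p = tt$p.value, slopes = slopes,
         degenerate = degenerate, n_subjects = length(v))
  }
  structure(list(rewarded = fit_stratum(el[el$reward_prev == 1L, ]),
                 unrewarded = fit_stratum(el[el$reward_prev == 0L, ])),
            class = "rt_contrast")
}

#' Model-predicted reaction-time condition means
#'
#' Replays a session under fitted hierarchical parameters, collects the
#' per-trial RT predictor (one minus the posterior probability of an
#' ongoing sequence), and averages it in the RT-contrast conditions:
#' previous reward x whether the second-stage key was repeated, on
#' different-machine trials with a repeated first-stage key.
#'
#' @param params a [hier_params()] (fitted or true).
#' @param session a session data.frame.
#' @param cfg a [task_config()].
#' @return data.frame with columns `reward_prev`, `stay2`, `rt_pred_mean`,
#'   `n` (arbitrary units).
#' @export
model_rt_curve <- function(params, session, cfg = task_config()) {
  if (!inherits(params, "hier_params") &&
      !all(c("alpha_a", "alpha_s") %in% names(params)))
    stopf("model_rt_curve requires hierarchical parameters")
  rtp <- hier_loglik(params, session, cfg = cfg)$rt_pred
  pairs <- trial_pairs(session)
  rtp <- rtp[-1L]                     # align with pairs (trial t >= 2)
  el <- pairs$same_a1 & !pairs$same_machine
  d <- data.frame(reward_prev = pairs$reward_prev[el],
                  stay2 = pairs$stay2[el], rtp = rtp[el])
  out <- expand.grid(reward_prev = c(1L, 0L), stay2 = c(1L, 0L))
  out$rt_pred_mean <- mapply(function(r, s) {
    v <- d$rtp[d$reward_prev == r & d$stay2 == s]
    if (length(v)) mean(v) else NA_real_
  }, out$reward_prev, out$stay2)
  out$n <- mapply(function(r, s) sum(d$reward_prev == r & d$stay2 == s),
                  out$reward_prev, out$stay2)
  out
}

# permutation p-value for a binary covariate: |difference in stay
# proportions| against the label-permutation null
perm_p_binary <- function(x, y, n_perm) {
  if (length(unique(x)) < 2L) return(list(p = 1, threshold = NA_real_))
  obs <- abs(mean(y[x == 1]) - mean(y[x == 0]))
  n1 <- sum(x == 1); n <- length(y); s <- sum(y)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    s1 <- sum(y[sample.int(n, n1)])
    stat <- abs(s1 / n1 - (s - s1) / (n - n1))
    if (stat >= obs - 1e-12) ge <- ge + 1L
  }
  list(p = (1L + ge) / (n_perm + 1L), threshold = NA_real_)
}

# maximally selected two-sample statistic over candidate RT thresholds
perm_p_continuous <- function(x, y, n_perm, min_side) {
  ord <- order(x)
  ys <- y[ord]; xs <- x[ord]
  n <- length(y)
  ks <- which(diff(xs) > 0)                     # cut after position k
  ks <- ks[ks >= min_side & ks <= n - min_side]
  if (!length(ks)) return(list(p = 1, threshold = NA_real_))
  max_stat <- function(yy) {
    cs <- cumsum(yy)
    stats_k <- abs(cs[ks] / ks - (cs[n] - cs[ks]) / (n - ks))
    max(stats_k)
  }
  obs_all <- {
    cs <- cumsum(ys)
    abs(cs[ks] / ks - (cs[n] - cs[ks]) / (n - ks))
  }
  obs <- max(obs_all)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    if (max_stat(ys[sample.int(n)]) >= obs - 1e-12) ge <- ge + 1L
  }
  kbest <- ks[which.max(obs_all)]
  list(p = (1L + ge) / (n_perm + 1L),
       threshold = (xs[kbest] + xs[kbest + 1L]) / 2)
}

#' Recursive partitioning of second-stage stays
#'
#' Conditional-inference-style tree on different-machine trial pairs:
#' response is the second-stage stay indicator; covariates are the previous
#' trial's reward, whether the first-stage key was repeated, and the
#' second-stage RT. At each node a permutation p-value is computed per
#' covariate (difference in proportions for the binary covariates, a
#' maximally selected two-sample statistic over candidate thresholds for
#' RT), Bonferroni-adjusted across covariates; the node splits on the most
#' significant covariate while the adjusted p-value is below `alpha` and
#' the node is large enough.
#'
#' @param dataset sessions.
#' @param alpha significance level for splitting (default 0.05).
#' @param min_node minimum node size to attempt a split (default 40).
#' @param n_perm permutations per test (default 9999).
#' @param seed RNG seed for the permutation draws.
#' @return Nested `partition_node` structure; print with
#'   [format_partition()].
#' @export
partition_tree <- function(dataset, alpha = 0.05, min_node = 40L,
                           n_perm = 9999L, seed = 1L) {
  pairs <- trial_pairs(dataset)
  el <- pairs[!pairs$same_machine & !is.na(pairs$rt2), ]
  d <- data.frame(y = el$stay2, reward = el$reward_prev,
                  same_a1 = as.integer(el$same_a1), rt2 = el$rt2)
  set.seed(seed)
  grow_node(d, alpha, min_node, n_perm, depth = 0L)
}

grow_node <- function(d, alpha, min_node, n_perm, depth) {
  node <- list(n = nrow(d), stay = sum(d$y), switch = sum(1 - d$y),
               split = NULL, children = NULL, depth = depth)
  class(node) <- "partition_node"
  if (nrow(d) < min_node || length(unique(d$y)) < 2L) return(node)
  min_side <- max(5L, min_node %/% 4L)
  tests <- list(
    reward = perm_p_binary(d$reward, d$y, n_perm),
    same_a1 = perm_p_binary(d$same_a1, d$y, n_perm),
    rt2 = perm_p_continuous(d$rt2, d$y, n_perm, min_side))
  padj <- vapply(tests, function(t) min(1, 3 * t$p), numeric(1))
  if (min(padj) >= alpha) return(node)
  win <- names(which.min(padj))
  thr <- tests[[win]]$threshold
  if (win == "rt2") {
    left <- d[d$rt2 <= thr, ]; right <- d[d$rt2 > thr, ]
  } else {
    left <- d[d[[win]] == 0, ]; right <- d[d[[win]] == 1, ]
  }
  if (nrow(left) == 0L || nrow(right) == 0L) return(node)
  node$split <- list(covariate = win, threshold = thr,
                     p = tests[[win]]$p, p_adjusted = padj[[win]])
  node$children <- list(
    left = grow_node(left, alpha, min_node, n_perm, depth + 1L),
    right = grow_node(right, alpha, min_node, n_perm, depth + 1L))
  node
}

#' Render a partition tree as indented text
#'
#' @param node a `partition_node` from [partition_tree()].
#' @param indent internal.
#' @return Character vector of lines.
#' @export
format_partition <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  head <- sprintf("%sn=%d stay=%d switch=%d", pad, node$n, node$stay,
                  node$switch)
  if (is.null(node$split)) return(head)
  lab <- if (node$split$covariate == "rt2")
    sprintf("rt2 <=/> %.3f", node$split$threshold)
  else sprintf("%s = 0/1", node$split$covariate)
  c(sprintf("%s [split: %s, p_adj=%.4g]", head, lab,
            node$split$p_adjusted),
    format_partition(node$children$left, indent + 1L),
    format_partition(node$children$right, indent + 1L))
}

#' @export
print.partition_node <- function(x, ...) {
  cat(format_partition(x), sep = "\n")
  invisible(x)
}
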