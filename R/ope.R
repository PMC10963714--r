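#' Assemble an off-policy evaluation dataset
#'
#' Combines logged trajectories, a shaped reward version, the estimated
#' physician behaviour policy and a target (evaluation) policy into the
#' per-step quantities the estimators need: behaviour probabilities of the
#' taken actions, target-policy probabilities, rewards, and — when a
#' Q-model is supplied — the model values `qhat(s_t, a_t)` and
#' `vhat(s_t) = sum_a pi_e(a|s_t) qhat(s_t, a)` used as control variates.
#'
#' Deterministic target policies should be passed through [soften()] first;
#' otherwise almost all importance weights collapse to zero.
#'
#' @param trajectories A `trajectory_set`.
#' @param rewards Shaped rewards for one version (tibble with `patient_id`,
#'   `step`, `reward`).
#' @param behaviour_policy The logged-data policy (e.g.
#'   [knn_behaviour_policy()]).
#' @param eval_policy The target `ventrl_policy`.
#' @param model Optional `q_model` for the doubly robust control variates
#'   (`NULL` gives pure importance sampling: `qhat = vhat = 0`).
#' @returns An `ope_dataset`.
#' @export
make_ope_dataset <- function(trajectories, rewards, behaviour_policy,
                             eval_policy, model = NULL) {
  eval_part <- ope_policy_part(trajectories, behaviour_policy, eval_policy,
                               model)
  ope_attach_rewards(eval_part, rewards)
}

# policy/model-dependent part, reusable across reward versions
ope_policy_part <- function(trajectories, behaviour_policy, eval_policy,
                            model = NULL) {
  per <- lapply(trajectories, function(tr) {
    Tn <- tr$T
    pb_mat <- policy_probs_trajectory(behaviour_policy, tr)
    pe_mat <- policy_probs_trajectory(eval_policy, tr)
    taken <- cbind(seq_len(Tn), tr$actions)
    pib <- pb_mat[taken]
    pie <- pe_mat[taken]
    if (!is.null(model)) {
      Q <- q_values(model, tr$states)
      qhat <- Q[taken]
      vhat <- rowSums(pe_mat * Q)
    } else {
      qhat <- numeric(Tn)
      vhat <- numeric(Tn)
    }
    list(patient_id = tr$patient_id, T = Tn, pib = pib, pie = pie,
         qhat = qhat, vhat = vhat)
  })
  structure(list(per = per, n = length(per),
                 H = max(vapply(per, `[[`, 0, "T"))),
            class = "ope_policy_part")
}

ope_attach_rewards <- function(part, rewards) {
  by_pid <- split(rewards, rewards$patient_id)
  per <- lapply(part$per, function(p) {
    r <- by_pid[[as.character(p$patient_id)]]
    r <- r[order(r$step), ]
    abort_if(nrow(r) != p$T, "Reward sequence length mismatch.")
    p$r <- r$reward
    p
  })
  structure(list(per = per, n = part$n, H = part$H), class = "ope_dataset")
}

# padded matrices: rewards/qhat/vhat zero past termination, rho frozen
ope_matrices <- function(dataset) {
  n <- dataset$n
  H <- dataset$H
  R <- Qh <- Vh <- matrix(0, n, H)
  rho <- matrix(1, n, H)
  for (i in seq_len(n)) {
    p <- dataset$per[[i]]
    bad <- which(p$pib <= 0)
    abort_if(length(bad) > 0,
             sprintf("Behaviour probability is zero at step %d of trajectory %s.",
                     bad[1], p$patient_id),
             class = "ventrl_support_error")
    Tn <- p$T
    R[i, seq_len(Tn)] <- p$r
    Qh[i, seq_len(Tn)] <- p$qhat
    Vh[i, seq_len(Tn)] <- p$vhat
    ratios <- p$pie / p$pib
    cr <- cumprod(ratios)
    rho[i, ] <- c(cr, rep(cr[Tn], H - Tn))
  }
  list(R = R, Qh = Qh, Vh = Vh, rho = rho, n = n, H = H)
}

#' Self-normalised per-decision importance weights
#'
#' `rho_t^i = prod_{u<=t} pi_e(a_u|.) / pi_b(a_u|.)`, frozen after a
#' trajectory terminates, normalised across trajectories at each step:
#' `w_t^i = rho_t^i / sum_j rho_t^j`. Columns sum to one.
#'
#' @param dataset An `ope_dataset` (see [make_ope_dataset()]).
#' @returns n x H matrix of weights (one column per step).
#' @export
importance_weights <- function(dataset) {
  m <- ope_matrices(dataset)
  sweep(m$rho, 2, colSums(m$rho), "/")
}

# core estimator: g^(j) for all requested j on (a resample of) the matrices.
# idx: trajectory indices with multiplicity. Returns named numeric vector.
# j = Inf denotes the full-horizon weighted doubly robust estimate.
g_j_values <- function(m, J, gamma, idx = NULL) {
  idx <- idx %||% seq_len(m$n)
  nn <- length(idx)
  rho <- m$rho[idx, , drop = FALSE]
  W <- sweep(rho, 2, colSums(rho), "/")
  Wprev <- cbind(rep(1 / nn, nn), W[, -m$H, drop = FALSE])
  R <- m$R[idx, , drop = FALSE]
  Qh <- m$Qh[idx, , drop = FALSE]
  Vh <- m$Vh[idx, , drop = FALSE]
  disc <- gamma^(seq_len(m$H) - 1)

  # columnwise totals of the three terms (0-based step t = column - 1)
  is_term <- colSums(W * R) * disc                 # importance-sampled reward
  cv_term <- colSums(W * Qh - Wprev * Vh) * disc   # control variate
  vhead <- colSums(Wprev * Vh) * disc              # model head at step j

  cum_is <- c(0, cumsum(is_term))
  cum_cv <- c(0, cumsum(cv_term))
  vapply(J, function(j) {
    if (is.infinite(j)) {
      cum_is[m$H + 1] - cum_cv[m$H + 1]
    } else {
      jj <- min(j, m$H)
      head_val <- if (j >= m$H) 0 else vhead[j + 1]
      cum_is[jj + 1] + head_val - cum_cv[jj + 1]
    }
  }, numeric(1))
}

# per-trajectory contribution matrix (n x |J|); column means equal g^(j)
g_j_contributions <- function(m, J, gamma) {
  W <- sweep(m$rho, 2, colSums(m$rho), "/")
  Wprev <- cbind(rep(1 / m$n, m$n), W[, -m$H, drop = FALSE])
  disc <- matrix(gamma^(seq_len(m$H) - 1), m$n, m$H, byrow = TRUE)
  is_mat <- W * m$R * disc
  cv_mat <- (W * m$Qh - Wprev * m$Vh) * disc
  vhead_mat <- Wprev * m$Vh * disc

  cum_is <- cbind(0, t(apply(is_mat, 1, cumsum)))
  cum_cv <- cbind(0, t(apply(cv_mat, 1, cumsum)))
  out <- vapply(J, function(j) {
    if (is.infinite(j)) {
      cum_is[, m$H + 1] - cum_cv[, m$H + 1]
    } else {
      jj <- min(j, m$H)
      head_val <- if (j >= m$H) numeric(m$n) else vhead_mat[, j + 1]
      cum_is[, jj + 1] + head_val - cum_cv[, jj + 1]
    }
  }, numeric(m$n))
  out * m$n # contributions: column means equal the estimates
}

new_ope_result <- function(estimate, estimator, dataset, gamma,
                           ci = c(NA_real_, NA_real_), ci_level = NA_real_,
                           blend = NULL, contributions = NULL) {
  vb <- behaviour_value(dataset, gamma)
  structure(list(estimate = estimate, estimator = estimator,
                 ci_lower = ci[1], ci_upper = ci[2], ci_level = ci_level,
                 blend_weights = blend, behaviour_value = vb,
                 relative_value = estimate - vb,
                 contributions = contributions, n = dataset$n,
                 discount = gamma),
            class = "ope_result")
}

#' @export
print.ope_result <- function(x, ...) {
  cat(sprintf("<ope_result> %s: %.4f (behaviour %.4f, relative %+.4f)\n",
              x$estimator, x$estimate, x$behaviour_value, x$relative_value))
  if (!is.na(x$ci_lower)) {
    cat(sprintf("  %.0f%% bootstrap CI [%.4f, %.4f]\n", 100 * x$ci_level,
                x$ci_lower, x$ci_upper))
  }
  invisible(x)
}

#' Tidy an OPE result
#'
#' @param x An `ope_result`.
#' @param ... Unused.
#' @returns One-row tibble with the estimate, CI, behaviour value and
#'   relative value.
#' @export
tidy.ope_result <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, estimate = x$estimate,
                 ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 ci_level = x$ci_level, behaviour_value = x$behaviour_value,
                 relative_value = x$relative_value, n = x$n)
}

#' Per-decision weighted importance sampling estimate
#'
#' `sum_t gamma^t sum_i w_t^i r_t^i` with self-normalised weights.
#'
#' @param dataset An `ope_dataset`.
#' @param gamma Discount factor.
#' @returns An `ope_result`.
#' @export
pdwis_estimate <- function(dataset, gamma = 0.99) {
  m <- ope_matrices(dataset)
  W <- sweep(m$rho, 2, colSums(m$rho), "/")
  disc <- gamma^(seq_len(m$H) - 1)
  est <- sum(colSums(W * m$R) * disc)
  contrib <- rowSums(sweep(W * m$R, 2, disc, "*")) * m$n
  new_ope_result(est, "PDWIS", dataset, gamma,
                 contributions = matrix(contrib, ncol = 1))
}

#' Weighted doubly robust estimate
#'
#' The full-horizon member of the partial-horizon family: importance-sampled
#' rewards with model-based control variates. Identical to [pdwis_estimate()]
#' when the model values are identically zero.
#'
#' @inheritParams pdwis_estimate
#' @returns An `ope_result`.
#' @export
wdr_estimate <- function(dataset, gamma = 0.99) {
  m <- ope_matrices(dataset)
  est <- g_j_values(m, Inf, gamma)
  contrib <- g_j_contributions(m, Inf, gamma)
  new_ope_result(est, "WDR", dataset, gamma, contributions = contrib)
}

#' Partial-horizon doubly robust return
#'
#' `g^(j)`: importance sampling for the first `j` steps, the model value
#' thereafter, with per-step control variates. `j = 0` is the pure model
#' estimate (mean `vhat(s_0)`); `j = Inf` is the full weighted doubly
#' robust estimate.
#'
#' @inheritParams pdwis_estimate
#' @param j Non-negative integer or `Inf`.
#' @returns List with `g` (the scalar) and `contributions` (per-trajectory,
#'   mean equals `g`).
#' @export
j_step_return <- function(dataset, gamma = 0.99, j = Inf) {
  m <- ope_matrices(dataset)
  list(g = unname(g_j_values(m, j, gamma)),
       contributions = as.numeric(g_j_contributions(m, j, gamma)))
}

#' Empirical value of the behaviour policy
#'
#' Mean discounted return of the logged trajectories.
#'
#' @inheritParams pdwis_estimate
#' @returns Scalar.
#' @export
behaviour_value <- function(dataset, gamma = 0.99) {
  mean(vapply(dataset$per, function(p) {
    sum(gamma^(seq_len(p$T) - 1) * p$r)
  }, numeric(1)))
}

# exact simplex-constrained QP: minimise x' M x, x >= 0, sum x = 1,
# by enumeration of active sets (optimal support satisfies M_S x = c 1)
simplex_qp <- function(M) {
  J <- nrow(M)
  M <- M + diag(1e-12, J)
  best <- NULL
  best_obj <- Inf
  for (code in seq_len(2^J - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(J) - 1)) > 0)
    xs <- tryCatch(solve(M[S, S, drop = FALSE], rep(1, length(S))),
                   error = function(e) NULL)
    if (is.null(xs) || sum(xs) <= 0) next
    xs <- xs / sum(xs)
    if (any(xs < -1e-12)) next
    xs <- pmax(xs, 0)
    xs <- xs / sum(xs)
    x <- numeric(J)
    x[S] <- xs
    obj <- drop(t(x) %*% M %*% x)
    if (obj < best_obj - 1e-15) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

#' MAGIC off-policy estimate
#'
#' Blends the partial-horizon doubly robust returns `g^(j)`, j in `J`, with
#' simplex weights minimising an estimated mean-squared error: the
#' covariance of the per-trajectory contributions (scaled to the covariance
#' of the means) plus the outer product of a bias proxy — the signed
#' distance of each `g^(j)` to a percentile-bootstrap interval of the
#' full-horizon estimate `g^(Inf)`. The confidence interval reports the
#' percentile bootstrap of the blended estimate with the weights held fixed.
#'
#' When `behaviour_dataset` is supplied (the same trajectories packaged with
#' the behaviour policy as its own evaluation policy, so all weights are
#' exactly 1/n), the relative value is computed *horizon-matched*: the
#' behaviour policy's partial-horizon returns `g_b^(j)` are blended with the
#' target's MSE-optimal weights and subtracted, so the truncation bias the
#' two share cancels in the difference. The plain empirical behaviour value
#' is still reported.
#'
#' @inheritParams pdwis_estimate
#' @param J Set of partial horizons (non-negative integers and/or `Inf`);
#'   at least two.
#' @param n_bootstrap Bootstrap replicates.
#' @param ci_level Confidence level (default 0.9).
#' @param seed Integer seed for the bootstrap.
#' @param behaviour_dataset Optional `ope_dataset` of the behaviour policy
#'   evaluated against itself, for horizon-matched relative values.
#' @returns An `ope_result` with blend weights.
#' @export
magic_estimate <- function(dataset, gamma = 0.99,
                           J = c(0, 1, 2, 5, 10, 25, Inf),
                           n_bootstrap = 200, ci_level = 0.9, seed = 1L,
                           behaviour_dataset = NULL) {
  abort_if(length(J) < 2, "`J` must contain at least two horizons.")
  abort_if(dataset$n < 10,
           "Fewer than 10 trajectories; the bootstrap would be unreliable.")
  m <- ope_matrices(dataset)
  J <- sort(unique(J))
  g <- g_j_values(m, J, gamma)
  C <- g_j_contributions(m, J, gamma)
  omega <- stats::cov(C) / m$n

  set.seed(seed)
  boot <- matrix(0, n_bootstrap, length(J))
  for (b in seq_len(n_bootstrap)) {
    idx <- sample.int(m$n, m$n, replace = TRUE)
    boot[b, ] <- g_j_values(m, J, gamma, idx)
  }
  alpha <- 1 - ci_level
  inf_col <- which(is.infinite(J))
  ref <- if (length(inf_col)) boot[, inf_col] else boot[, length(J)]
  lo <- stats::quantile(ref, alpha / 2, names = FALSE)
  hi <- stats::quantile(ref, 1 - alpha / 2, names = FALSE)
  bias <- pmin(g - lo, 0) + pmax(g - hi, 0)

  x <- simplex_qp(omega + outer(bias, bias))
  est <- sum(x * g)

  blended <- boot %*% x
  ci <- stats::quantile(blended, c(alpha / 2, 1 - alpha / 2), names = FALSE)

  blend <- stats::setNames(x, ifelse(is.infinite(J), "Inf", J))
  out <- new_ope_result(est, "MAGIC", dataset, gamma, ci = ci,
                        ci_level = ci_level, blend = blend,
                        contributions = C)
  if (!is.null(behaviour_dataset)) {
    g_b <- g_j_values(ope_matrices(behaviour_dataset), J, gamma)
    out$behaviour_value_matched <- sum(x * g_b)
    out$relative_value <- est - out$behaviour_value_matched
  }
  out
}

#' Cross off-policy evaluation
#'
#' The two-round selection design: each candidate policy is first evaluated
#' (MAGIC) under the reward version it was trained on and passes round 1 if
#' its relative value is positive; round-1 passers are then evaluated under
#' all remaining reward versions and pass round 2 only if the relative value
#' stays positive under every version. Policies are finally ranked by the
#' minimum relative value across versions (`rank_rule = "min"`, the
#' default) or the mean (`"mean"`).
#'
#' Two evaluation-design rules are applied. First, a candidate's Q-model
#' supplies doubly robust control variates only under the reward version it
#' was trained on; under the other versions it estimates the wrong reward's
#' value, so those evaluations are model-free. Second, the partial horizons
#' blended for model-free cross-version evaluation start at the cohort's
#' median stay length (`J` = median T, twice that, and infinity): shorter
#' truncations are structurally blind to the terminal outcome component the
#' alternative weightings emphasise. All relative values are
#' horizon-matched against the behaviour policy (see [magic_estimate()]).
#'
#' @param candidates List of candidate entries, each a list with `id`,
#'   `policy` (a `ventrl_policy`, typically [soften()]ed), `model` (its
#'   `q_model`, used for control variates under its own version) and
#'   `reward_version` (a name of `versions`).
#' @param trajectories Held-out `trajectory_set` to evaluate on.
#' @param behaviour_policy The estimated physician policy.
#' @param versions Named list of [reward_config()]s (default the six study
#'   weightings).
#' @param gamma Discount factor.
#' @param threshold Round pass threshold on the relative value (default 0).
#' @param rank_rule `"min"` or `"mean"`.
#' @param J Partial horizons for the own-version (model-aided) evaluation.
#' @param J_cross Partial horizons for cross-version evaluation; `NULL`
#'   (default) uses the median stay length, twice it, and `Inf`.
#' @param ... Passed to [magic_estimate()] (`n_bootstrap`, `ci_level`,
#'   `seed`).
#' @returns A `cross_ope_matrix`: tibble with one row per evaluated
#'   (policy, version) cell, with a `summary` attribute tibble carrying the
#'   per-policy pass flags and final ranks.
#' @export
cross_ope <- function(candidates, trajectories, behaviour_policy,
                      versions = reward_version_grid(), gamma = 0.99,
                      threshold = 0, rank_rule = c("min", "mean"),
                      J = c(0, 1, 2, 5, 10, 25, Inf), J_cross = NULL, ...) {
  rank_rule <- match.arg(rank_rule)
  vnames <- names(versions)
  for (cand in candidates) {
    abort_if(!cand$reward_version %in% vnames,
             sprintf("Candidate %s is tagged with unknown reward version %s.",
                     cand$id, cand$reward_version))
  }
  if (is.null(J_cross)) {
    med_T <- stats::median(vapply(trajectories, `[[`, 0L, "T"))
    J_cross <- unique(c(med_T, 2 * med_T, Inf))
  }
  rewards_by_v <- lapply(versions, function(cfg) {
    shape_cohort_rewards(trajectories, versions = list(v = cfg)) |>
      dplyr::select(-dplyr::all_of("version"))
  })
  zero_model <- function(part) {
    part$per <- lapply(part$per, function(p) {
      p$qhat <- 0 * p$qhat
      p$vhat <- 0 * p$vhat
      p
    })
    part
  }
  # behaviour-vs-behaviour part (weights exactly 1/n), model-free
  part_b0 <- ope_policy_part(trajectories, behaviour_policy,
                             behaviour_policy, NULL)

  cells <- list()
  summaries <- list()
  for (cand in candidates) {
    part_m <- ope_policy_part(trajectories, behaviour_policy, cand$policy,
                              cand$model)
    part_0 <- if (is.null(cand$model)) part_m else zero_model(part_m)
    part_bm <- if (is.null(cand$model)) part_b0 else
      ope_policy_part(trajectories, behaviour_policy, behaviour_policy,
                      cand$model)
    eval_version <- function(v, round) {
      own <- v == cand$reward_version
      ds <- ope_attach_rewards(if (own) part_m else part_0,
                               rewards_by_v[[v]])
      ds_b <- ope_attach_rewards(if (own) part_bm else part_b0,
                                 rewards_by_v[[v]])
      res <- magic_estimate(ds, gamma = gamma,
                            J = if (own) J else J_cross,
                            behaviour_dataset = ds_b, ...)
      dplyr::mutate(tidy(res),
                    behaviour_value_matched = res$behaviour_value_matched,
                    policy_id = cand$id,
                    trained_version = cand$reward_version,
                    eval_version = v, round = round)
    }
    own <- eval_version(cand$reward_version, round = 1L)
    round1_pass <- own$relative_value > threshold
    rows <- own
    round2_pass <- NA
    if (round1_pass) {
      others <- lapply(setdiff(vnames, cand$reward_version), eval_version,
                       round = 2L)
      rows <- dplyr::bind_rows(c(list(own), others))
      round2_pass <- all(rows$relative_value > threshold)
    }
    cells[[cand$id]] <- rows
    stat <- if (rank_rule == "min") min(rows$relative_value) else
      mean(rows$relative_value)
    summaries[[cand$id]] <- tibble::tibble(
      policy_id = cand$id, trained_version = cand$reward_version,
      round1_pass = round1_pass, round2_pass = round2_pass,
      rank_stat = stat, n_versions_evaluated = nrow(rows))
  }
  out <- dplyr::bind_rows(cells)
  summ <- dplyr::bind_rows(summaries)
  summ$final_rank <- NA_integer_
  passers <- which(!is.na(summ$round2_pass) & summ$round2_pass)
  summ$final_rank[passers] <- rank(-summ$rank_stat[passers],
                                   ties.method = "first")
  attr(out, "summary") <- summ
  class(out) <- c("cross_ope_matrix", class(out))
  out
}

#' Per-policy summary of a cross-OPE run
#'
#' @param x A `cross_ope_matrix`.
#' @param ... Unused.
#' @returns Tibble with pass flags and final ranks.
#' @export
glance.cross_ope_matrix <- function(x, ...) {
  attr(x, "summary")
}
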