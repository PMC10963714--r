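#' Policies over the ventilator action grid
#'
#' A policy maps `(state, previous_action)` to a probability vector over the
#' actions. Deterministic policies (greedy, king-knight restricted) put all
#' mass on one action; [soften()] spreads an epsilon over the remaining
#' allowed actions so importance ratios in off-policy evaluation stay
#' finite.
#'
#' @name ventrl_policy
NULL

new_policy <- function(fun, kind, n_actions, metadata = list()) {
  structure(list(fun = fun, kind = kind, n_actions = as.integer(n_actions),
                 metadata = metadata),
            class = "ventrl_policy")
}

#' @export
print.ventrl_policy <- function(x, ...) {
  cat(sprintf("<ventrl_policy> kind=%s over %d actions\n", x$kind,
              x$n_actions))
  invisible(x)
}

#' Action probabilities of a policy
#'
#' @param policy A `ventrl_policy`.
#' @param state Normalised state vector.
#' @param prev_action Previous action index, or `NA` at the first step.
#' @returns Probability vector over the policy's actions; its `"allowed"`
#'   attribute carries the action set the policy was allowed to choose from.
#' @export
policy_probs <- function(policy, state, prev_action = NA) {
  p <- policy$fun(state, prev_action)
  stopifnot(length(p) == policy$n_actions)
  p
}

#' Deterministic action of a policy
#'
#' @inheritParams policy_probs
#' @returns The highest-probability action (ties to the lowest index).
#' @export
policy_action <- function(policy, state, prev_action = NA) {
  which.max(policy_probs(policy, state, prev_action))
}

#' Greedy policy of a Q-model
#'
#' Deterministic argmax of Q over all actions, ignoring the previous action;
#' argmax ties break towards the lowest action index.
#'
#' @param model A `q_model`.
#' @returns A `ventrl_policy` of kind `"greedy"`.
#' @export
greedy_policy <- function(model) {
  n_act <- model$spec$n_actions
  new_policy(function(state, prev_action) {
    q <- as.numeric(q_values(model, state))
    p <- numeric(n_act)
    p[which.max(q)] <- 1
    attr(p, "allowed") <- seq_len(n_act)
    p
  }, kind = "greedy", n_actions = n_act,
  metadata = list(reward_version = model$metadata$reward_version))
}

#' King-knight restricted policy of a Q-model
#'
#' Argmax of Q over the king-knight mask of the previous action: one step up
#' or down in PEEP and/or FiO2, cessation of ventilation only from the
#' configured low-support actions, and unrestricted choice when the patient
#' is not ventilated. With no previous action (first step) all actions are
#' allowed.
#'
#' @param model A `q_model` over the full grid's actions.
#' @param cfg A [restriction_config()].
#' @returns A `ventrl_policy` of kind `"king_knight"`.
#' @export
restricted_policy <- function(model, cfg = restriction_config()) {
  n_act <- model$spec$n_actions
  abort_if(n_act != cfg$grid$n_actions,
           "Model action space does not match the restriction's grid.")
  new_policy(function(state, prev_action) {
    allowed <- if (is.na(prev_action)) {
      seq_len(n_act)
    } else {
      king_knight_mask(prev_action, cfg)
    }
    q <- as.numeric(q_values(model, state))
    a <- allowed[which.max(q[allowed])]
    p <- numeric(n_act)
    p[a] <- 1
    attr(p, "allowed") <- allowed
    p
  }, kind = "king_knight", n_actions = n_act,
  metadata = list(reward_version = model$metadata$reward_version,
                  restriction = cfg))
}

#' Epsilon-soften a policy
#'
#' Keeps probability `1 - eps` on the policy's choice and spreads `eps`
#' uniformly over the other *allowed* actions (mask-aware: a restricted
#' policy's softened version never leaves the mask). `eps = 0` is the
#' identity.
#'
#' @param policy A `ventrl_policy`.
#' @param eps Epsilon in `[0, 1)`.
#' @returns A `ventrl_policy`.
#' @export
soften <- function(policy, eps = 0.01) {
  assert_number(eps, "eps", lower = 0, upper = 1, strict_upper = TRUE)
  if (eps == 0) return(policy)
  n_act <- policy$n_actions
  new_policy(function(state, prev_action) {
    p0 <- policy$fun(state, prev_action)
    allowed <- attr(p0, "allowed") %||% seq_len(n_act)
    p <- numeric(n_act)
    if (length(allowed) == 1) {
      p[allowed] <- 1
    } else {
      p[allowed] <- eps / (length(allowed) - 1)
      a <- which.max(p0)
      p[a] <- 1 - eps
    }
    attr(p, "allowed") <- allowed
    p
  }, kind = paste0("soft_", policy$kind), n_actions = n_act,
  metadata = c(policy$metadata, list(eps = eps)))
}

# chunked exact Euclidean k-nearest-neighbour search
knn_indices <- function(train, query, k, chunk = 512L) {
  train_sq <- rowSums(train^2)
  out <- matrix(0L, nrow(query), k)
  for (start in seq(1, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    qs <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(qs^2), train_sq, "+") - 2 * tcrossprod(qs, train)
    for (j in seq_along(idx)) {
      out[idx[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

#' K-nearest-neighbour physician behaviour policy
#'
#' Estimates the physicians' historical action distribution:
#' `pi_b(a | s) = (count of a among the k nearest training states +
#' alpha_s) / (k + n_actions * alpha_s)`, with exact Euclidean neighbour
#' search on the z-scored states. `alpha_s > 0` keeps every action's
#' probability strictly positive, as off-policy evaluation requires.
#'
#' @param states Training state matrix (z-scored).
#' @param actions Integer actions taken at those states.
#' @param k Number of neighbours (default 100).
#' @param alpha_s Additive smoothing (default 0.5).
#' @param n_actions Size of the action space.
#' @returns A `ventrl_policy` of kind `"behaviour"`.
#' @export
knn_behaviour_policy <- function(states, actions, k = 100, alpha_s = 0.5,
                                 n_actions = max(actions)) {
  abort_if(k > nrow(states),
           sprintf("k = %d exceeds the %d training states.", k, nrow(states)))
  abort_if(k < 1, "`k` must be at least 1.")
  states <- as.matrix(states)
  actions <- as.integer(actions)
  pol <- new_policy(function(state, prev_action) {
    nn <- knn_indices(states, matrix(state, 1), k)
    cnt <- tabulate(actions[nn[1, ]], nbins = n_actions)
    p <- (cnt + alpha_s) / (k + n_actions * alpha_s)
    attr(p, "allowed") <- seq_len(n_actions)
    p
  }, kind = "behaviour", n_actions = n_actions,
  metadata = list(k = k, alpha_s = alpha_s, n_train = nrow(states)))
  pol$batch_fun <- function(query) {
    nn <- knn_indices(states, query, k)
    cnt <- t(apply(nn, 1, function(ix) tabulate(actions[ix],
                                                nbins = n_actions)))
    (cnt + alpha_s) / (k + n_actions * alpha_s)
  }
  pol
}

# probability matrix of a policy over the steps of one trajectory,
# with the physician's previous action as context
policy_probs_trajectory <- function(policy, traj) {
  n_act <- policy$n_actions
  if (policy$kind == "behaviour" && !is.null(policy$batch_fun)) {
    return(policy$batch_fun(traj$states))
  }
  prev <- c(NA, traj$actions[-traj$T])
  t(vapply(seq_len(traj$T), function(t) {
    as.numeric(policy_probs(policy, traj$states[t, ], prev[t]))
  }, numeric(n_act)))
}
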