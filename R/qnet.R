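#' Dueling Q-network specification
#'
#' A fully connected dueling architecture: a shared trunk of 3-5 hidden
#' layers (32, 64 or 128 ReLU units each) feeding two heads, a scalar state
#' value V(s) and a per-action advantage A(s, a). The heads are combined as
#' `Q(s, a) = V(s) + A(s, a) - mean(A(s, .))`, which removes the additive
#' unidentifiability between V and A.
#'
#' @param input_dim State vector dimension.
#' @param n_hidden_layers Number of hidden layers (3, 4 or 5).
#' @param width Units per hidden layer (32, 64 or 128).
#' @param n_actions Number of actions (17 for the default PEEP x FiO2 grid).
#' @param prev_action_onehot If `TRUE`, a one-hot of the previous action is
#'   appended to the input (off by default).
#' @returns A `qnetwork_spec`.
#' @export
qnetwork_spec <- function(input_dim, n_hidden_layers = 3, width = 64,
                          n_actions = 17, prev_action_onehot = FALSE) {
  abort_if(!n_hidden_layers %in% 3:5,
           "`n_hidden_layers` must be 3, 4 or 5.")
  abort_if(!width %in% c(32, 64, 128),
           "`width` must be one of 32, 64, 128.")
  assert_number(input_dim, "input_dim", lower = 1)
  assert_number(n_actions, "n_actions", lower = 2)
  structure(list(input_dim = as.integer(input_dim),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 width = as.integer(width),
                 n_actions = as.integer(n_actions),
                 prev_action_onehot = isTRUE(prev_action_onehot)),
            class = "qnetwork_spec")
}

#' Training configuration for the offline Q-agent
#'
#' @param discount Discount factor gamma in (0, 1].
#' @param lr Initial learning rate (Adam).
#' @param lr_schedule `"step"` (decay by `lr_decay` every `lr_step` updates)
#'   or `"plateau"` (decay by `lr_decay` when the smoothed loss has not
#'   improved for `plateau_patience` evaluation intervals).
#' @param lr_decay Multiplicative decay factor in (0, 1].
#' @param lr_step Updates between step decays.
#' @param plateau_patience Evaluation intervals (of 100 updates) without
#'   improvement before a plateau decay.
#' @param batch_size Minibatch size.
#' @param target_sync Updates between target-network synchronisations.
#' @param alpha Priority exponent (0 = uniform replay).
#' @param beta0 Initial importance-sampling exponent, annealed linearly to 1.
#' @param eps_priority Priority floor added to |TD error|.
#' @param grad_clip Global gradient-norm clip.
#' @param weight_decay Decoupled L2 penalty applied at each Adam step;
#'   shrinks the network's extrapolation on state-action pairs the
#'   physicians rarely visited.
#' @param target_clip `"auto"` (default) clips bootstrapped targets to the
#'   empirical discounted-return range of the training data (with a 20%
#'   margin) — a guard against the unbounded value extrapolation offline
#'   Q-learning is prone to on actions the physicians rarely took; a numeric
#'   `c(lo, hi)` sets the bounds directly; `NULL` disables clipping.
#' @param n_updates Number of minibatch updates.
#' @param seed Integer seed (training is deterministic given it).
#' @returns A `train_config`.
#' @export
train_config <- function(discount = 0.99, lr = 1e-3, lr_schedule = "step",
                         lr_decay = 0.5, lr_step = 2000,
                         plateau_patience = 5, batch_size = 64,
                         target_sync = 250, alpha = 0.6, beta0 = 0.4,
                         eps_priority = 1e-3, grad_clip = 5,
                         weight_decay = 1e-4, target_clip = "auto",
                         n_updates = 2000, seed = 1L) {
  assert_number(discount, "discount", lower = 0, upper = 1,
                strict_lower = TRUE)
  abort_if(!lr_schedule %in% c("step", "plateau"),
           "`lr_schedule` must be \"step\" or \"plateau\".")
  assert_number(alpha, "alpha", lower = 0)
  assert_number(beta0, "beta0", lower = 0, upper = 1)
  assert_number(eps_priority, "eps_priority", lower = 0, strict_lower = TRUE)
  structure(list(discount = discount, lr = lr, lr_schedule = lr_schedule,
                 lr_decay = lr_decay, lr_step = lr_step,
                 plateau_patience = plateau_patience,
                 batch_size = as.integer(batch_size),
                 target_sync = as.integer(target_sync), alpha = alpha,
                 beta0 = beta0, eps_priority = eps_priority,
                 grad_clip = grad_clip, weight_decay = weight_decay,
                 target_clip = target_clip,
                 n_updates = as.integer(n_updates),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Combine dueling value and advantage heads
#'
#' `Q(s, a) = V(s) + A(s, a) - mean(A(s, .))`. Invariant to adding a
#' constant to all advantages.
#'
#' @param v State value: scalar or length-n vector.
#' @param a Advantages: vector (one state) or n x n_actions matrix.
#' @returns Q-values with the shape of `a`.
#' @examples
#' dueling_combine(0, c(0, 3)) # c(-1.5, 1.5)
#' @export
dueling_combine <- function(v, a) {
  if (is.matrix(a)) {
    sweep(a - rowMeans(a), 1, -as.numeric(v))
  } else {
    v + a - mean(a)
  }
}

# ---- network internals -----------------------------------------------------

init_params <- function(spec) {
  dims <- c(spec$input_dim + if (spec$prev_action_onehot) spec$n_actions else 0L,
            rep(spec$width, spec$n_hidden_layers))
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  }
  trunk <- lapply(seq_len(spec$n_hidden_layers), function(l) {
    list(W = he(dims[l], dims[l + 1]), b = numeric(dims[l + 1]))
  })
  list(trunk = trunk,
       v = list(W = he(spec$width, 1L), b = numeric(1)),
       a = list(W = he(spec$width, spec$n_actions),
                b = numeric(spec$n_actions)))
}

net_forward <- function(params, X, keep_cache = FALSE) {
  H <- X
  cache <- list(X)
  for (layer in params$trunk) {
    H <- pmax(H %*% layer$W + rep(layer$b, each = nrow(H)), 0)
    if (keep_cache) cache[[length(cache) + 1L]] <- H
  }
  V <- as.numeric(H %*% params$v$W + params$v$b)
  A <- H %*% params$a$W + rep(params$a$b, each = nrow(H))
  Q <- dueling_combine(V, A)
  if (keep_cache) list(Q = Q, V = V, A = A, H = H, cache = cache) else Q
}

# gradient of sum_i w_i (Q[i, a_i] - y_i)^2 / n wrt params
net_backward <- function(params, fwd, actions, targets, weights) {
  n <- length(actions)
  K <- ncol(fwd$A)
  qsa <- fwd$Q[cbind(seq_len(n), actions)]
  td <- qsa - targets
  dQ <- matrix(0, n, K)
  dQ[cbind(seq_len(n), actions)] <- 2 * weights * td / n

  dV <- rowSums(dQ)
  dA <- dQ - rowSums(dQ) / K

  H <- fwd$H
  g_v <- list(W = crossprod(H, dV), b = sum(dV))
  g_a <- list(W = crossprod(H, dA), b = colSums(dA))
  dH <- tcrossprod(dV, as.numeric(params$v$W)) + dA %*% t(params$a$W)

  L <- length(params$trunk)
  gt <- vector("list", L)
  for (l in L:1) {
    Hl <- fwd$cache[[l + 1]]   # post-activation of layer l
    dZ <- dH * (Hl > 0)
    gt[[l]] <- list(W = crossprod(fwd$cache[[l]], dZ), b = colSums(dZ))
    if (l > 1) dH <- dZ %*% t(params$trunk[[l]]$W)
  }
  # field order must match init_params() for the optimiser tree walk
  list(grads = list(trunk = gt, v = g_v, a = g_a), td = td)
}

flatten_grads <- function(g) {
  c(unlist(lapply(g$trunk, function(l) c(l$W, l$b))),
    g$v$W, g$v$b, g$a$W, g$a$b)
}

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0)
}

adam_step <- function(params, grads, state, lr, clip_norm,
                      weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  gn <- sqrt(sum(flatten_grads(grads)^2))
  scale <- if (is.finite(clip_norm) && gn > clip_norm) clip_norm / gn else 1
  state$t <- state$t + 1
  upd <- function(p, g, m, v) {
    g <- g * scale
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    # decoupled weight decay (AdamW)
    list(p = p * (1 - lr * weight_decay) - lr * mh / (sqrt(vh) + eps),
         m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      upd(p, g, m, v)
    }
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v, t = state$t))
}

#' Double-Q learning target
#'
#' `r` for terminal transitions; otherwise
#' `r + gamma * Q_target(s', argmax_a Q_online(s', a))`, with argmax ties
#' broken towards the lowest action index. Selecting with the online network
#' and evaluating with the target network decouples action choice from value
#' estimation, reducing maximisation bias.
#'
#' @param r Reward(s).
#' @param q_online_next,q_target_next Next-state Q-values under the online
#'   and target networks: vectors (single transition) or n x n_actions
#'   matrices.
#' @param terminal Logical flag(s).
#' @param discount Gamma.
#' @returns Numeric target(s).
#' @examples
#' double_q_target(1, c(0.2, 0.5), c(0.7, 0.3), FALSE, 0.9) # 1.27
#' @export
double_q_target <- function(r, q_online_next, q_target_next, terminal,
                            discount) {
  if (!is.matrix(q_online_next)) q_online_next <- matrix(q_online_next, 1)
  if (!is.matrix(q_target_next)) q_target_next <- matrix(q_target_next, 1)
  a_star <- max.col(q_online_next, ties.method = "first")
  boot <- q_target_next[cbind(seq_len(nrow(q_target_next)), a_star)]
  as.numeric(r + ifelse(terminal, 0, discount * boot))
}

#' Prioritised replay sampling
#'
#' Samples transition indices with replacement with probability
#' `P(i) = p_i^alpha / sum_j p_j^alpha` and returns the importance weights
#' `w_i = (N * P(i))^-beta`, normalised by the batch maximum.
#'
#' @param priorities Positive priorities.
#' @param alpha Priority exponent (0 = uniform).
#' @param beta Importance exponent in `[0, 1]` (0 = unit weights).
#' @param batch_size Number of draws.
#' @returns List with `indices`, `weights`, `prob` (the full P vector).
#' @export
per_sample <- function(priorities, alpha, beta, batch_size) {
  abort_if(length(priorities) == 0, "Replay buffer is empty.")
  abort_if(any(priorities <= 0), "Priorities must be positive.")
  prob <- priorities^alpha
  prob <- prob / sum(prob)
  idx <- sample.int(length(prob), batch_size, replace = TRUE, prob = prob)
  w <- (length(prob) * prob[idx])^(-beta)
  list(indices = idx, weights = w / max(w), prob = prob)
}

# transition table from a trajectory set and shaped rewards
build_transitions <- function(trajectories, rewards) {
  by_pid <- split(rewards, rewards$patient_id)
  parts <- lapply(trajectories, function(tr) {
    r <- by_pid[[as.character(tr$patient_id)]]
    r <- r[order(r$step), ]
    abort_if(nrow(r) != tr$T, "Reward sequence length does not match trajectory.")
    Tn <- tr$T
    s_next <- rbind(tr$states[-1, , drop = FALSE],
                    matrix(0, 1, ncol(tr$states)))
    list(s = tr$states, a = tr$actions, r = r$reward, s_next = s_next,
         terminal = seq_len(Tn) == Tn,
         patient_id = rep(tr$patient_id, Tn))
  })
  list(s = do.call(rbind, lapply(parts, `[[`, "s")),
       a = unlist(lapply(parts, `[[`, "a")),
       r = unlist(lapply(parts, `[[`, "r")),
       s_next = do.call(rbind, lapply(parts, `[[`, "s_next")),
       terminal = unlist(lapply(parts, `[[`, "terminal")),
       patient_id = unlist(lapply(parts, `[[`, "patient_id")))
}

#' Train a dueling double-DQN offline
#'
#' Fills a replay buffer with all transitions of the training trajectories
#' (rewards shaped for one reward version), then runs minibatch updates with
#' double-Q targets, prioritised sampling (priorities `|TD error| +
#' eps_priority`), importance-weighted squared TD loss, Adam with gradient
#' clipping and the configured learning-rate schedule, and periodic target
#' network synchronisation.
#'
#' @param trajectories A `trajectory_set` (or a pre-built transition list
#'   with elements `s`, `a`, `r`, `s_next`, `terminal`).
#' @param rewards Shaped rewards for one version, as from
#'   [shape_cohort_rewards()] filtered to a single `version` (ignored if
#'   `trajectories` is already a transition list).
#' @param spec A [qnetwork_spec()]; defaults to 3 x 64 on the data's
#'   dimensions.
#' @param cfg A [train_config()].
#' @param reward_version Label stored in the model metadata.
#' @returns A `q_model` with elements `spec`, `params`, `loss_trace`,
#'   `metadata`.
#' @export
train_q <- function(trajectories, rewards = NULL, spec = NULL,
                    cfg = train_config(), reward_version = NA_character_) {
  from_trajectories <- inherits(trajectories, "trajectory_set")
  trans <- if (from_trajectories) {
    abort_if(is.null(rewards), "`rewards` required when passing trajectories.")
    build_transitions(trajectories, rewards)
  } else {
    trajectories
  }
  n_trans <- nrow(trans$s)
  abort_if(n_trans == 0, "No transitions to train on.")
  spec <- spec %||% qnetwork_spec(input_dim = ncol(trans$s),
                                  n_actions = max(trans$a))
  abort_if(ncol(trans$s) != spec$input_dim,
           "State dimension does not match the network spec.")
  abort_if(max(trans$a) > spec$n_actions,
           "Action index exceeds the network's action space.")

  clip_bounds <- NULL
  if (identical(cfg$target_clip, "auto")) {
    if (from_trajectories) {
      # empirical discounted returns of the logged episodes (each trajectory
      # ends in a terminal transition, so the flags delimit them exactly);
      # targets far outside this support indicate extrapolation
      ends <- which(trans$terminal)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      rets <- mapply(function(s, e) {
        sum(cfg$discount^(seq_len(e - s + 1) - 1) * trans$r[s:e])
      }, starts, ends)
      margin <- 0.2 * max(abs(rets), 1e-8)
      clip_bounds <- c(min(rets) - margin, max(rets) + margin)
    } else {
      # raw transition lists may contain truncated episodes; fall back to
      # the loose geometric bound, which only guards against divergence
      rmax <- max(abs(trans$r), 1e-8)
      bound <- rmax / (1 - min(cfg$discount, 0.999))
      clip_bounds <- c(-bound, bound)
    }
  } else if (is.numeric(cfg$target_clip)) {
    clip_bounds <- range(cfg$target_clip)
  }

  set.seed(cfg$seed)
  params <- init_params(spec)
  target <- params
  opt <- adam_init(params)
  priorities <- rep(1, n_trans)
  lr <- cfg$lr
  loss_trace <- numeric(0)
  smooth <- Inf
  best <- Inf
  stall <- 0L

  for (u in seq_len(cfg$n_updates)) {
    beta <- cfg$beta0 + (1 - cfg$beta0) * (u - 1) / max(cfg$n_updates - 1, 1)
    samp <- per_sample(priorities, cfg$alpha, beta, cfg$batch_size)
    i <- samp$indices

    q_on_next <- net_forward(params, trans$s_next[i, , drop = FALSE])
    q_tg_next <- net_forward(target, trans$s_next[i, , drop = FALSE])
    y <- double_q_target(trans$r[i], q_on_next, q_tg_next,
                         trans$terminal[i], cfg$discount)
    if (!is.null(clip_bounds)) y <- clip(y, clip_bounds[1], clip_bounds[2])

    fwd <- net_forward(params, trans$s[i, , drop = FALSE], keep_cache = TRUE)
    bk <- net_backward(params, fwd, trans$a[i], y, samp$weights)
    loss <- mean(samp$weights * bk$td^2)
    abort_if(!is.finite(loss),
             sprintf("Non-finite loss at update %d; reduce the learning rate.", u),
             class = "ventrl_nan_loss")
    loss_trace[u] <- loss

    st <- adam_step(params, bk$grads, opt, lr, cfg$grad_clip,
                    weight_decay = cfg$weight_decay %||% 0)
    params <- st$params
    opt <- st$state
    priorities[i] <- abs(bk$td) + cfg$eps_priority

    if (u %% cfg$target_sync == 0) target <- params

    if (cfg$lr_schedule == "step") {
      if (u %% cfg$lr_step == 0) lr <- lr * cfg$lr_decay
    } else if (u %% 100 == 0) {
      smooth <- mean(loss_trace[max(1, u - 99):u])
      if (smooth < best - 1e-8) {
        best <- smooth
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$plateau_patience) {
          lr <- lr * cfg$lr_decay
          stall <- 0L
        }
      }
    }
  }

  structure(list(spec = spec, params = params, loss_trace = loss_trace,
                 metadata = list(reward_version = reward_version,
                                 train_config = cfg, n_transitions = n_trans)),
            class = "q_model")
}

#' Evaluate Q-values of a fitted model
#'
#' @param model A `q_model`.
#' @param states Numeric matrix (or single state vector) on the normalised
#'   feature scale.
#' @returns n x n_actions matrix of Q-values.
#' @export
q_values <- function(model, states) {
  stopifnot(inherits(model, "q_model"))
  if (!is.matrix(states)) states <- matrix(states, 1)
  net_forward(model$params, states)
}

#' @export
print.q_model <- function(x, ...) {
  cat(sprintf("<q_model> %d hidden x %d units -> %d actions; %d updates, final loss %.4g\n",
              x$spec$n_hidden_layers, x$spec$width, x$spec$n_actions,
              length(x$loss_trace), utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Tidy the training-loss trace of a fitted Q-model
#'
#' @param x A `q_model`.
#' @param ... Unused.
#' @returns Tibble with `update`, `loss`.
#' @export
tidy.q_model <- function(x, ...) {
  tibble::tibble(update = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' One-row summary of a fitted Q-model
#'
#' @param x A `q_model`.
#' @param ... Unused.
#' @returns Tibble with the architecture, reward version, transition count
#'   and final smoothed loss.
#' @export
glance.q_model <- function(x, ...) {
  k <- min(100, length(x$loss_trace))
  tibble::tibble(
    n_hidden_layers = x$spec$n_hidden_layers,
    width = x$spec$width,
    n_actions = x$spec$n_actions,
    reward_version = x$metadata$reward_version,
    n_transitions = x$metadata$n_transitions,
    n_updates = length(x$loss_trace),
    final_loss = mean(utils::tail(x$loss_trace, k))
  )
}
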