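# Independent oracles: tabular MDPs solved by dynamic programming /
# value iteration, and simulators producing OPE datasets with known truth.
# These never call the estimators they are used to check.

# finite-horizon tabular MDP
# P: S x A x S transition array, R: S x A reward, mu0: initial distribution
random_mdp <- function(n_states, n_actions, horizon, gamma = 0.95,
                       seed = 1) {
  set.seed(seed)
  P <- array(stats::rexp(n_states * n_actions * n_states),
             dim = c(n_states, n_actions, n_states))
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      P[s, a, ] <- P[s, a, ] / sum(P[s, a, ])
    }
  }
  R <- matrix(stats::rnorm(n_states * n_actions), n_states, n_actions)
  mu0 <- stats::rexp(n_states)
  list(P = P, R = R, mu0 = mu0 / sum(mu0), H = horizon, gamma = gamma,
       S = n_states, A = n_actions)
}

# random stochastic policy matrix S x A with full support
random_policy_matrix <- function(mdp, seed, concentration = 1) {
  set.seed(seed)
  pi <- matrix(stats::rexp(mdp$S * mdp$A)^concentration, mdp$S, mdp$A)
  pi / rowSums(pi)
}

# exact policy value and time-indexed Q/V by backward induction
mdp_policy_value <- function(mdp, pi) {
  V <- matrix(0, mdp$H + 1, mdp$S) # V[t+1, ] = value with t steps elapsed
  Qs <- vector("list", mdp$H)
  for (t in mdp$H:1) {
    Q <- mdp$R + mdp$gamma *
      apply(mdp$P, 2, function(Psa) Psa %*% V[t + 1, ])
    Qs[[t]] <- Q
    V[t, ] <- rowSums(pi * Q)
  }
  list(value = sum(mdp$mu0 * V[1, ]), V = V, Q = Qs)
}

# sample trajectories under pib; package them as an ope_dataset for pie.
# qv: optional list of time-indexed S x A "model" Q matrices (e.g. the DP
# truth, possibly perturbed); NULL gives qhat = vhat = 0.
simulate_mdp_dataset <- function(mdp, pib, pie, n, seed, qv = NULL) {
  set.seed(seed)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sample.int(mdp$S, 1, prob = mdp$mu0)
    r <- pb <- pe <- qh <- vh <- numeric(mdp$H)
    for (t in seq_len(mdp$H)) {
      a <- sample.int(mdp$A, 1, prob = pib[s, ])
      r[t] <- mdp$R[s, a]
      pb[t] <- pib[s, a]
      pe[t] <- pie[s, a]
      if (!is.null(qv)) {
        qh[t] <- qv[[t]][s, a]
        vh[t] <- sum(pie[s, ] * qv[[t]][s, ])
      }
      s <- sample.int(mdp$S, 1, prob = mdp$P[s, a, ])
    }
    per[[i]] <- list(patient_id = i, T = mdp$H, pib = pb, pie = pe,
                     qhat = qh, vhat = vh, r = r)
  }
  structure(list(per = per, n = n, H = mdp$H), class = "ope_dataset")
}

# Monte-Carlo value of pie on the MDP (independent of the estimators)
mdp_mc_value <- function(mdp, pie, n, seed) {
  set.seed(seed)
  rets <- vapply(seq_len(n), function(i) {
    s <- sample.int(mdp$S, 1, prob = mdp$mu0)
    tot <- 0
    for (t in seq_len(mdp$H)) {
      a <- sample.int(mdp$A, 1, prob = pie[s, ])
      tot <- tot + mdp$gamma^(t - 1) * mdp$R[s, a]
      s <- sample.int(mdp$S, 1, prob = mdp$P[s, a, ])
    }
    tot
  }, numeric(1))
  c(value = mean(rets), se = stats::sd(rets) / sqrt(n))
}

# deterministic 5-state chain: action 1 ("hold") stays/steps back with a
# small immediate reward, action 2 ("advance") steps right; entering the
# terminal state 5 pays 1. Optimal policy advances everywhere.
chain_mdp <- function(n_states = 5, hold_reward = 0.05, goal_reward = 1,
                      gamma = 0.9) {
  S <- n_states
  P <- array(0, dim = c(S, 2, S))
  R <- matrix(0, S, 2)
  for (s in seq_len(S - 1)) {
    P[s, 1, max(s - 1, 1)] <- 1
    R[s, 1] <- hold_reward
    P[s, 2, s + 1] <- 1
    R[s, 2] <- if (s + 1 == S) goal_reward else 0
  }
  P[S, , S] <- 1 # absorbing terminal
  list(P = P, R = R, S = S, A = 2, gamma = gamma, terminal = S)
}

# infinite-horizon value iteration with absorbing terminal (Q[terminal,]=0)
value_iteration <- function(mdp, tol = 1e-10, max_iter = 10000) {
  Q <- matrix(0, mdp$S, mdp$A)
  for (it in seq_len(max_iter)) {
    Vmax <- apply(Q, 1, max)
    if (!is.null(mdp$terminal)) Vmax[mdp$terminal] <- 0
    Qn <- mdp$R + mdp$gamma *
      apply(mdp$P, 2, function(Psa) Psa %*% Vmax)
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
  Q
}

# offline transition table from episodes under a uniform behaviour policy;
# states one-hot encoded, episodes end at the terminal state or max_len
chain_transitions <- function(mdp, n_episodes, max_len = 12, seed = 1) {
  set.seed(seed)
  s_list <- list(); a_vec <- integer(0); r_vec <- numeric(0)
  sn_list <- list(); term <- logical(0)
  onehot <- diag(mdp$S)
  for (ep in seq_len(n_episodes)) {
    s <- 1L
    for (t in seq_len(max_len)) {
      a <- sample.int(mdp$A, 1)
      s2 <- which(stats::rmultinom(1, 1, mdp$P[s, a, ]) == 1)
      s_list[[length(s_list) + 1L]] <- onehot[s, ]
      a_vec <- c(a_vec, a)
      r_vec <- c(r_vec, mdp$R[s, a])
      sn_list[[length(sn_list) + 1L]] <- onehot[s2, ]
      done <- !is.null(mdp$terminal) && s2 == mdp$terminal
      term <- c(term, done) # truncation is not termination: still bootstrap
      s <- s2
      if (done) break
    }
  }
  list(s = do.call(rbind, s_list), a = a_vec, r = r_vec,
       s_next = do.call(rbind, sn_list), terminal = term)
}

# brute-force interval membership used as the binning oracle
oracle_bin <- function(peep, fio2, edges_p, edges_f) {
  ip <- NA_integer_
  for (i in seq_len(length(edges_p) - 1)) {
    closed_right <- i == length(edges_p) - 1
    if (peep >= edges_p[i] &&
        (peep < edges_p[i + 1] || (closed_right && peep <= edges_p[i + 1]))) {
      ip <- i - 1L
      break
    }
  }
  if_ <- NA_integer_
  for (i in seq_len(length(edges_f) - 1)) {
    closed_right <- i == length(edges_f) - 1
    if (fio2 >= edges_f[i] &&
        (fio2 < edges_f[i + 1] || (closed_right && fio2 <= edges_f[i + 1]))) {
      if_ <- i - 1L
      break
    }
  }
  c(ip, if_)
}

# tiny cohort fixtures for fast tests
small_cohort <- function(n = 30, seed = 5, n_aux = 4, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed,
                             n_aux_features = n_aux, ...))
}

# random-weight Q-model (untrained network) for policy oracle tests
random_q_model <- function(input_dim, n_actions = 17, seed = 1) {
  trans <- list(s = matrix(stats::rnorm(2 * input_dim), 2, input_dim),
                a = c(1L, pmin(2L, n_actions)), r = c(0, 0),
                s_next = matrix(0, 2, input_dim), terminal = c(TRUE, TRUE))
  suppressWarnings(train_q(trans, spec = qnetwork_spec(input_dim, 3, 32,
                                                       n_actions),
                           cfg = train_config(n_updates = 1, batch_size = 2,
                                              seed = seed)))
}
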