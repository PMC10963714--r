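test_that("dueling combination centres advantages and is shift-invariant", {
  expect_equal(dueling_combine(2, rep(1, 17)), rep(2, 17))
  expect_equal(dueling_combine(0, c(0, 3)), c(-1.5, 1.5))
  set.seed(3)
  a <- stats::rnorm(17)
  expect_equal(dueling_combine(1.3, a), dueling_combine(1.3, a + 5))
  # matrix form agrees with the vector form row by row
  A <- matrix(stats::rnorm(3 * 17), 3)
  V <- stats::rnorm(3)
  QM <- dueling_combine(V, A)
  for (i in 1:3) expect_equal(QM[i, ], dueling_combine(V[i], A[i, ]))
})

test_that("double-Q targets decouple selection from evaluation", {
  expect_equal(double_q_target(1, c(5, 9), c(3, 2), TRUE, 0.9), 1)
  # online argmax is action 2, evaluated on the target net: 1 + 0.9 * 0.3
  expect_equal(double_q_target(1, c(0.2, 0.5), c(0.7, 0.3), FALSE, 0.9), 1.27)
  # identical networks reduce to the standard max target
  q <- c(0.4, 0.9, 0.1)
  expect_equal(double_q_target(0.5, q, q, FALSE, 0.8), 0.5 + 0.8 * max(q))
  # ties break to the lowest action index
  expect_equal(double_q_target(0, c(1, 1), c(7, -7), FALSE, 1), 7)
})

test_that("prioritised sampling matches its probability law", {
  expect_error(per_sample(numeric(0), 0.6, 0.4, 8))

  set.seed(8)
  # alpha = 0: uniform probabilities; beta = 0: unit weights
  u <- per_sample(c(10, 1, 0.1), alpha = 0, beta = 0, batch_size = 50)
  expect_equal(u$prob, rep(1 / 3, 3))
  expect_equal(u$weights, rep(1, 50))

  s <- per_sample(c(1, 3), alpha = 1, beta = 0.5, batch_size = 10)
  expect_equal(s$prob, c(0.25, 0.75))

  # sampling frequencies pass a chi-square GoF test at 1e5 draws
  p <- c(0.5, 1, 2, 4)
  alpha <- 0.7
  draws <- per_sample(p, alpha = alpha, beta = 0.4, batch_size = 1e5)
  expected_p <- p^alpha / sum(p^alpha)
  gof <- stats::chisq.test(tabulate(draws$indices, 4), p = expected_p)
  expect_gt(gof$p.value, 0.01)

  # importance weights follow (N P)^-beta, normalised by the batch max
  w_raw <- (4 * expected_p[draws$indices])^(-0.4)
  expect_equal(draws$weights, w_raw / max(w_raw))
})

test_that("myopic training on one transition converges to its reward", {
  trans <- list(s = matrix(c(1, 0), 1), a = 1L, r = 0.7,
                s_next = matrix(0, 1, 2), terminal = TRUE)
  mod <- train_q(trans, spec = qnetwork_spec(2, 3, 32, 2),
                 cfg = train_config(discount = 1e-9, n_updates = 800,
                                    batch_size = 8, lr = 5e-3, seed = 4))
  expect_equal(q_values(mod, c(1, 0))[1, 1], 0.7, tolerance = 0.01)
})

test_that("training is bit-reproducible under a fixed seed", {
  mdp <- chain_mdp()
  trans <- chain_transitions(mdp, 30, seed = 2)
  cfg <- train_config(n_updates = 150, seed = 11)
  m1 <- train_q(trans, spec = qnetwork_spec(5, 3, 32, 2), cfg = cfg)
  m2 <- train_q(trans, spec = qnetwork_spec(5, 3, 32, 2), cfg = cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
})

test_that("the trained agent recovers the value-iteration optimum on a chain", {
  mdp <- chain_mdp()
  q_star <- value_iteration(mdp)
  pi_star <- max.col(q_star, ties.method = "first")

  trans <- chain_transitions(mdp, 400, seed = 7)
  mod <- train_q(trans, spec = qnetwork_spec(5, 3, 32, 2),
                 cfg = train_config(discount = mdp$gamma, n_updates = 4000,
                                    lr = 5e-3, lr_step = 1500,
                                    target_sync = 50, weight_decay = 0,
                                    seed = 21))
  Q_hat <- q_values(mod, diag(5))
  # greedy policy matches at every non-terminal state
  expect_equal(max.col(Q_hat, ties.method = "first")[1:4], pi_star[1:4])
  # Q-values close to the dynamic-programming truth on covered states
  expect_lt(max(abs(Q_hat[1:4, ] - q_star[1:4, ])), 0.05)
})

test_that("tidy and glance expose the training trace and architecture", {
  mdp <- chain_mdp()
  trans <- chain_transitions(mdp, 20, seed = 3)
  mod <- train_q(trans, spec = qnetwork_spec(5, 3, 32, 2),
                 cfg = train_config(n_updates = 50, seed = 1),
                 reward_version = "v2")
  td <- tidy(mod)
  expect_equal(nrow(td), 50)
  expect_true(all(is.finite(td$loss)))
  gl <- glance(mod)
  expect_equal(gl$width, 32L)
  expect_equal(gl$reward_version, "v2")
})
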