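# shared tabular fixture: random 6-state MDP with soft behaviour and a
# distinct soft target policy, solved exactly by backward induction
ope_fixture <- function(n = 400, seed = 3, qv_scale = NULL) {
  mdp <- random_mdp(n_states = 6, n_actions = 3, horizon = 8, gamma = 0.95,
                    seed = 1)
  pib <- random_policy_matrix(mdp, seed = 2)
  pie <- 0.8 * pib + 0.2 * random_policy_matrix(mdp, seed = 4)
  truth <- mdp_policy_value(mdp, pie)
  qv <- NULL
  if (!is.null(qv_scale)) qv <- lapply(truth$Q, function(Q) qv_scale * Q)
  ds <- simulate_mdp_dataset(mdp, pib, pie, n = n, seed = seed, qv = qv)
  list(mdp = mdp, pib = pib, pie = pie, truth = truth, ds = ds)
}

test_that("self-normalised weights sum to one and collapse on-policy", {
  fx <- ope_fixture(n = 60)
  W <- importance_weights(fx$ds)
  expect_equal(colSums(W), rep(1, fx$ds$H))

  # pi_e = pi_b: every weight is 1/n at every step
  mdp <- fx$mdp
  ds_on <- simulate_mdp_dataset(mdp, fx$pib, fx$pib, n = 40, seed = 9)
  W_on <- importance_weights(ds_on)
  expect_equal(W_on, matrix(1 / 40, 40, mdp$H))

  # a zero behaviour probability on a taken action is an error
  bad <- fx$ds
  bad$per[[1]]$pib[2] <- 0
  expect_error(importance_weights(bad), class = "ventrl_support_error")
})

test_that("PDWIS reduces to the empirical mean return on-policy", {
  fx <- ope_fixture()
  ds_on <- simulate_mdp_dataset(fx$mdp, fx$pib, fx$pib, n = 50, seed = 12)
  est <- pdwis_estimate(ds_on, gamma = fx$mdp$gamma)
  emp <- mean(vapply(ds_on$per, function(p) {
    sum(fx$mdp$gamma^(seq_len(p$T) - 1) * p$r)
  }, numeric(1)))
  expect_equal(est$estimate, emp)
  expect_equal(est$behaviour_value, emp)

  # zero rewards give a zero estimate
  ds0 <- ds_on
  ds0$per <- lapply(ds0$per, function(p) { p$r <- 0 * p$r; p })
  expect_equal(pdwis_estimate(ds0, gamma = 0.9)$estimate, 0)
})

test_that("WDR equals PDWIS exactly when the model values vanish", {
  fx <- ope_fixture(n = 80)
  expect_equal(wdr_estimate(fx$ds, 0.95)$estimate,
               pdwis_estimate(fx$ds, 0.95)$estimate)
  # and the identity holds on arbitrary random data
  set.seed(41)
  per <- lapply(1:25, function(i) {
    Tn <- sample(2:6, 1)
    list(patient_id = i, T = Tn, pib = stats::runif(Tn, 0.2, 1),
         pie = stats::runif(Tn, 0.2, 1), qhat = numeric(Tn),
         vhat = numeric(Tn), r = stats::rnorm(Tn))
  })
  ds <- structure(list(per = per, n = 25, H = 6), class = "ope_dataset")
  expect_equal(wdr_estimate(ds, 0.9)$estimate,
               pdwis_estimate(ds, 0.9)$estimate)
})

test_that("the partial-horizon family interpolates model and importance estimates", {
  fx <- ope_fixture(n = 100, qv_scale = 0.8)
  # j = 0 is the mean model value of the initial states
  g0 <- j_step_return(fx$ds, fx$mdp$gamma, 0)
  expect_equal(g0$g, mean(vapply(fx$ds$per, function(p) p$vhat[1],
                                 numeric(1))))
  expect_equal(mean(g0$contributions), g0$g)
  # j past the horizon equals the full WDR
  expect_equal(j_step_return(fx$ds, 0.95, Inf)$g,
               j_step_return(fx$ds, 0.95, 50)$g)
})

test_that("exact model values on a deterministic problem make every g^(j) equal", {
  # deterministic chain followed by both policies: Q is exact, so the
  # control variates telescope and all partial horizons agree
  S <- 4
  P <- array(0, c(S, 2, S))
  for (s in 1:S) {
    P[s, 1, min(s + 1, S)] <- 1
    P[s, 2, min(s + 1, S)] <- 1
  }
  R <- matrix(c(0.3, 0.3), S, 2, byrow = TRUE)
  mdp <- list(P = P, R = R, mu0 = c(1, 0, 0, 0), H = 5, gamma = 0.9,
              S = S, A = 2)
  pi_det <- matrix(c(1, 0), S, 2, byrow = TRUE)
  truth <- mdp_policy_value(mdp, pi_det)
  ds <- simulate_mdp_dataset(mdp, pi_det, pi_det, n = 20, seed = 2,
                             qv = truth$Q)
  gs <- vapply(c(0, 1, 2, 3, Inf), function(j) {
    j_step_return(ds, mdp$gamma, j)$g
  }, numeric(1))
  expect_equal(gs, rep(truth$value, 5))
})

test_that("the simplex QP matches grid search and picks zero-variance corners", {
  # diagonal covariance with one zero entry: all weight on that horizon
  x <- ventrl:::simplex_qp(diag(c(1, 0, 2)))
  expect_equal(x, c(0, 1, 0))

  set.seed(8)
  for (i in 1:10) {
    A <- matrix(stats::rnorm(9), 3)
    M <- crossprod(A) + diag(0.01, 3)
    x <- ventrl:::simplex_qp(M)
    expect_equal(sum(x), 1)
    expect_true(all(x >= 0))
    obj <- drop(t(x) %*% M %*% x)
    # dense grid-search fallback over the 2-simplex
    grid <- seq(0, 1, by = 0.002)
    best <- Inf
    for (a in grid) {
      b <- grid[grid <= 1 - a + 1e-12]
      c3 <- 1 - a - b
      vals <- M[1, 1] * a^2 + M[2, 2] * b^2 + M[3, 3] * c3^2 +
        2 * M[1, 2] * a * b + 2 * M[1, 3] * a * c3 + 2 * M[2, 3] * b * c3
      best <- min(best, min(vals))
    }
    expect_lt(obj, best + 1e-9)
  }
})

test_that("all estimators agree with the dynamic-programming oracle on a tabular MDP", {
  fx <- ope_fixture(n = 2000, seed = 5, qv_scale = 1)
  truth <- fx$truth$value
  gamma <- fx$mdp$gamma

  for (est in list(pdwis_estimate(fx$ds, gamma),
                   wdr_estimate(fx$ds, gamma),
                   magic_estimate(fx$ds, gamma, J = c(0, 1, 2, 5, Inf),
                                  n_bootstrap = 100, seed = 7))) {
    co <- est$contributions
    blended <- if (est$estimator == "MAGIC") {
      co %*% est$blend_weights
    } else {
      co
    }
    se <- stats::sd(blended) / sqrt(fx$ds$n)
    expect_lt(abs(est$estimate - truth), 3 * se + 1e-12)
  }

  # MAGIC blend weights live on the simplex and beat every vertex
  mg <- magic_estimate(fx$ds, gamma, J = c(0, 1, 2, 5, Inf),
                       n_bootstrap = 100, seed = 7)
  expect_equal(sum(mg$blend_weights), 1)
  expect_true(all(mg$blend_weights >= 0))
})

test_that("a biased model head is down-weighted by the bias proxy", {
  # model values shrunk to 70%: the pure model estimate g^(0) is badly
  # biased, and the blend must mitigate most of that bias
  fx <- ope_fixture(n = 2000, seed = 5, qv_scale = 0.7)
  truth <- fx$truth$value
  mg <- magic_estimate(fx$ds, fx$mdp$gamma, J = c(0, 1, 2, 5, Inf),
                       n_bootstrap = 100, seed = 7)
  g0_err <- abs(j_step_return(fx$ds, fx$mdp$gamma, 0)$g - truth)
  expect_lt(abs(mg$estimate - truth), g0_err / 2)
  # substantial weight leaves the model-only horizon
  expect_lt(mg$blend_weights[["0"]], 0.5)
})

test_that("estimation error shrinks as the dataset grows", {
  errs <- sapply(c(100, 1000), function(n) {
    med <- sapply(1:8, function(r) {
      fx <- ope_fixture(n = n, seed = 100 + r)
      abs(pdwis_estimate(fx$ds, 0.95)$estimate - fx$truth$value)
    })
    stats::median(med)
  })
  expect_lt(errs[2], errs[1])
})

test_that("magic guards small samples and reports CI plus blend weights", {
  fx <- ope_fixture(n = 40, qv_scale = 1)
  small <- structure(list(per = fx$ds$per[1:5], n = 5, H = fx$ds$H),
                     class = "ope_dataset")
  expect_error(magic_estimate(small, 0.95))
  mg <- magic_estimate(fx$ds, 0.95, J = c(0, 2, Inf), n_bootstrap = 50,
                       seed = 3)
  expect_true(is.finite(mg$ci_lower) && is.finite(mg$ci_upper))
  expect_lte(mg$ci_lower, mg$ci_upper)
  td <- tidy(mg)
  expect_equal(td$estimate, mg$estimate)
  expect_equal(td$relative_value, mg$estimate - mg$behaviour_value)
})
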