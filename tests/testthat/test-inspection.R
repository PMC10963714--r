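inspection_fixture <- function(n = 12, seed = 6) {
  coh <- small_cohort(n = n, seed = seed)
  trajs <- build_trajectories(coh$events, coh$outcomes)
  mod <- random_q_model(ncol(trajs[[1]]$states), n_actions = 17, seed = 3)
  list(trajs = trajs, mod = mod)
}

test_that("delta-Q is the exact Q difference with the right sign structure", {
  fx <- inspection_fixture()
  gp <- greedy_policy(fx$mod)
  rec <- delta_q_records(fx$mod, gp, fx$trajs)
  expect_equal(rec$delta_q, rec$q_policy - rec$q_physician)
  # greedy recommendations can never look worse than the physician's
  expect_true(all(rec$delta_q >= -1e-12))
  # agreement means exactly zero
  agree <- rec$physician_action == rec$policy_action
  expect_true(any(agree))
  expect_equal(rec$delta_q[agree], rep(0, sum(agree)))

  # restricted policy: negative delta-Q possible, but only when the
  # physician acted outside the mask
  kk <- restricted_policy(fx$mod)
  cfgr <- restriction_config()
  rec_kk <- delta_q_records(fx$mod, kk, fx$trajs) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(prev_action = dplyr::lag(.data$physician_action)) |>
    dplyr::ungroup()
  # whenever the physician acted inside the mask, delta-Q >= 0; negative
  # values only occur when the clinical action was outside the restriction
  inside <- vapply(seq_len(nrow(rec_kk)), function(i) {
    if (is.na(rec_kk$prev_action[i])) return(TRUE)
    rec_kk$physician_action[i] %in% king_knight_mask(rec_kk$prev_action[i],
                                                     cfgr)
  }, logical(1))
  expect_true(all(rec_kk$delta_q[inside] >= -1e-12))
})

test_that("surfaces conserve the global mean and handle empty cells", {
  fx <- inspection_fixture()
  rec <- delta_q_records(fx$mod, greedy_policy(fx$mod), fx$trajs)
  surf <- aggregate_surfaces(rec)
  expect_equal(nrow(surf), 17)
  # count-weighted cell means recover the global mean delta-Q
  expect_equal(sum(surf$count * surf$mean_delta_q, na.rm = TRUE) /
                 sum(surf$count), mean(rec$delta_q))
  expect_equal(sum(surf$count), nrow(rec))
  # unvisited actions are NA, not zero
  empty <- surf$count == 0
  if (any(empty)) expect_true(all(is.na(surf$mean_delta_q[empty])))

  # a single record fills exactly its own cell
  surf1 <- aggregate_surfaces(rec[1, ])
  expect_equal(sum(surf1$count), 1L)
  filled <- surf1[surf1$count == 1, ]
  expect_equal(filled$action, rec$physician_action[1])
  expect_equal(filled$mean_delta_q, rec$delta_q[1])
})

test_that("per-action Q histograms conserve counts and expose depressed actions", {
  fx <- inspection_fixture(n = 8)
  hist_tab <- q_distribution_per_action(fx$mod, fx$trajs, bins = 15)
  n_states <- sum(vapply(fx$trajs, `[[`, 0L, "T"))
  counts <- hist_tab |>
    dplyr::group_by(.data$action) |>
    dplyr::summarise(n = sum(.data$count))
  expect_equal(counts$n, rep(n_states, 17))

  # depress one action's Q systematically: its histogram mean is lowest.
  # built on a modified copy of the fitted network's advantage head bias
  mod2 <- fx$mod
  mod2$params$a$b[5] <- mod2$params$a$b[5] - 50
  hist2 <- q_distribution_per_action(mod2, fx$trajs, bins = 15)
  means <- hist2 |>
    dplyr::distinct(.data$action, .data$mean_q)
  expect_equal(means$action[which.min(means$mean_q)], 5L)
})

test_that("outcome-stratified action counts conserve step totals", {
  fx <- inspection_fixture(n = 14, seed = 19)
  rec <- delta_q_records(fx$mod, greedy_policy(fx$mod), fx$trajs)
  tab <- action_distribution_by_outcome(rec)
  n_surv <- sum(!rec$died)
  n_dead <- sum(rec$died)
  totals <- tab |>
    dplyr::group_by(.data$outcome, .data$source) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop")
  expect_equal(sort(unique(totals$n)), sort(unique(c(n_surv, n_dead))))
  expect_true(all(totals$n[totals$outcome == "survivor"] == n_surv))

  # all-survivor cohort leaves the non-survivor grids empty
  rec_s <- rec[!rec$died, ]
  tab_s <- action_distribution_by_outcome(rec_s)
  expect_equal(sum(tab_s$count[tab_s$outcome == "non_survivor"]), 0L)
})

test_that("the signed log transform is odd, monotone and unit-calibrated", {
  fx <- inspection_fixture(n = 5)
  tr <- fx$trajs[[1]]
  s <- 0.7
  ser <- trajectory_series(fx$mod, greedy_policy(fx$mod), tr, sigma = s)
  expect_equal(nrow(ser), tr$T)
  f <- function(x) sign(x) * log1p(abs(x) / s)
  expect_equal(ser$log_delta_q, f(ser$delta_q))
  expect_equal(f(0), 0)
  expect_equal(f(-2.3), -f(2.3))
  expect_equal(f(s * (exp(1) - 1)), 1)
  xs <- seq(-3, 3, by = 0.1)
  expect_true(all(diff(f(xs)) > 0))
})

test_that("alerts fire exactly on jumps beyond the threshold", {
  base <- tibble::tibble(patient_id = 1, time_h = 0:19,
                         delta_q = rep(0.5, 20))
  expect_equal(nrow(clinical_alerts(base, tau = 0.1, window = 6)), 0L)

  jumped <- base
  jumped$delta_q[15] <- 0.5 + 2 * 0.3 # single jump of 2 tau
  al <- clinical_alerts(jumped, tau = 0.3, window = 6)
  expect_equal(al$time_h, 14)
  expect_equal(al$jump, 0.6)
  expect_equal(al$reference_median, 0.5)

  expect_equal(nrow(clinical_alerts(jumped, tau = Inf, window = 6)), 0L)
  expect_warning(clinical_alerts(base[1:3, ], tau = 0.1, window = 6))
  expect_error(clinical_alerts(base, tau = -1))
})

test_that("inspection products are pure functions of their inputs", {
  fx <- inspection_fixture(n = 6)
  gp <- greedy_policy(fx$mod)
  r1 <- delta_q_records(fx$mod, gp, fx$trajs)
  r2 <- delta_q_records(fx$mod, gp, fx$trajs)
  expect_identical(r1, r2)
  expect_identical(aggregate_surfaces(r1), aggregate_surfaces(r2))
})
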