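test_that("empty cohort and determinism contracts hold", {
  empty <- simulate_cohort(sim_config(n_patients = 0, seed = 3))
  expect_equal(nrow(empty$events), 0L)
  expect_equal(nrow(empty$outcomes), 0L)

  cfg <- sim_config(n_patients = 25, seed = 123, n_aux_features = 3)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$outcomes, b$outcomes)
  # a different seed changes the draw
  c <- simulate_cohort(sim_config(n_patients = 25, seed = 124,
                                  n_aux_features = 3))
  expect_false(identical(a$events, c$events))
})

test_that("simulated tables have the expected layout and invariants", {
  coh <- small_cohort(n = 20, seed = 8)
  expect_named(coh$events, c("patient_id", "time_h", "variable", "value"))
  expect_named(coh$outcomes,
               c("patient_id", "died", "los_h", "discharge_destination"))
  expect_setequal(unique(coh$outcomes$patient_id), 1:20)
  expect_true(all(coh$outcomes$los_h >= 1))
  expect_true(all(coh$outcomes$discharge_destination[coh$outcomes$died] ==
                    "died"))
  expect_true(all(coh$outcomes$discharge_destination %in%
                    c("home", "rehab", "other_hospital", "died")))
  # settings recorded every hour; observables thinned by missingness
  n_peep <- sum(coh$events$variable == "peep")
  n_pao2 <- sum(coh$events$variable == "pao2")
  expect_lt(n_pao2, n_peep)
})

test_that("mortality rises monotonically with the severity hazard slope", {
  m_of_h1 <- function(h1) {
    coh <- simulate_cohort(sim_config(n_patients = 700, seed = 77,
                                      n_aux_features = 2,
                                      dynamics = list(hazard_h1 = h1)))
    mean(coh$outcomes$died)
  }
  m_low <- m_of_h1(0.5)
  m_mid <- m_of_h1(1.1)
  m_high <- m_of_h1(2.2)
  expect_lt(m_low, m_mid)
  expect_lt(m_mid, m_high)
})

test_that("CSV round trip preserves the cohort and echoes the config", {
  coh <- small_cohort(n = 8, seed = 21)
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(coh, dir)
  back <- read_cohort_csv(dir)
  expect_equal(back$events$value, coh$events$value)
  expect_equal(back$outcomes$died, coh$outcomes$died)
  side <- jsonlite::read_json(file.path(dir, "sim_config.json"))
  expect_equal(side$n_patients, 8)
  expect_equal(side$seed, 21)
})

test_that("ground-truth value behaves like an on-policy Monte-Carlo oracle", {
  cfg <- sim_config(n_patients = 1, seed = 5, n_aux_features = 2)

  expect_error(ground_truth_value(cfg, n_rollouts = 1))

  # a zero-weight reward configuration values every policy at zero
  zero_cfg <- reward_config(w_pf = 0, w_vd = 0, r_death = 0, r_survive = 0,
                            c_los = 0,
                            dest_multiplier = c(home = 0, rehab = 0,
                                                other_hospital = 0, died = 0))
  gt0 <- ground_truth_value(cfg, reward_cfg = zero_cfg, n_rollouts = 40,
                            seed = 2)
  expect_equal(gt0$value, 0)

  # discount 0 equals the mean first-step reward, recomputed by hand
  rc <- reward_config(lambda = 1)
  gt <- ground_truth_value(cfg, reward_cfg = rc, discount = 0,
                           n_rollouts = 60, seed = 31)
  set.seed(31)
  core <- ventrl:::sim_core(cfg, 60)
  first <- vapply(core, function(st) {
    Tn <- length(st$action)
    r1 <- if (Tn > 1) {
      intermediate_reward(st$pf[1], st$pf[2], st$vdvt[1], st$vdvt[2],
                          rc)$reward
    } else {
      rc$lambda * terminal_reward(st$died, st$los_h, st$destination, rc)
    }
    r1
  }, numeric(1))
  expect_equal(gt$value, mean(first))

  # on-policy identity: behaviour value matches a fresh cohort's mean return
  gt_b <- ground_truth_value(cfg, reward_cfg = rc, discount = 0.99,
                             n_rollouts = 250, seed = 4)
  set.seed(99)
  core2 <- ventrl:::sim_core(cfg, 250)
  emp <- mean(vapply(core2, ventrl:::discounted_core_return, numeric(1),
                     reward_cfg = rc, discount = 0.99))
  se <- gt_b$se
  expect_lt(abs(gt_b$value - emp), 3 * sqrt(2) * se)
})

test_that("physician transitions concentrate near the previous action", {
  coh <- simulate_cohort(sim_config(n_patients = 150, seed = 13,
                                    n_aux_features = 2))
  grid <- action_grid()
  acts <- coh$events |>
    dplyr::filter(.data$variable %in% c("peep", "fio2_pct", "ventilated")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value") |>
    dplyr::arrange(.data$patient_id, .data$time_h)
  a <- bin_action(acts$peep, acts$fio2_pct, acts$ventilated > 0.5, grid)
  same_pt <- acts$patient_id[-1] == acts$patient_id[-nrow(acts)]
  d <- ventrl:::action_chebyshev(a[-1], a[-length(a)], grid)[same_pt]
  expect_gt(mean(d <= 1, na.rm = TRUE), 0.8)
})
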