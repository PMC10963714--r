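test_that("carry-forward imputation follows the age-limit rule", {
  out <- carry_forward_impute(c(0, 3), c(5, 7), hours = 0:8, limit = 4)
  expect_equal(out$value, c(5, 5, 5, 7, 7, 7, 7, 7, NA))
  expect_equal(out$status,
               c("observed", "imputed", "imputed", "observed", rep("imputed", 4),
                 "missing"))

  # empty series: everything missing
  empty <- carry_forward_impute(numeric(0), numeric(0), hours = 0:3)
  expect_true(all(is.na(empty$value)))
  expect_true(all(empty$status == "missing"))

  # infinite limit with one observation gives a constant series
  const <- carry_forward_impute(0, 42, hours = 0:9, limit = Inf)
  expect_equal(const$value, rep(42, 10))

  expect_error(carry_forward_impute(c(3, 1), c(1, 2)),
               class = "ventrl_unsorted_error")
})

test_that("imputation never overwrites observations and the mask partitions slots", {
  set.seed(11)
  for (rep in 1:20) {
    times <- sort(sample(0:30, sample(3:10, 1)))
    vals <- stats::rnorm(length(times))
    lim <- sample(c(2, 5, Inf), 1)
    out <- carry_forward_impute(times, vals, hours = 0:30, limit = lim)
    obs <- out$time_h %in% times
    expect_equal(out$value[obs], vals[match(out$time_h[obs], times)])
    expect_equal(out$status[obs], rep("observed", sum(obs)))
    expect_equal(sum(out$status == "observed") + sum(out$status == "imputed") +
                   sum(out$status == "missing"), 31L)
  }
})

test_that("trajectories carry the schema shape, outcomes and valid actions", {
  coh <- small_cohort(n = 15, seed = 44)
  trajs <- build_trajectories(coh$events, coh$outcomes)
  expect_s3_class(trajs, "trajectory_set")
  expect_length(trajs, 15)
  grid <- attr(trajs, "grid")
  for (tr in trajs) {
    expect_equal(nrow(tr$states), tr$T)
    expect_equal(tr$T, coh$outcomes$los_h[coh$outcomes$patient_id ==
                                            tr$patient_id])
    expect_true(all(is.finite(tr$states)))
    expect_true(all(tr$actions >= 1 & tr$actions <= grid$n_actions))
    expect_equal(length(tr$actions), tr$T)
  }
  # error path: a patient absent from outcomes is reported by id
  expect_error(build_trajectories(coh$events, coh$outcomes[-3, ]),
               class = "ventrl_outcome_error")
})

test_that("single-patient hourly events give T equal to the hour count", {
  ev <- tibble::tibble(
    patient_id = 1,
    time_h = rep(0:2, 4),
    variable = rep(c("peep", "fio2_pct", "ventilated", "pao2"), each = 3),
    value = c(8, 8, 10, 50, 50, 60, 1, 1, 1, 90, 95, 100)
  )
  out <- tibble::tibble(patient_id = 1, died = FALSE, los_h = 3,
                        discharge_destination = "home")
  schema <- feature_schema(c("peep", "fio2_pct", "ventilated", "pao2"),
                           carry_forward_limit = c(Inf, Inf, Inf, 8))
  trajs <- build_trajectories(ev, out, schema = schema)
  expect_equal(trajs[[1]]$T, 3L)
  expect_equal(trajs[[1]]$actions,
               bin_action(c(8, 8, 10), c(50, 50, 60), TRUE))
})

test_that("z-scoring guards degenerate variance and honours train statistics", {
  ev <- tibble::tibble(
    patient_id = rep(1:2, each = 8),
    time_h = rep(rep(0:1, 4), 2),
    variable = rep(rep(c("peep", "fio2_pct", "ventilated", "pao2"), each = 2), 2),
    value = c(8, 8, 50, 50, 1, 1, 90, 110,
              8, 8, 50, 50, 1, 1, 70, 130)
  )
  out <- tibble::tibble(patient_id = 1:2, died = FALSE, los_h = 2,
                        discharge_destination = "home")
  schema <- feature_schema(c("peep", "fio2_pct", "ventilated", "pao2"),
                           carry_forward_limit = Inf)
  trajs <- build_trajectories(ev, out, schema = schema)
  # constant features normalise to all zeros (sd guarded to 1)
  expect_true(all(trajs[[1]]$states[, "peep"] == 0))
  stats_tab <- normalization_stats(trajs)
  expect_equal(stats_tab$sd[stats_tab$feature == "peep"], 1)
  # externally supplied statistics are honoured verbatim
  stats_tab$mean[stats_tab$feature == "pao2"] <- 0
  stats_tab$sd[stats_tab$feature == "pao2"] <- 2
  trajs2 <- build_trajectories(ev, out, schema = schema, stats = stats_tab)
  expect_equal(trajs2[[1]]$states[, "pao2"], c(45, 55))
})

test_that("schema aggregations add trailing-window summary columns", {
  ev <- tibble::tibble(patient_id = 1, time_h = 0:5,
                       variable = "pao2", value = c(1, 2, 3, 4, 5, 6))
  ev <- dplyr::bind_rows(ev, tibble::tibble(
    patient_id = 1, time_h = 0:5, variable = "ventilated", value = 0))
  out <- tibble::tibble(patient_id = 1, died = FALSE, los_h = 6,
                        discharge_destination = "home")
  schema <- feature_schema(c("pao2", "ventilated"),
                           carry_forward_limit = Inf,
                           windows = list(4, numeric(0)),
                           ops = list(c("mean", "max"), character(0)),
                           normalization = "none")
  trajs <- build_trajectories(ev, out, schema = schema)
  raw <- trajs[[1]]$raw
  expect_true(all(c("pao2_w4mean", "pao2_w4max") %in% colnames(raw)))
  expect_equal(raw[, "pao2_w4mean"], c(1, 1.5, 2, 2.5, 3.5, 4.5))
  expect_equal(raw[, "pao2_w4max"], c(1, 2, 3, 4, 5, 6))
})

test_that("imputed fractions match the closed-form expectation of the mask process", {
  rate <- 0.3
  limit <- 8
  coh <- simulate_cohort(sim_config(
    n_patients = 120, seed = 202, n_aux_features = 2,
    missingness_rates = c(pao2 = rate, paco2 = rate, etco2 = rate, aux = 0)))
  trajs <- build_trajectories(coh$events, coh$outcomes)
  statuses <- unlist(lapply(trajs, function(tr) tr$mask[, "pao2"]))
  # each hourly cell is independently observed w.p. 1 - rate; a cell is
  # missing iff the last min(t, limit) + 1 draws all failed
  lens <- vapply(trajs, `[[`, 0L, "T")
  exp_missing <- mean(unlist(lapply(lens, function(Tn) {
    t <- seq_len(Tn) - 1
    rate^(pmin(t, limit) + 1)
  })))
  expect_lt(abs(mean(statuses == "observed") - (1 - rate)), 0.02)
  expect_lt(abs(mean(statuses == "missing") - exp_missing), 0.02)
  expect_lt(abs(mean(statuses == "imputed") - (rate - exp_missing)), 0.02)
})

test_that("low-quality exclusion matches a brute-force recount", {
  coh <- small_cohort(n = 25, seed = 15)
  trajs <- build_trajectories(coh$events, coh$outcomes)

  all_kept <- exclude_low_quality(trajs, 1.0)
  expect_length(all_kept$kept, 25)
  # at threshold zero only fully observed stays survive
  none_kept <- exclude_low_quality(trajs, 0.0)
  expect_length(none_kept$kept,
                sum(all_kept$report$missing_fraction == 0))

  thr <- stats::median(all_kept$report$missing_fraction)
  res <- exclude_low_quality(trajs, thr)
  schema <- attr(trajs, "schema")
  req <- schema$variable[schema$required]
  brute <- vapply(trajs, function(tr) {
    mean(tr$mask[, colnames(tr$mask) %in% req] != "observed") <= thr
  }, logical(1))
  expect_equal(vapply(res$kept, `[[`, 0, "patient_id"),
               vapply(trajs, `[[`, 0, "patient_id")[brute])
  expect_equal(sum(res$report$excluded), sum(!brute))
})

test_that("train/test split is a seeded patient-level partition", {
  coh <- small_cohort(n = 10, seed = 62)
  trajs <- build_trajectories(coh$events, coh$outcomes)
  sp <- split_train_test(trajs, 0.7, seed = 9)
  expect_length(sp$train, 7)
  expect_length(sp$test, 3)
  ids <- function(set) vapply(set, `[[`, 0, "patient_id")
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(trajs))
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- split_train_test(trajs, 0.7, seed = 9)
  expect_identical(ids(sp$train), ids(sp2$train))
  expect_error(split_train_test(ventrl:::subset_trajectory_set(trajs, 1),
                                0.5, 1))
})
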