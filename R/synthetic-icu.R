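#' Synthetic ICU cohort configuration
#'
#' Configuration of the seeded stochastic simulator of ventilated
#' COVID-ARDS-like ICU admissions. The simulator is a fixture: it reproduces
#' the *statistical structure* the pipeline assumes — hourly time steps,
#' ventilator settings and gas-exchange observables with realistic
#' missingness, physician actions concentrated mid-grid with mostly small
#' step-to-step transitions, an inverted-U PEEP response, and terminal
#' outcomes calibrated to an ICU mortality near 24.4% — not patient-level
#' physiological fidelity.
#'
#' The generative model: a latent severity `z_t` follows
#' `z_{t+1} = ar * z_t + effect(a_t) + eps`, where the treatment effect of a
#' ventilated action is an inverted-U in PEEP (maximal benefit at
#' `peep_optimum_center`, harm beyond `peep_optimum_width`) plus an FiO2
#' toxicity term; the P/F observable decreases in severity and in squared
#' PEEP distance from the optimum and increases transiently with FiO2
#' (shunt-mediated); dead-space fraction rises logistically with severity
#' and with PEEP above the optimum; the per-hour death hazard is logistic in
#' severity, its intercept solved from `mortality_calibration` via a
#' geometric-survival inversion at a reference exposure; survivors are
#' discharged once severity falls below a threshold, to a destination drawn
#' from a severity-at-discharge-dependent categorical.
#'
#' Physician behaviour is a softmax over the 17 actions whose utility
#' favours higher ventilatory support at higher severity and carries a
#' strong bonus for staying within Chebyshev distance 1 of the previous
#' action, which concentrates consecutive actions on the grid.
#'
#' @param n_patients Number of admissions to simulate.
#' @param max_horizon Maximum stay in hours (default 72 to keep experiments
#'   desk-scale; configurable).
#' @param n_aux_features Number of auxiliary AR(1) channels correlated with
#'   severity (stand-ins for the wider clinical feature set).
#' @param seed Integer seed; identical configs give bit-identical tables.
#' @param severity_ar_coef AR coefficient of the latent severity, in (0, 1).
#' @param peep_optimum_center,peep_optimum_width Centre and width (cmH2O) of
#'   the inverted-U PEEP response.
#' @param mortality_calibration Target ICU mortality fraction (default
#'   0.244).
#' @param missingness_rates Named per-variable missingness fractions; names
#'   among `pao2`, `paco2`, `etco2`, `aux`.
#' @param behavior_temperature Softmax temperature of the physician policy.
#' @param grid The [action_grid()] the physicians act on.
#' @param dynamics Optional named list overriding individual dynamics
#'   coefficients (see `sim_dynamics()` for names and defaults).
#' @returns A `sim_config` object.
#' @examples
#' cfg <- sim_config(n_patients = 10, seed = 1)
#' tabs <- simulate_cohort(cfg)
#' head(tabs$events)
#' @export
sim_config <- function(n_patients,
                       max_horizon = 72,
                       n_aux_features = 16,
                       seed = 1L,
                       severity_ar_coef = 0.9,
                       peep_optimum_center = 10,
                       peep_optimum_width = 4,
                       mortality_calibration = 0.244,
                       missingness_rates = c(pao2 = 0.3, paco2 = 0.3,
                                             etco2 = 0.3, aux = 0.2),
                       behavior_temperature = 1,
                       grid = action_grid(),
                       dynamics = list()) {
  assert_number(n_patients, "n_patients", lower = 0)
  assert_number(max_horizon, "max_horizon", lower = 1)
  assert_number(severity_ar_coef, "severity_ar_coef", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(mortality_calibration, "mortality_calibration",
                lower = 0, upper = 1)
  assert_number(behavior_temperature, "behavior_temperature",
                lower = 0, strict_lower = TRUE)
  abort_if(any(missingness_rates < 0 | missingness_rates > 1),
           "`missingness_rates` must lie in [0, 1].")
  dyn <- utils::modifyList(sim_dynamics(), dynamics)
  structure(list(
    n_patients = as.integer(n_patients),
    max_horizon = as.integer(max_horizon),
    n_aux_features = as.integer(n_aux_features),
    seed = as.integer(seed),
    severity_ar_coef = severity_ar_coef,
    peep_optimum_center = peep_optimum_center,
    peep_optimum_width = peep_optimum_width,
    mortality_calibration = mortality_calibration,
    missingness_rates = missingness_rates,
    behavior_temperature = behavior_temperature,
    grid = grid,
    dynamics = dyn
  ), class = "sim_config")
}

# dynamics coefficients; exposed for documentation and overrides.
# hazard_ref_exposure is the effective at-risk time (hours) used to invert
# the per-hour hazard intercept from the target cohort mortality; fixed by
# one-off calibration against the default cohort.
sim_dynamics <- function() {
  list(
    sigma_z = 0.25,          # severity innovation sd
    z0_mean = 1.0,           # initial severity mean
    z0_sd = 0.5,
    peep_benefit = 0.12,     # severity reduction at optimal PEEP
    fio2_recovery = 0.02,    # severity reduction per unit FiO2 above 0.21
    fio2_toxicity = 0.04,    # toxicity load per unit FiO2 above the threshold
    fio2_tox_threshold = 0.6, # FiO2 below this deposits no toxicity
    hazard_tox = 0.1,        # log-odds of hourly death per unit toxicity load
    nv_effect = 0.06,        # severity drift per unit z when not ventilated
    pf_base = 260,           # mmHg, severity-free P/F at optimal PEEP
    k_z = 90,                # P/F loss per unit severity
    k_peep = 1.6,            # P/F loss per (cmH2O off optimum)^2
    fio2_pf_boost = 35,      # transient P/F gain per unit FiO2 above 0.21
    pf_noise = 15,
    vd_c0 = -1.4, vd_c1 = 0.55, vd_c2 = 0.12, vd_noise = 0.02,
    paco2_base = 35, paco2_slope = 25, paco2_noise = 1.5,
    toxmarker_noise = 0.15,  # sd of the inflammation-marker observable
    hazard_h1 = 1.1,         # log-odds of hourly death per unit severity
    hazard_ref_exposure = 16.5,
    hazard_z_ref = 0.9,      # reference severity of the calibration inversion
    discharge_threshold = 0.0,
    discharge_prob = 0.25,   # hourly discharge prob once below threshold
    aux_ar = 0.8, aux_load_sd = 0.5, aux_noise = 0.3,
    behav_sev_pref = 1.6,    # utility of support level scaled by severity
    behav_mid_pref = 2.0,    # penalty per unit |support - 0.45|
    behav_stickiness = 3.5,  # bonus for staying within Chebyshev 1
    behav_nv_base = -2.0, behav_nv_sev = 2.5,
    # practice-style heterogeneity: per-patient persistent preference of the
    # treating team for high / mid FiO2 (probabilities of balanced,
    # aggressive, moderate styles; default is a single balanced style)
    style_probs = c(balanced = 1, aggressive = 0, moderate = 0),
    style_strength = 2.5
  )
}

#' Simulator preset with a short-term/long-term conflict
#'
#' A [sim_config()] variant in which raising FiO2 strongly improves
#' short-term gas exchange — both an immediate shunt-mediated P/F boost and
#' an accelerated decline of the latent severity that drives P/F — while
#' depositing a cumulative oxygen-toxicity load that raises the death
#' hazard without showing up in the gas-exchange observables. Policies
#' chasing the intermediate reward therefore genuinely profit from maximal
#' FiO2 at a mortality cost that only a terminal-weighted reward sees. Used
#' to demonstrate that cross off-policy evaluation unmasks reward-hacking
#' policies.
#'
#' @param n_patients,seed,... Passed to [sim_config()].
#' @param dynamics Further dynamics overrides merged over the preset.
#' @returns A `sim_config`.
#' @export
sim_config_conflict <- function(n_patients, seed = 1L, dynamics = list(),
                                ...) {
  preset <- list(fio2_pf_boost = 200, fio2_recovery = 0.5,
                 fio2_toxicity = 3, hazard_tox = 0.6,
                 peep_benefit = 0.12, k_peep = 2.5,
                 z0_mean = 1.5, z0_sd = 0.4,
                 discharge_threshold = 0, discharge_prob = 0.3,
                 behav_mid_pref = 3, behav_sev_pref = 2.5,
                 style_probs = c(balanced = 0.4, aggressive = 0.3,
                                 moderate = 0.3))
  sim_config(n_patients = n_patients, seed = seed,
             dynamics = utils::modifyList(preset, dynamics), ...)
}

# bin midpoints used by the simulator's physiology (last PEEP bin open)
grid_midpoints <- function(grid) {
  pe <- grid$peep_edges
  fe <- grid$fio2_edges
  pm <- (pe[-length(pe)] + pe[-1]) / 2
  if (is.infinite(pm[length(pm)])) {
    pm[length(pm)] <- pe[length(pe) - 1] + 2
  }
  fm <- (fe[-length(fe)] + fe[-1]) / 2 / 100
  tab <- action_table(grid)
  vent <- tab[!is.na(tab$i_peep), ]
  list(peep = pm[vent$i_peep + 1L], fio2 = fm[vent$i_fio2 + 1L])
}

# physician softmax utilities for one step, vectorised over patients.
# z: numeric vector; prev: integer actions (NA before the first step);
# style: optional integer per patient (1 balanced, 2 aggressive, 3 moderate)
behaviour_utilities <- function(z, prev, config, style = NULL) {
  dyn <- config$dynamics
  grid <- config$grid
  n_vent <- grid$n_actions - 1L
  mids <- grid_midpoints(grid)
  support <- (mids$peep / max(mids$peep) + mids$fio2) / 2
  support <- (support - min(support)) / (max(support) - min(support))

  u <- matrix(0, length(z), grid$n_actions)
  u[, seq_len(n_vent)] <- outer(z, support, function(zz, s) {
    dyn$behav_sev_pref * zz * s
  }) - matrix(dyn$behav_mid_pref * abs(support - 0.45),
              length(z), n_vent, byrow = TRUE)
  u[, grid$nv_index] <- dyn$behav_nv_base - dyn$behav_nv_sev * z

  if (!is.null(style)) {
    tabf <- action_coords(seq_len(n_vent), grid)[, 2]
    target <- c(NA, grid$n_fio2 - 1L, 1L) # aggressive: top bin; moderate: low
    for (s in 2:3) {
      rows <- which(style == s)
      if (length(rows)) {
        pen <- -dyn$style_strength * abs(tabf - target[s])
        u[rows, seq_len(n_vent)] <- u[rows, seq_len(n_vent)] +
          matrix(pen, length(rows), n_vent, byrow = TRUE)
      }
    }
  }

  has_prev <- !is.na(prev)
  if (any(has_prev)) {
    tab <- action_coords(seq_len(n_vent), grid)
    for (i in which(has_prev)) {
      p <- prev[i]
      if (p == grid$nv_index) {
        u[i, grid$nv_index] <- u[i, grid$nv_index] + dyn$behav_stickiness
      } else {
        pc <- action_coords(p, grid)
        near <- pmax(abs(tab[, 1] - pc[1, 1]), abs(tab[, 2] - pc[1, 2])) <= 1
        u[i, which(near)] <- u[i, which(near)] + dyn$behav_stickiness
      }
    }
  }
  u / config$behavior_temperature
}

# severity increment of each action, vectorised over actions
action_effect <- function(config) {
  dyn <- config$dynamics
  grid <- config$grid
  mids <- grid_midpoints(grid)
  rel <- (mids$peep - config$peep_optimum_center) / config$peep_optimum_width
  vent_eff <- -dyn$peep_benefit * (1 - rel^2) -
    dyn$fio2_recovery * (mids$fio2 - 0.21) / 0.79
  c(vent_eff, NA_real_) # NV handled separately (depends on z)
}

# per-step oxygen-toxicity load of each ventilated action; only FiO2 above
# the clinical safety threshold (default 60%) deposits load
action_toxicity <- function(config) {
  dyn <- config$dynamics
  mids <- grid_midpoints(config$grid)
  thr <- dyn$fio2_tox_threshold
  c(dyn$fio2_toxicity * pmax(0, mids$fio2 - thr) / (1 - thr), 0)
}

# core simulator: complete per-patient series, no missingness.
# policy_fun(obs_matrix, prev_action) -> n x n_actions probability matrix,
# or NULL for the built-in physician behaviour.
sim_core <- function(config, n, policy_fun = NULL) {
  dyn <- config$dynamics
  grid <- config$grid
  n_vent <- grid$n_actions - 1L
  mids <- grid_midpoints(grid)
  eff <- action_effect(config)
  opt <- config$peep_optimum_center

  p_step_ref <- 1 - (1 - config$mortality_calibration)^(1 / dyn$hazard_ref_exposure)
  # intercept inverted at the default slope so overriding hazard_h1 shifts
  # mortality monotonically instead of being re-calibrated away
  h0 <- stats::qlogis(max(p_step_ref, 1e-12)) -
    sim_dynamics()$hazard_h1 * dyn$hazard_z_ref

  if (n == 0) return(list())

  tox_of <- action_toxicity(config)
  tox <- numeric(n) # cumulative oxygen-toxicity load
  style <- sample.int(3, n, replace = TRUE, prob = dyn$style_probs)
  z <- stats::rnorm(n, dyn$z0_mean, dyn$z0_sd)
  aux_load <- stats::rnorm(config$n_aux_features, 0, dyn$aux_load_sd)
  aux <- matrix(stats::rnorm(n * config$n_aux_features, 0, dyn$aux_noise),
                n, config$n_aux_features)
  aux <- aux + outer(z, aux_load)

  alive <- rep(TRUE, n)
  in_icu <- rep(TRUE, n)
  prev <- rep(NA_integer_, n)

  # time-major accumulators, assembled per patient at the end
  acc <- list()
  died <- rep(FALSE, n)
  los <- rep(config$max_horizon, n)

  for (t in seq_len(config$max_horizon)) {
    act_idx <- which(in_icu)
    if (length(act_idx) == 0) break

    if (is.null(policy_fun)) {
      # initial settings are style-neutral (standard starting support);
      # practice styles express themselves through subsequent adjustments
      u <- behaviour_utilities(z[act_idx], prev[act_idx], config,
                               style = if (t > 1) style[act_idx])
      pmat <- t(apply(u, 1, softmax))
    } else {
      obs <- cbind(pf = dyn$pf_base - dyn$k_z * z[act_idx],
                   z = z[act_idx], aux[act_idx, , drop = FALSE])
      pmat <- policy_fun(obs, prev[act_idx])
      pmat <- pmat / rowSums(pmat)
    }
    # Gumbel-max sampling: exact categorical draw per row
    g <- matrix(-log(-log(stats::runif(length(act_idx) * grid$n_actions))),
                length(act_idx), grid$n_actions)
    a <- max.col(log(pmat) + g, ties.method = "first")
    a_prob <- pmat[cbind(seq_along(act_idx), a)]

    is_nv <- a == grid$nv_index
    peep_t <- ifelse(is_nv, 0, mids$peep[pmin(a, n_vent)])
    fio2_t <- ifelse(is_nv, 0.21, mids$fio2[pmin(a, n_vent)])

    # severity transition
    eff_t <- ifelse(is_nv, dyn$nv_effect * z[act_idx], eff[pmin(a, n_vent)])
    z_new <- config$severity_ar_coef * z[act_idx] + eff_t +
      stats::rnorm(length(act_idx), 0, dyn$sigma_z)

    # observables at this step
    pf <- dyn$pf_base - dyn$k_z * z[act_idx] -
      dyn$k_peep * (peep_t - opt)^2 +
      dyn$fio2_pf_boost * (fio2_t - 0.21) / 0.79 +
      stats::rnorm(length(act_idx), 0, dyn$pf_noise)
    pf <- pmax(pf, 30)
    pao2 <- pf * fio2_t
    vdvt <- stats::plogis(dyn$vd_c0 + dyn$vd_c1 * z[act_idx] +
                            dyn$vd_c2 * pmax(0, peep_t - opt)) +
      stats::rnorm(length(act_idx), 0, dyn$vd_noise)
    vdvt <- clip(vdvt, 0.01, 0.95)
    paco2 <- dyn$paco2_base + dyn$paco2_slope * vdvt +
      stats::rnorm(length(act_idx), 0, dyn$paco2_noise)
    paco2 <- pmax(paco2, 15)
    etco2 <- paco2 * (1 - vdvt)

    tox_new <- tox[act_idx] + tox_of[a]
    toxmarker <- tox_new + stats::rnorm(length(act_idx), 0, dyn$toxmarker_noise)

    aux[act_idx, ] <- dyn$aux_ar * aux[act_idx, , drop = FALSE] +
      outer(z[act_idx], aux_load) * (1 - dyn$aux_ar) +
      matrix(stats::rnorm(length(act_idx) * config$n_aux_features, 0,
                          dyn$aux_noise),
             length(act_idx), config$n_aux_features)

    acc[[t]] <- list(
      pid = act_idx, t = rep(t - 1L, length(act_idx)), action = a,
      behav_prob = a_prob, peep = peep_t, fio2 = fio2_t,
      ventilated = !is_nv, pao2 = pao2, paco2 = paco2, etco2 = etco2,
      pf = pf, vdvt = vdvt, z = z[act_idx], toxmarker = toxmarker,
      aux = aux[act_idx, , drop = FALSE]
    )

    # terminal events after the transition
    tox[act_idx] <- tox_new
    hz <- stats::plogis(h0 + dyn$hazard_h1 * z_new +
                          dyn$hazard_tox * tox[act_idx])
    dies <- stats::runif(length(act_idx)) < hz
    can_dc <- !dies & z_new < dyn$discharge_threshold
    dc <- can_dc & stats::runif(length(act_idx)) < dyn$discharge_prob

    z[act_idx] <- z_new
    prev[act_idx] <- a

    ended <- dies | dc | t == config$max_horizon
    if (any(ended)) {
      idx_end <- act_idx[ended]
      died[idx_end] <- dies[ended]
      los[idx_end] <- t
      in_icu[idx_end] <- FALSE
      alive[idx_end[dies[ended]]] <- FALSE
    }
  }

  # survivor discharge destinations from severity at discharge
  dest <- character(n)
  for (i in seq_len(n)) {
    if (died[i]) {
      dest[i] <- "died"
    } else {
      z_end <- z[i]
      pr <- softmax(c(home = -2 * z_end, rehab = 0.3,
                      other_hospital = 0.8 * z_end))
      dest[i] <- sample(c("home", "rehab", "other_hospital"), 1, prob = pr)
    }
  }

  # assemble per-patient series (time order preserved within patient)
  pid_all <- unlist(lapply(acc, `[[`, "pid"))
  ord <- order(pid_all, unlist(lapply(acc, `[[`, "t")))
  flat <- function(fld) unlist(lapply(acc, `[[`, fld))[ord]
  aux_all <- do.call(rbind, lapply(acc, `[[`, "aux"))[ord, , drop = FALSE]
  pid_sorted <- pid_all[ord]
  idx_by_pid <- split(seq_along(pid_sorted), pid_sorted)

  fields <- list(action = as.integer(flat("action")),
                 behav_prob = flat("behav_prob"), peep = flat("peep"),
                 fio2 = flat("fio2"), ventilated = as.logical(flat("ventilated")),
                 pao2 = flat("pao2"), paco2 = flat("paco2"),
                 etco2 = flat("etco2"), pf = flat("pf"),
                 vdvt = flat("vdvt"), z = flat("z"),
                 toxmarker = flat("toxmarker"))

  lapply(seq_len(n), function(i) {
    rows <- idx_by_pid[[as.character(i)]]
    st <- lapply(fields, function(v) v[rows])
    st$aux <- aux_all[rows, , drop = FALSE]
    st$patient_id <- i
    st$died <- died[i]
    st$los_h <- los[i]
    st$destination <- dest[i]
    st
  })
}

#' Simulate a synthetic ICU cohort
#'
#' Runs the seeded simulator in [sim_config()] and returns long-format
#' tables in the layout the trajectory builder consumes. Observable values
#' are masked (rows dropped) at the configured per-variable missingness
#' rates to exercise carry-forward imputation; ventilator settings are
#' always recorded.
#'
#' @param config A [sim_config()].
#' @returns A list with `events` (tibble: `patient_id`, `time_h`, `variable`,
#'   `value`), `outcomes` (tibble: `patient_id`, `died`, `los_h`,
#'   `discharge_destination`) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  core <- sim_core(config, config$n_patients)
  events_outcomes_from_core(core, config)
}

events_outcomes_from_core <- function(core, config) {
  if (length(core) == 0) {
    return(list(
      events = tibble::tibble(patient_id = integer(0), time_h = numeric(0),
                              variable = character(0), value = numeric(0)),
      outcomes = tibble::tibble(patient_id = integer(0), died = logical(0),
                                los_h = numeric(0),
                                discharge_destination = character(0)),
      config = config
    ))
  }
  mr <- config$missingness_rates
  rate_for <- function(v) {
    if (v %in% names(mr)) mr[[v]] else if ("aux" %in% names(mr)) mr[["aux"]] else 0
  }
  aux_names <- sprintf("aux_%02d", seq_len(config$n_aux_features))

  events <- purrr::map_dfr(core, function(st) {
    Tn <- length(st$action)
    base <- tibble::tibble(
      patient_id = st$patient_id,
      time_h = rep(seq_len(Tn) - 1, 7),
      variable = rep(c("peep", "fio2_pct", "ventilated", "pao2", "paco2",
                       "etco2", "toxmarker"), each = Tn),
      value = c(st$peep, st$fio2 * 100, as.numeric(st$ventilated),
                st$pao2, st$paco2, st$etco2, st$toxmarker)
    )
    auxtab <- tibble::tibble(
      patient_id = st$patient_id,
      time_h = rep(seq_len(Tn) - 1, config$n_aux_features),
      variable = rep(aux_names, each = Tn),
      value = as.vector(st$aux)
    )
    dplyr::bind_rows(base, auxtab)
  })

  maskable <- events$variable %in% c("pao2", "paco2", "etco2", "toxmarker",
                                     aux_names)
  rates <- vapply(events$variable, function(v) {
    if (startsWith(v, "aux_")) rate_for("aux") else rate_for(v)
  }, numeric(1))
  drop <- maskable & stats::runif(nrow(events)) < rates
  events <- events[!drop, ]

  outcomes <- purrr::map_dfr(core, function(st) {
    tibble::tibble(patient_id = st$patient_id, died = st$died,
                   los_h = st$los_h,
                   discharge_destination = st$destination)
  })
  list(events = events, outcomes = outcomes, config = config)
}

#' Write a simulated cohort to disk
#'
#' Writes `events.csv`, `outcomes.csv` (UTF-8, header row) and a
#' `sim_config.json` sidecar echoing the full configuration.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @returns Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(events = file.path(dir, "events.csv"),
             outcomes = file.path(dir, "outcomes.csv"),
             config = file.path(dir, "sim_config.json"))
  utils::write.csv(cohort$events, paths["events"], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths["outcomes"], row.names = FALSE)
  cfg <- unclass(cohort$config)
  cfg$grid <- list(peep_edges = cfg$grid$peep_edges,
                   fio2_edges = cfg$grid$fio2_edges)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir Directory containing `events.csv` and `outcomes.csv`.
#' @returns A list with `events` and `outcomes` tibbles.
#' @export
read_cohort_csv <- function(dir) {
  events <- tibble::as_tibble(utils::read.csv(file.path(dir, "events.csv")))
  outcomes <- tibble::as_tibble(utils::read.csv(file.path(dir, "outcomes.csv")))
  outcomes$died <- as.logical(outcomes$died)
  list(events = events, outcomes = outcomes)
}

#' Monte-Carlo ground-truth policy value on the simulator
#'
#' On-policy estimate of the expected discounted shaped return of a policy
#' under the simulator — the oracle against which off-policy estimates are
#' validated in tests. The policy receives the simulator's raw observables;
#' `policy_fun = NULL` evaluates the built-in physician behaviour.
#'
#' @param config A [sim_config()] (its `n_patients` is ignored).
#' @param policy_fun `function(obs, prev_action)` returning a probability
#'   matrix over actions, or `NULL` for the physician behaviour.
#' @param reward_cfg A [reward_config()].
#' @param discount Discount factor in `[0, 1]`.
#' @param n_rollouts Number of simulated admissions (>= 2).
#' @param seed Integer seed.
#' @returns A tibble with `value`, `se`, `n`.
#' @export
ground_truth_value <- function(config, policy_fun = NULL,
                               reward_cfg = reward_config(),
                               discount = 0.99, n_rollouts = 200,
                               seed = 1L) {
  abort_if(n_rollouts < 2, "`n_rollouts` must be at least 2 to estimate a standard error.")
  assert_number(discount, "discount", lower = 0, upper = 1)
  set.seed(seed)
  core <- sim_core(config, n_rollouts, policy_fun = policy_fun)
  returns <- vapply(core, function(st) {
    discounted_core_return(st, reward_cfg, discount)
  }, numeric(1))
  tibble::tibble(value = mean(returns),
                 se = stats::sd(returns) / sqrt(n_rollouts),
                 n = n_rollouts)
}

# shaped discounted return of one core rollout (true gas series, no
# missingness): intermediate components per step, lambda * terminal at end
discounted_core_return <- function(st, reward_cfg, discount) {
  Tn <- length(st$action)
  r <- numeric(Tn)
  if (Tn > 1) {
    inter <- intermediate_reward(st$pf[-Tn], st$pf[-1],
                                 st$vdvt[-Tn], st$vdvt[-1], reward_cfg)
    r[seq_len(Tn - 1)] <- inter$reward
  }
  r[Tn] <- r[Tn] + reward_cfg$lambda *
    terminal_reward(st$died, st$los_h, st$destination, reward_cfg)
  sum(discount^(seq_len(Tn) - 1) * r)
}
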