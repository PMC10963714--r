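#' Reward configuration
#'
#' Parameters of the shaped clinical reward. The reward has two separable
#' components: an intermediate gas-exchange component rewarding hour-to-hour
#' improvement in oxygenation (P/F ratio) and penalising worsening
#' dead-space fraction (Vd/Vt), and a terminal outcome component combining
#' ICU mortality, length of stay and discharge destination. The weighting
#' factor `lambda` multiplies the terminal component; the study grid varies
#' it over `c(0.25, 0.5, 1, 2, 4, 8)` (reward versions v1..v6).
#'
#' Per-component deltas are scaled (`s_pf` mmHg of P/F change and `s_vd` of
#' Vd/Vt change each count as one unit) and clipped to `±clip` so a single
#' extreme measurement cannot dominate a trajectory. The terminal component
#' is `-r_death` on death, and on survival
#' `r_survive * dest_multiplier[destination] - c_los * los_h`. The default
#' LOS penalty is chosen so a 14-day stay costs half of `r_survive`.
#'
#' @param lambda Positive weighting of the terminal component.
#' @param w_pf,w_vd Weights of the P/F and Vd/Vt intermediate terms.
#' @param s_pf Scale of P/F change, mmHg per unit reward.
#' @param s_vd Scale of Vd/Vt change per unit reward.
#' @param clip Maximum absolute value of each intermediate term.
#' @param r_death Penalty magnitude for ICU death.
#' @param r_survive Bonus magnitude for survival.
#' @param dest_multiplier Named multipliers in `[0, 1]` for survivor
#'   discharge destinations.
#' @param c_los Per-hour length-of-stay penalty for survivors.
#' @returns A `reward_config` object.
#' @examples
#' cfg <- reward_config(lambda = 2)
#' terminal_reward(died = FALSE, los_h = 0, destination = "home", cfg = cfg)
#' @export
reward_config <- function(lambda = 1, w_pf = 1, w_vd = 1,
                          s_pf = 50, s_vd = 0.1, clip = 1,
                          r_death = 1, r_survive = 1,
                          dest_multiplier = c(home = 1, rehab = 0.75,
                                              other_hospital = 0.5),
                          c_los = 0.5 * r_survive / (14 * 24)) {
  assert_number(lambda, "lambda", lower = 0, strict_lower = TRUE)
  assert_number(s_pf, "s_pf", lower = 0, strict_lower = TRUE)
  assert_number(s_vd, "s_vd", lower = 0, strict_lower = TRUE)
  assert_number(clip, "clip", lower = 0, strict_lower = TRUE)
  abort_if(any(dest_multiplier < 0 | dest_multiplier > 1),
           "`dest_multiplier` values must lie in [0, 1].")
  abort_if(is.null(names(dest_multiplier)) || any(names(dest_multiplier) == ""),
           "`dest_multiplier` must be a named vector.")
  structure(list(lambda = lambda, w_pf = w_pf, w_vd = w_vd,
                 s_pf = s_pf, s_vd = s_vd, clip = clip,
                 r_death = r_death, r_survive = r_survive,
                 dest_multiplier = dest_multiplier, c_los = c_los),
            class = "reward_config")
}

#' The six study reward versions
#'
#' Returns the reward configuration grid of the two-round evaluation design:
#' identical component parameters, terminal weighting lambda varied over the
#' predefined values 0.25, 0.5, 1, 2, 4, 8 (versions v1..v6).
#'
#' @param lambdas Positive weighting values.
#' @param ... Passed to [reward_config()] for the shared parameters.
#' @returns Named list of `reward_config` objects ("v1", "v2", ...).
#' @export
reward_version_grid <- function(lambdas = c(0.25, 0.5, 1, 2, 4, 8), ...) {
  abort_if(any(lambdas <= 0), "All `lambdas` must be positive.")
  out <- lapply(lambdas, function(l) reward_config(lambda = l, ...))
  names(out) <- paste0("v", seq_along(lambdas))
  out
}

#' P/F ratio
#'
#' Oxygenation index: arterial partial pressure of oxygen divided by the
#' inspired oxygen fraction.
#'
#' @param pao2 PaO2 in mmHg.
#' @param fio2 FiO2 as a fraction in (0, 1].
#' @returns P/F in mmHg.
#' @examples
#' pf_ratio(100, 0.5) # 200
#' @export
pf_ratio <- function(pao2, fio2) {
  abort_if(any(fio2 <= 0, na.rm = TRUE), "`fio2` must be positive.")
  abort_if(any(pao2 < 0, na.rm = TRUE), "`pao2` must be non-negative.")
  pao2 / fio2
}

#' Dead-space fraction (Enghoff-Bohr)
#'
#' Vd/Vt estimated from arterial and end-tidal CO2:
#' `(PaCO2 - ETCO2) / PaCO2`, clipped to `[0, 1]`. Values requiring the clip
#' (ETCO2 above PaCO2) are physiologically implausible and flagged via the
#' `"clipped"` attribute.
#'
#' @param paco2 PaCO2 in mmHg (positive).
#' @param etco2 ETCO2 in mmHg (non-negative).
#' @returns Fractions in `[0, 1]` with a logical `"clipped"` attribute.
#' @examples
#' dead_space_fraction(40, 30) # 0.25
#' @export
dead_space_fraction <- function(paco2, etco2) {
  abort_if(any(paco2 <= 0, na.rm = TRUE), "`paco2` must be positive.")
  abort_if(any(etco2 < 0, na.rm = TRUE), "`etco2` must be non-negative.")
  raw <- (paco2 - etco2) / paco2
  out <- clip(raw, 0, 1)
  attr(out, "clipped") <- !is.na(raw) & (raw < 0 | raw > 1)
  out
}

#' Intermediate gas-exchange reward
#'
#' Rewards improvement between consecutive measurements:
#' `w_pf * clip(dpf / s_pf) - w_vd * clip(dvdvt / s_vd)` where `dpf` and
#' `dvdvt` are the changes (next minus current) in P/F ratio and dead-space
#' fraction. A missing value on either side makes that component contribute
#' zero (recorded in the validity flags) rather than imputing gas exchange.
#'
#' @param pf,pf_next P/F ratio at the current and next step (mmHg; may be NA).
#' @param vdvt,vdvt_next Dead-space fraction at the current and next step.
#' @param cfg A [reward_config()].
#' @returns A tibble with columns `reward`, `pf_valid`, `vd_valid`.
#' @examples
#' intermediate_reward(150, 200, 0.3, 0.3, reward_config()) # +1 from P/F
#' @export
intermediate_reward <- function(pf, pf_next, vdvt, vdvt_next,
                                cfg = reward_config()) {
  n <- max(length(pf), length(pf_next), length(vdvt), length(vdvt_next))
  pf <- rep_len(pf, n); pf_next <- rep_len(pf_next, n)
  vdvt <- rep_len(vdvt, n); vdvt_next <- rep_len(vdvt_next, n)

  pf_valid <- !is.na(pf) & !is.na(pf_next)
  vd_valid <- !is.na(vdvt) & !is.na(vdvt_next)

  dpf <- ifelse(pf_valid, pf_next - pf, 0)
  dvd <- ifelse(vd_valid, vdvt_next - vdvt, 0)

  r <- cfg$w_pf * clip(dpf / cfg$s_pf, -cfg$clip, cfg$clip) -
    cfg$w_vd * clip(dvd / cfg$s_vd, -cfg$clip, cfg$clip)
  tibble::tibble(reward = r, pf_valid = pf_valid, vd_valid = vd_valid)
}

#' Terminal outcome reward
#'
#' `-r_death` for ICU death; for survivors,
#' `r_survive * dest_multiplier[destination] - c_los * los_h`.
#'
#' @param died Logical.
#' @param los_h ICU length of stay in hours.
#' @param destination Discharge destination (ignored for deaths); must be a
#'   name of `cfg$dest_multiplier`.
#' @param cfg A [reward_config()].
#' @returns Numeric terminal rewards.
#' @export
terminal_reward <- function(died, los_h, destination, cfg = reward_config()) {
  n <- max(length(died), length(los_h), length(destination))
  died <- rep_len(as.logical(died), n)
  los_h <- rep_len(as.numeric(los_h), n)
  destination <- rep_len(as.character(destination), n)

  surv <- !died
  unknown <- surv & !(destination %in% names(cfg$dest_multiplier))
  abort_if(any(unknown),
           sprintf("Unknown discharge destination(s): %s. Valid: %s.",
                   paste(unique(destination[unknown]), collapse = ", "),
                   paste(names(cfg$dest_multiplier), collapse = ", ")),
           class = "ventrl_destination_error")

  out <- numeric(n)
  out[died] <- -cfg$r_death
  out[surv] <- cfg$r_survive * cfg$dest_multiplier[destination[surv]] -
    cfg$c_los * los_h[surv]
  unname(out)
}

#' Shape a trajectory's reward sequence
#'
#' Produces the per-step rewards `r_1..r_T` for one trajectory: the
#' intermediate gas-exchange reward at every step with a next measurement,
#' plus `lambda` times the terminal outcome reward added at the final step.
#'
#' @param traj An `icu_trajectory` (see [build_trajectories()]).
#' @param cfg A [reward_config()].
#' @returns A tibble with columns `step`, `reward`, `pf_valid`, `vd_valid`,
#'   `terminal` (logical, TRUE at the last step only).
#' @export
shape_trajectory_rewards <- function(traj, cfg = reward_config()) {
  stopifnot(inherits(traj, "icu_trajectory"))
  T_len <- traj$T
  gas <- traj$gas
  if (T_len > 1) {
    inter <- intermediate_reward(gas$pf[-T_len], gas$pf[-1],
                                 gas$vdvt[-T_len], gas$vdvt[-1], cfg)
  } else {
    inter <- tibble::tibble(reward = numeric(0), pf_valid = logical(0),
                            vd_valid = logical(0))
  }
  term <- terminal_reward(traj$outcome$died, traj$outcome$los_h,
                          traj$outcome$discharge_destination, cfg)
  tibble::tibble(
    step = seq_len(T_len),
    reward = c(inter$reward, cfg$lambda * term),
    pf_valid = c(inter$pf_valid, FALSE),
    vd_valid = c(inter$vd_valid, FALSE),
    terminal = seq_len(T_len) == T_len
  )
}

#' Shape rewards for a whole cohort under several reward versions
#'
#' @param trajectories List of `icu_trajectory` objects.
#' @param versions Named list of [reward_config()]s, e.g.
#'   [reward_version_grid()].
#' @returns A tibble keyed by `patient_id`, `version`, `step` with the shaped
#'   rewards.
#' @export
shape_cohort_rewards <- function(trajectories,
                                 versions = reward_version_grid()) {
  purrr::map_dfr(names(versions), function(v) {
    purrr::map_dfr(trajectories, function(tr) {
      out <- shape_trajectory_rewards(tr, versions[[v]])
      out$patient_id <- tr$patient_id
      out$version <- v
      out
    })
  }) |>
    dplyr::select(dplyr::all_of(c("patient_id", "version", "step", "reward",
                                  "pf_valid", "vd_valid", "terminal")))
}
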