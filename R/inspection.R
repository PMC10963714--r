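#' Delta-Q records for a trajectory set
#'
#' Delta-Q compares the quality the model assigns to the policy's
#' recommendation with the quality of the physician's historical action:
#' `delta_q = Q(s, policy action) - Q(s, physician action)`. Zero means
#' agreement; positive values mean the model predicts its own action is
#' better; a restricted policy can produce negative values when the
#' physician's (or global best) action lies outside the safety mask.
#'
#' @param model A `q_model`.
#' @param policy A `ventrl_policy` (queried with the physician's previous
#'   action as context).
#' @param trajectories A `trajectory_set` (or single `icu_trajectory`).
#' @returns A tibble of delta-Q records: `patient_id`, `time_h`,
#'   `physician_action`, `policy_action`, `q_physician`, `q_policy`,
#'   `delta_q`.
#' @export
delta_q_records <- function(model, policy, trajectories) {
  if (inherits(trajectories, "icu_trajectory")) {
    trajectories <- list(trajectories)
  }
  purrr::map_dfr(trajectories, function(tr) {
    Q <- q_values(model, tr$states)
    prev <- c(NA, tr$actions[-tr$T])
    pol_a <- vapply(seq_len(tr$T), function(t) {
      policy_action(policy, tr$states[t, ], prev[t])
    }, integer(1))
    idx <- seq_len(tr$T)
    tibble::tibble(
      patient_id = tr$patient_id,
      time_h = idx - 1,
      physician_action = tr$actions,
      policy_action = pol_a,
      q_physician = Q[cbind(idx, tr$actions)],
      q_policy = Q[cbind(idx, pol_a)],
      delta_q = q_policy - q_physician,
      died = tr$outcome$died
    )
  })
}

#' Aggregate Q and delta-Q surfaces over the action grid
#'
#' Per physician-action cell: the record count, mean physician Q, mean
#' policy Q and mean delta-Q. Cells with no records are reported with
#' `NA` means, never zero. The count-weighted mean of the cell delta-Q
#' means equals the overall mean delta-Q.
#'
#' @param records Delta-Q records from [delta_q_records()].
#' @param grid The [action_grid()] (for labels and coordinates).
#' @returns An `action_surface` tibble: one row per action with `count`,
#'   `mean_q_physician`, `mean_q_policy`, `mean_delta_q`.
#' @export
aggregate_surfaces <- function(records, grid = action_grid()) {
  tab <- action_table(grid)
  agg <- records |>
    dplyr::group_by(action = .data$physician_action) |>
    dplyr::summarise(count = dplyr::n(),
                     mean_q_physician = mean(.data$q_physician),
                     mean_q_policy = mean(.data$q_policy),
                     mean_delta_q = mean(.data$delta_q),
                     .groups = "drop")
  out <- dplyr::left_join(tab, agg, by = "action")
  out$count[is.na(out$count)] <- 0L
  class(out) <- c("action_surface", class(out))
  out
}

#' Q-value histograms per action
#'
#' For each action, the distribution of `Q(s, a)` over every state in the
#' dataset (all state-action pairs as encountered), tabulated on a common
#' set of bins. Useful for spotting systematic biases against individual
#' actions.
#'
#' @param model A `q_model`.
#' @param trajectories A `trajectory_set`.
#' @param bins Number of histogram bins (shared across actions).
#' @param grid The [action_grid()] for labels.
#' @returns Tibble with `action`, `label`, `bin_mid`, `count`, plus per-action
#'   `mean_q` repeated on each row.
#' @export
q_distribution_per_action <- function(model, trajectories, bins = 30,
                                      grid = action_grid()) {
  states <- do.call(rbind, lapply(trajectories, `[[`, "states"))
  Q <- q_values(model, states)
  rng <- range(Q)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  tab <- action_table(grid)
  purrr::map_dfr(seq_len(ncol(Q)), function(a) {
    cnt <- graphics::hist(Q[, a], breaks = edges, plot = FALSE)$counts
    tibble::tibble(action = a, label = tab$label[a], bin_mid = mids,
                   count = cnt, mean_q = mean(Q[, a]))
  })
}

#' Action counts by outcome stratum
#'
#' Counts physician and policy actions separately for survivors and
#' non-survivors: the four heatmap panels comparing historical practice
#' with the learned policy across outcomes.
#'
#' @param records Delta-Q records from [delta_q_records()] (they carry the
#'   physician action, policy action and outcome per step).
#' @param grid The [action_grid()] for labels.
#' @returns Tibble with `outcome` (`"survivor"/"non_survivor"`), `source`
#'   (`"physician"/"policy"`), `action`, `label`, `count`.
#' @export
action_distribution_by_outcome <- function(records, grid = action_grid()) {
  tab <- action_table(grid)
  strata <- tidyr::expand_grid(
    outcome = c("survivor", "non_survivor"),
    source = c("physician", "policy")
  )
  purrr::pmap_dfr(strata, function(outcome, source) {
    sub <- records[records$died == (outcome == "non_survivor"), ]
    acts <- if (source == "physician") sub$physician_action else
      sub$policy_action
    tibble::tibble(outcome = outcome, source = source,
                   action = seq_len(grid$n_actions),
                   label = tab$label,
                   count = tabulate(acts, nbins = grid$n_actions))
  })
}

#' Per-trajectory delta-Q series with signed log transform
#'
#' One record per hour of a single admission with
#' `log_delta_q = sign(delta_q) * log(1 + |delta_q| / sigma)` — a monotone,
#' odd transform that compresses large discrepancies while preserving sign
#' and zero, suitable for colour scales on trajectory visualisations.
#'
#' @param model A `q_model`.
#' @param policy A `ventrl_policy`.
#' @param trajectory A single `icu_trajectory`.
#' @param sigma Positive scale; by default the standard deviation of the
#'   trajectory's delta-Q (1 if degenerate).
#' @returns The delta-Q record tibble with `log_delta_q`, `peep_bin`,
#'   `fio2_bin` columns added.
#' @export
trajectory_series <- function(model, policy, trajectory, sigma = NULL) {
  rec <- delta_q_records(model, policy, trajectory)
  if (is.null(sigma)) {
    sigma <- stats::sd(rec$delta_q)
    if (!is.finite(sigma) || sigma == 0) sigma <- 1
  }
  assert_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  rec$log_delta_q <- sign(rec$delta_q) * log1p(abs(rec$delta_q) / sigma)
  rec
}

#' Delta-Q jump alerts
#'
#' Flags hours where delta-Q jumps away from its recent history: an alert
#' fires at time `t` when `|delta_q(t) - median(delta_q over the previous
#' window hours)| > tau`. Sudden jumps signal a change in state or physician
#' action worth clinical reassessment.
#'
#' @param series A per-trajectory record tibble (from [trajectory_series()]
#'   or [delta_q_records()] for one patient), ordered by time.
#' @param tau Positive jump threshold (`Inf` disables alerts).
#' @param window Number of preceding hours in the reference median
#'   (default 6).
#' @returns The alert rows of `series` with `reference_median` and `jump`
#'   columns; zero rows (with a warning) when the series is shorter than the
#'   window.
#' @export
clinical_alerts <- function(series, tau, window = 6) {
  assert_number(window, "window", lower = 1)
  abort_if(!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau <= 0,
           "`tau` must be a single positive number (Inf allowed).")
  n <- nrow(series)
  if (n <= window) {
    rlang::warn("Series shorter than the alert window; no alerts computed.")
    out <- series[0, ]
    out$reference_median <- numeric(0)
    out$jump <- numeric(0)
    return(out)
  }
  ref <- vapply((window + 1):n, function(t) {
    stats::median(series$delta_q[(t - window):(t - 1)])
  }, numeric(1))
  jump <- series$delta_q[(window + 1):n] - ref
  hit <- which(abs(jump) > tau)
  out <- series[window + hit, ]
  out$reference_median <- ref[hit]
  out$jump <- jump[hit]
  out
}
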