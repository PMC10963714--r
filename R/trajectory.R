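#' Feature schema
#'
#' Declares the state-space features built from the long-format event table:
#' one row per variable with its unit, carry-forward imputation limit
#' (hours; `Inf` for ventilator settings that persist until changed),
#' optional trailing aggregation windows (4, 6 or 24 h) with aggregation
#' operations (`last`, `mean`, `min`, `max`), and whether the feature is
#' z-scored. `last` uses the imputed hourly value itself; the other ops add
#' derived columns named `<variable>_w<window><op>`.
#'
#' @param variable Character vector of unique variable names (must match
#'   `variable` values of the event table).
#' @param unit Units, for documentation.
#' @param carry_forward_limit Hours an observation may be carried forward.
#' @param windows List column (one element per variable) of aggregation
#'   windows in hours, subset of `c(4, 6, 24)`; empty for none.
#' @param ops List column of aggregation ops, subset of
#'   `c("mean", "min", "max")` applied at each window.
#' @param normalization `"zscore"` or `"none"` per variable.
#' @param required Logical; counted in the missing-data exclusion filter.
#' @returns A `feature_schema` tibble.
#' @export
feature_schema <- function(variable, unit = "",
                           carry_forward_limit = 8,
                           windows = NULL, ops = NULL,
                           normalization = "zscore",
                           required = TRUE) {
  n <- length(variable)
  abort_if(anyDuplicated(variable) > 0, "`variable` names must be unique.")
  abort_if(any(carry_forward_limit <= 0), "`carry_forward_limit` must be > 0.")
  windows <- windows %||% rep(list(numeric(0)), n)
  ops <- ops %||% rep(list(character(0)), n)
  abort_if(!all(unlist(windows) %in% c(4, 6, 24)),
           "Aggregation windows must be among 4, 6, 24 hours.")
  abort_if(!all(unlist(ops) %in% c("mean", "min", "max")),
           "Aggregation ops must be among mean, min, max.")
  out <- tibble::tibble(
    variable = as.character(variable),
    unit = rep_len(unit, n),
    carry_forward_limit = rep_len(as.numeric(carry_forward_limit), n),
    windows = windows,
    ops = ops,
    normalization = rep_len(normalization, n),
    required = rep_len(required, n)
  )
  class(out) <- c("feature_schema", class(out))
  out
}

#' Default schema for the synthetic cohort
#'
#' Ventilator settings carry forward indefinitely (they persist until
#' changed); blood-gas labs carry 8 h; end-tidal CO2 (a continuous monitor
#' signal) 4 h; auxiliary channels 6 h. All numeric features are z-scored.
#'
#' @param n_aux_features Number of `aux_*` channels in the event table.
#' @returns A `feature_schema`.
#' @export
default_feature_schema <- function(n_aux_features = 16) {
  aux <- sprintf("aux_%02d", seq_len(n_aux_features))
  feature_schema(
    variable = c("peep", "fio2_pct", "ventilated", "pao2", "paco2", "etco2",
                 "toxmarker", aux),
    unit = c("cmH2O", "%", "flag", "mmHg", "mmHg", "mmHg", "au",
             rep("z", n_aux_features)),
    carry_forward_limit = c(Inf, Inf, Inf, 8, 8, 4, 8,
                            rep(6, n_aux_features)),
    normalization = c("zscore", "zscore", "none", "zscore", "zscore",
                      "zscore", "zscore", rep("zscore", n_aux_features)),
    required = c(rep(TRUE, 6), FALSE, rep(FALSE, n_aux_features))
  )
}

#' Carry-forward imputation onto an hourly grid
#'
#' Fills each hourly slot with the most recent observation no older than
#' `limit` hours; slots with no sufficiently recent observation stay
#' missing. The mask distinguishes directly observed slots (an observation
#' at that hour), imputed slots, and missing slots; imputation never
#' overwrites an observed value.
#'
#' @param time_h Observation times in hours (sorted, non-negative).
#' @param value Observed values.
#' @param hours Integer hourly slots to fill (default `0:max(time_h)`).
#' @param limit Maximum age in hours of a carried observation (> 0; may be
#'   `Inf`).
#' @returns A tibble with `time_h`, `value`, `status`
#'   (`"observed"/"imputed"/"missing"`).
#' @examples
#' carry_forward_impute(c(0, 3), c(5, 7), hours = 0:6, limit = 4)
#' @export
carry_forward_impute <- function(time_h, value, hours = NULL, limit = 8) {
  abort_if(is.unsorted(time_h), "`time_h` must be sorted increasingly.",
           class = "ventrl_unsorted_error")
  abort_if(!is.numeric(limit) || length(limit) != 1 || is.na(limit) ||
             limit <= 0, "`limit` must be a single positive number (Inf allowed).")
  if (is.null(hours)) {
    hours <- if (length(time_h)) 0:floor(max(time_h)) else integer(0)
  }
  if (length(time_h) == 0) {
    return(tibble::tibble(time_h = hours, value = NA_real_,
                          status = rep("missing", length(hours))))
  }
  idx <- findInterval(hours, time_h)
  val <- ifelse(idx >= 1, value[pmax(idx, 1)], NA_real_)
  age <- ifelse(idx >= 1, hours - time_h[pmax(idx, 1)], Inf)
  ok <- idx >= 1 & age <= limit
  status <- ifelse(!ok, "missing", ifelse(age == 0, "observed", "imputed"))
  tibble::tibble(time_h = hours,
                 value = ifelse(ok, val, NA_real_),
                 status = status)
}

rolling_op <- function(x, window, op) {
  f <- switch(op, mean = mean, min = min, max = max)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    xs <- x[max(1, i - window + 1):i]
    xs <- xs[!is.na(xs)]
    if (length(xs)) f(xs) else NA_real_
  }, numeric(1))
}

# per-patient raw feature matrix + status mask from long events
build_one_patient <- function(ev, schema, grid) {
  hours <- 0:floor(max(ev$time_h))
  Tn <- length(hours)
  base_cols <- list()
  status <- list()
  for (k in seq_len(nrow(schema))) {
    v <- schema$variable[k]
    sub <- ev[ev$variable == v, ]
    sub <- sub[order(sub$time_h), ]
    imp <- carry_forward_impute(sub$time_h, sub$value, hours = hours,
                                limit = schema$carry_forward_limit[k])
    base_cols[[v]] <- imp$value
    status[[v]] <- imp$status
    for (w in schema$windows[[k]]) {
      for (op in schema$ops[[k]]) {
        base_cols[[sprintf("%s_w%d%s", v, w, op)]] <-
          rolling_op(imp$value, w, op)
      }
    }
  }
  raw <- do.call(cbind, base_cols)
  rownames(raw) <- NULL
  mask <- do.call(cbind, status)
  colnames(mask) <- schema$variable

  vent <- base_cols[["ventilated"]]
  vent <- !is.na(vent) & vent > 0.5
  peep <- base_cols[["peep"]]
  fio2 <- base_cols[["fio2_pct"]]
  # ventilated hours with no setting ever observed cannot be binned
  settings_ok <- !vent | (!is.na(peep) & !is.na(fio2))
  abort_if(!all(settings_ok),
           "Ventilated hours without PEEP/FiO2 observations; check carry-forward limits.")
  actions <- bin_action(ifelse(vent, peep, 0),
                        ifelse(vent, fio2, min(grid$fio2_edges)),
                        vent, grid)

  fio2_frac <- ifelse(vent, fio2 / 100, 0.21)
  pf <- ifelse(!is.na(base_cols[["pao2"]]) & fio2_frac > 0,
               base_cols[["pao2"]] / fio2_frac, NA_real_)
  vd_ok <- !is.na(base_cols[["paco2"]]) & !is.na(base_cols[["etco2"]]) &
    base_cols[["paco2"]] > 0
  vdvt <- rep(NA_real_, Tn)
  if (any(vd_ok)) {
    vdvt[vd_ok] <- as.numeric(dead_space_fraction(base_cols[["paco2"]][vd_ok],
                                                  base_cols[["etco2"]][vd_ok]))
  }
  list(hours = hours, raw = raw, mask = mask, actions = actions,
       gas = tibble::tibble(time_h = hours, pf = pf, vdvt = vdvt))
}

#' Build MDP trajectories from long-format event tables
#'
#' Turns `(patient_id, time_h, variable, value)` events plus an outcomes
#' table into one trajectory per admission: an hourly grid from the first to
#' the last event, carry-forward-imputed features, schema aggregations,
#' binned PEEP x FiO2 actions (settings carried forward between changes),
#' derived gas-exchange series (P/F, Vd/Vt) for reward shaping, and the
#' terminal outcome. Remaining missing feature values after imputation are
#' set to zero on the normalised scale (population mean) so states are
#' complete.
#'
#' Normalisation statistics are computed from the supplied patients unless
#' `stats` is given (pass the training-split statistics via
#' [normalization_stats()] to avoid test leakage).
#'
#' @param events Event tibble (`patient_id`, `time_h`, `variable`, `value`).
#' @param outcomes Outcome tibble (`patient_id`, `died`, `los_h`,
#'   `discharge_destination`).
#' @param schema A [feature_schema()].
#' @param grid An [action_grid()].
#' @param stats Optional normalisation statistics from
#'   [normalization_stats()].
#' @returns A `trajectory_set`: list of `icu_trajectory` objects with
#'   attributes `schema`, `grid`, `stats`.
#' @export
build_trajectories <- function(events, outcomes, schema = NULL,
                               grid = action_grid(), stats = NULL) {
  schema <- schema %||% default_feature_schema(
    n_aux_features = sum(startsWith(unique(events$variable), "aux_")))
  pids <- unique(events$patient_id)
  missing_out <- setdiff(pids, outcomes$patient_id)
  abort_if(length(missing_out) > 0,
           sprintf("Patients missing from outcomes: %s",
                   paste(missing_out, collapse = ", ")),
           class = "ventrl_outcome_error")

  ev_split <- split(events, events$patient_id)
  built <- lapply(pids, function(pid) {
    build_one_patient(ev_split[[as.character(pid)]], schema, grid)
  })
  names(built) <- pids

  if (is.null(stats)) {
    allraw <- do.call(rbind, lapply(built, `[[`, "raw"))
    zs_cols <- normalized_columns(schema, colnames(allraw))
    mu <- colMeans(allraw, na.rm = TRUE)
    sd <- apply(allraw, 2, stats::sd, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    sd[!is.finite(sd) | sd == 0] <- 1 # degenerate variance guard
    mu[!zs_cols] <- 0
    sd[!zs_cols] <- 1
    stats <- tibble::tibble(feature = colnames(allraw),
                            mean = unname(mu), sd = unname(sd))
  }

  trajs <- lapply(seq_along(pids), function(i) {
    b <- built[[i]]
    pid <- pids[i]
    states <- sweep(sweep(b$raw, 2, stats$mean[match(colnames(b$raw),
                                                     stats$feature)]),
                    2, stats$sd[match(colnames(b$raw), stats$feature)], "/")
    states[is.na(states)] <- 0
    out_row <- outcomes[outcomes$patient_id == pid, ]
    structure(list(
      patient_id = pid,
      states = states,
      raw = b$raw,
      mask = b$mask,
      actions = b$actions,
      gas = b$gas,
      outcome = list(died = out_row$died[1], los_h = out_row$los_h[1],
                     discharge_destination = out_row$discharge_destination[1]),
      T = length(b$actions)
    ), class = "icu_trajectory")
  })
  structure(trajs, class = "trajectory_set",
            schema = schema, grid = grid, stats = stats)
}

normalized_columns <- function(schema, cols) {
  base <- sub("_w\\d+(mean|min|max)$", "", cols)
  schema$normalization[match(base, schema$variable)] == "zscore"
}

#' @export
print.icu_trajectory <- function(x, ...) {
  cat(sprintf("<icu_trajectory> patient %s: T=%d, %s\n", x$patient_id, x$T,
              if (x$outcome$died) "died" else
                paste0("survived (", x$outcome$discharge_destination, ")")))
  invisible(x)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d trajectories, %d features\n",
              length(x), ncol(x[[1]]$states)))
  invisible(x)
}

#' Normalisation statistics of a trajectory set
#'
#' @param trajectories A `trajectory_set`.
#' @returns Tibble with `feature`, `mean`, `sd`.
#' @export
normalization_stats <- function(trajectories) {
  attr(trajectories, "stats")
}

subset_trajectory_set <- function(trajectories, idx) {
  structure(trajectories[idx], class = "trajectory_set",
            schema = attr(trajectories, "schema"),
            grid = attr(trajectories, "grid"),
            stats = attr(trajectories, "stats"))
}

#' Exclude trajectories with excessive missing data
#'
#' Removes trajectories whose pre-imputation missing fraction — the fraction
#' of (hour, required-feature) cells without a direct observation at that
#' hour — exceeds the threshold.
#'
#' @param trajectories A `trajectory_set`.
#' @param max_missing_fraction Threshold in `[0, 1]`.
#' @returns List with `kept` (a `trajectory_set`) and `report` (tibble:
#'   `patient_id`, `missing_fraction`, `excluded`).
#' @export
exclude_low_quality <- function(trajectories, max_missing_fraction = 0.7) {
  assert_number(max_missing_fraction, "max_missing_fraction",
                lower = 0, upper = 1)
  schema <- attr(trajectories, "schema")
  req <- schema$variable[schema$required]
  frac <- vapply(trajectories, function(tr) {
    m <- tr$mask[, colnames(tr$mask) %in% req, drop = FALSE]
    mean(m != "observed")
  }, numeric(1))
  excluded <- frac > max_missing_fraction
  report <- tibble::tibble(
    patient_id = vapply(trajectories, function(tr) tr$patient_id, numeric(1)),
    missing_fraction = frac,
    excluded = excluded
  )
  list(kept = subset_trajectory_set(trajectories, !excluded), report = report)
}

#' Patient-level train/test split
#'
#' Seeded shuffle into disjoint train and test sets; the train size is
#' `round(n * train_fraction)`.
#'
#' @param trajectories A `trajectory_set`.
#' @param train_fraction Fraction in (0, 1) (default 0.7).
#' @param seed Integer seed.
#' @returns List with `train` and `test` trajectory sets.
#' @export
split_train_test <- function(trajectories, train_fraction = 0.7, seed = 1L) {
  assert_number(train_fraction, "train_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  n <- length(trajectories)
  abort_if(n < 2, "Need at least 2 trajectories to split.")
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- round(n * train_fraction)
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = subset_trajectory_set(trajectories, sort(perm[seq_len(n_train)])),
       test = subset_trajectory_set(trajectories, sort(perm[-seq_len(n_train)])))
}

#' Tidy a trajectory set
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @returns A long tibble: one row per patient, hour and feature, with the
#'   normalised value, imputation status, action and outcome.
#' @export
tidy.trajectory_set <- function(x, ...) {
  purrr::map_dfr(x, function(tr) {
    feats <- colnames(tr$states)
    tibble::tibble(
      patient_id = tr$patient_id,
      time_h = rep(tr$gas$time_h, length(feats)),
      feature = rep(feats, each = tr$T),
      value = as.vector(tr$states),
      action = rep(tr$actions, length(feats)),
      died = tr$outcome$died
    )
  })
}
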