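#' PEEP x FiO2 action grid
#'
#' The discrete action space for ventilator decision support: a lattice of
#' PEEP bins crossed with FiO2 bins, plus a single non-ventilated (NV) action
#' representing absence of invasive mechanical ventilation. The default grid
#' uses the clinical cut-offs PEEP 0-6, 6-10, 10-14, 14+ cmH2O and FiO2
#' 21-40, 40-60, 60-80, 80-100 %, giving 4 x 4 + 1 = 17 actions. Bins are
#' left-closed/right-open with the last bin closed, so the edges partition
#' the quarter-plane.
#'
#' Ventilated actions carry ordinal coordinates `(i_peep, i_fio2)` (0-based)
#' used by the king-knight restriction; the NV action is always the last
#' index.
#'
#' @param peep_edges Increasing PEEP bin edges in cmH2O; the last may be `Inf`.
#' @param fio2_edges Increasing FiO2 bin edges in percent.
#' @returns An `action_grid` object.
#' @examples
#' grid <- action_grid()
#' grid$n_actions # 17
#' action_table(grid)
#' @export
action_grid <- function(peep_edges = c(0, 6, 10, 14, Inf),
                        fio2_edges = c(21, 40, 60, 80, 100)) {
  abort_if(length(peep_edges) < 2 || any(diff(peep_edges) <= 0),
           "`peep_edges` must be strictly increasing with at least two values.")
  abort_if(length(fio2_edges) < 2 || any(diff(fio2_edges) <= 0),
           "`fio2_edges` must be strictly increasing with at least two values.")
  n_peep <- length(peep_edges) - 1L
  n_fio2 <- length(fio2_edges) - 1L
  structure(
    list(
      peep_edges = as.numeric(peep_edges),
      fio2_edges = as.numeric(fio2_edges),
      n_peep = n_peep,
      n_fio2 = n_fio2,
      n_actions = n_peep * n_fio2 + 1L,
      nv_index = n_peep * n_fio2 + 1L
    ),
    class = "action_grid"
  )
}

#' @export
print.action_grid <- function(x, ...) {
  cat(sprintf("<action_grid> %d x %d PEEP x FiO2 bins + NV = %d actions\n",
              x$n_peep, x$n_fio2, x$n_actions))
  invisible(x)
}

edge_label <- function(edges, i) {
  hi <- edges[i + 1]
  if (is.infinite(hi)) sprintf("%g+", edges[i]) else sprintf("%g-%g", edges[i], hi)
}

#' Tabulate an action grid
#'
#' One row per action with its ordinal coordinates (0-based, `NA` for the NV
#' action) and a human-readable label.
#'
#' @param grid An [action_grid()].
#' @returns A tibble with columns `action`, `i_peep`, `i_fio2`, `peep_bin`,
#'   `fio2_bin`, `label`.
#' @export
action_table <- function(grid) {
  stopifnot(inherits(grid, "action_grid"))
  vent <- tibble::tibble(
    action = seq_len(grid$n_peep * grid$n_fio2),
    i_peep = (action - 1L) %/% grid$n_fio2,
    i_fio2 = (action - 1L) %% grid$n_fio2
  )
  vent$peep_bin <- vapply(vent$i_peep + 1L, function(i) edge_label(grid$peep_edges, i), "")
  vent$fio2_bin <- vapply(vent$i_fio2 + 1L, function(i) edge_label(grid$fio2_edges, i), "")
  vent$label <- sprintf("PEEP %s, FiO2 %s", vent$peep_bin, vent$fio2_bin)
  dplyr::bind_rows(
    vent,
    tibble::tibble(action = grid$nv_index, i_peep = NA_integer_,
                   i_fio2 = NA_integer_, peep_bin = NA_character_,
                   fio2_bin = NA_character_, label = "NV")
  )
}

# ordinal coordinates of ventilated action indices (0-based); NV -> NA
action_coords <- function(action, grid) {
  vent <- action != grid$nv_index
  ip <- ifelse(vent, (action - 1L) %/% grid$n_fio2, NA_integer_)
  if2 <- ifelse(vent, (action - 1L) %% grid$n_fio2, NA_integer_)
  cbind(i_peep = ip, i_fio2 = if2)
}

coords_to_action <- function(i_peep, i_fio2, grid) {
  as.integer(i_peep * grid$n_fio2 + i_fio2 + 1L)
}

# Chebyshev distance on the ventilated lattice; NA if either action is NV
action_chebyshev <- function(a, b, grid) {
  ca <- action_coords(a, grid)
  cb <- action_coords(b, grid)
  pmax(abs(ca[, 1] - cb[, 1]), abs(ca[, 2] - cb[, 2]))
}

#' Map ventilator settings to action indices
#'
#' Bins PEEP and FiO2 into the grid's lattice; any time point without
#' invasive ventilation maps to the NV action regardless of the settings.
#' Bins are left-closed/right-open with the final bin closed. FiO2 supplied
#' as a fraction (values <= 1) is rescaled to percent; PEEP below zero is
#' clipped to zero.
#'
#' @param peep PEEP in cmH2O (vectorised).
#' @param fio2 FiO2 in percent (21-100) or as a fraction (0.21-1).
#' @param ventilated Logical; is the patient invasively ventilated?
#' @param grid An [action_grid()].
#' @returns Integer action indices.
#' @examples
#' grid <- action_grid()
#' bin_action(8, 50, TRUE, grid)   # PEEP 6-10, FiO2 40-60
#' bin_action(0, 0, FALSE, grid)   # NV
#' @export
bin_action <- function(peep, fio2, ventilated, grid = action_grid()) {
  n <- max(length(peep), length(fio2), length(ventilated))
  peep <- rep_len(as.numeric(peep), n)
  fio2 <- rep_len(as.numeric(fio2), n)
  ventilated <- rep_len(as.logical(ventilated), n)

  fio2 <- ifelse(!is.na(fio2) & fio2 <= 1, fio2 * 100, fio2)
  peep <- pmax(peep, 0)

  bad <- ventilated & (is.na(peep) | is.na(fio2) |
                         fio2 < min(grid$fio2_edges) - 1e-9 |
                         fio2 > max(grid$fio2_edges) + 1e-9)
  abort_if(any(bad),
           sprintf("%d ventilated rows have FiO2 outside [%g, %g] or missing settings; clean the data first.",
                   sum(bad), min(grid$fio2_edges), max(grid$fio2_edges)),
           class = "ventrl_bin_error")

  ip <- findInterval(peep, grid$peep_edges, rightmost.closed = TRUE) - 1L
  ip <- pmin(pmax(ip, 0L), grid$n_peep - 1L)
  if2 <- findInterval(fio2, grid$fio2_edges, rightmost.closed = TRUE) - 1L
  if2 <- pmin(pmax(if2, 0L), grid$n_fio2 - 1L)

  out <- coords_to_action(ip, if2, grid)
  out[!ventilated] <- grid$nv_index
  out
}

#' King-knight restriction configuration
#'
#' Parameters of the safety restriction: the Chebyshev radius on the
#' PEEP x FiO2 lattice within which the next recommendation must stay, and
#' the set of ventilated actions from which cessation of mechanical
#' ventilation (the NV action) may be recommended. From NV every action is
#' permissible. The default cessation set is the lowest PEEP bin crossed with
#' the two lowest FiO2 bins — low-support settings compatible with
#' extubation readiness.
#'
#' @param radius Chebyshev neighbourhood radius (the restriction uses 1).
#' @param nv_allowed_from Integer vector of ventilated action indices from
#'   which NV may be recommended, or `NULL` for the default low-support set.
#' @param grid An [action_grid()].
#' @returns A `restriction_config` object.
#' @export
restriction_config <- function(radius = 1L, nv_allowed_from = NULL,
                               grid = action_grid()) {
  assert_number(radius, "radius", lower = 0)
  if (is.null(nv_allowed_from)) {
    tab <- action_table(grid)
    tab <- tab[!is.na(tab$i_peep), ]
    nv_allowed_from <- tab$action[tab$i_peep == 0L & tab$i_fio2 <= 1L]
  }
  nv_allowed_from <- as.integer(nv_allowed_from)
  abort_if(any(nv_allowed_from >= grid$nv_index | nv_allowed_from < 1L),
           "`nv_allowed_from` must contain ventilated action indices only.")
  structure(list(radius = as.integer(radius),
                 nv_allowed_from = sort(unique(nv_allowed_from)),
                 grid = grid),
            class = "restriction_config")
}

#' Allowed actions under the king-knight restriction
#'
#' Given the previous action, returns the set of actions a restricted policy
#' may recommend next: from NV, all actions; from a ventilated action, every
#' ventilated action within Chebyshev distance `radius` (one step up or down
#' in PEEP and/or FiO2 by default), plus NV if and only if the previous
#' action is in the configured cessation set.
#'
#' @param previous_action Integer action index.
#' @param cfg A [restriction_config()].
#' @returns Sorted integer vector of allowed action indices.
#' @examples
#' cfg <- restriction_config()
#' king_knight_mask(action_grid()$nv_index, cfg)  # all 17
#' @export
king_knight_mask <- function(previous_action, cfg = restriction_config()) {
  grid <- cfg$grid
  previous_action <- as.integer(previous_action)
  abort_if(length(previous_action) != 1L || is.na(previous_action) ||
             previous_action < 1L || previous_action > grid$n_actions,
           "`previous_action` must be a single valid action index.")
  if (previous_action == grid$nv_index) {
    return(seq_len(grid$n_actions))
  }
  co <- action_coords(previous_action, grid)
  ip <- co[1, 1]; if2 <- co[1, 2]
  ips <- max(0L, ip - cfg$radius):min(grid$n_peep - 1L, ip + cfg$radius)
  if2s <- max(0L, if2 - cfg$radius):min(grid$n_fio2 - 1L, if2 + cfg$radius)
  allowed <- coords_to_action(rep(ips, each = length(if2s)),
                              rep(if2s, times = length(ips)), grid)
  if (previous_action %in% cfg$nv_allowed_from) {
    allowed <- c(allowed, grid$nv_index)
  }
  sort(unique(allowed))
}

#' Full mask table for audit
#'
#' Enumerates [king_knight_mask()] for every possible previous action.
#'
#' @param cfg A [restriction_config()].
#' @returns A tibble with columns `previous_action`, `previous_label`,
#'   `n_allowed`, `allowed` (list column of integer vectors).
#' @export
mask_table <- function(cfg = restriction_config()) {
  grid <- cfg$grid
  tab <- action_table(grid)
  masks <- lapply(seq_len(grid$n_actions), king_knight_mask, cfg = cfg)
  tibble::tibble(
    previous_action = seq_len(grid$n_actions),
    previous_label = tab$label,
    n_allowed = lengths(masks),
    allowed = masks
  )
}
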