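#' Experiment configuration
#'
#' Drives the end-to-end desk-scale experiment: cohort (simulated or
#' supplied), trajectory building, reward shaping across the lambda grid,
#' Q-network training across the architecture/hyperparameter grid, policy
#' derivation (greedy and king-knight per model), two-round cross-OPE
#' selection and top-N inspection.
#'
#' @param sim A [sim_config()], or `NULL` when `cohort` is supplied.
#' @param cohort Optional list with `events` and `outcomes` tibbles.
#' @param schema Optional [feature_schema()].
#' @param grid An [action_grid()].
#' @param lambdas Terminal-reward weightings (default the six study values).
#' @param model_grid Tibble of architectures (`n_hidden_layers`, `width`).
#' @param train_grid List of [train_config()] templates (their seeds are
#'   re-derived per model).
#' @param restriction A [restriction_config()].
#' @param knn List with `k` and `alpha_s` for the behaviour policy.
#' @param ope List of OPE settings: `gamma`, `J`, `n_bootstrap`, `ci_level`,
#'   `eps` (softening), `threshold`, `rank_rule`.
#' @param max_missing_fraction Exclusion threshold for low-quality stays.
#' @param train_fraction Train split fraction.
#' @param top_n Number of top policies in the inspection bundle.
#' @param seed Global seed; all per-model seeds derive from it.
#' @param out_dir Optional run directory for the manifest and exports.
#' @returns An `experiment_config`.
#' @export
experiment_config <- function(sim = NULL, cohort = NULL, schema = NULL,
                              grid = action_grid(),
                              lambdas = c(0.25, 0.5, 1, 2, 4, 8),
                              model_grid = tibble::tibble(
                                n_hidden_layers = c(3, 4),
                                width = c(64, 32)),
                              train_grid = list(
                                train_config(lr = 1e-3, lr_schedule = "step"),
                                train_config(lr = 3e-4, lr_schedule = "step"),
                                train_config(lr = 1e-3, lr_schedule = "plateau"),
                                train_config(lr = 3e-4, lr_schedule = "plateau")),
                              restriction = restriction_config(grid = grid),
                              knn = list(k = 100, alpha_s = 0.5),
                              ope = list(gamma = 0.99,
                                         J = c(0, 1, 2, 5, 10, 25, Inf),
                                         n_bootstrap = 200, ci_level = 0.9,
                                         eps = 0.01, threshold = 0,
                                         rank_rule = "min"),
                              max_missing_fraction = 0.7,
                              train_fraction = 0.7, top_n = 100,
                              seed = 1L, out_dir = NULL) {
  abort_if(is.null(sim) && is.null(cohort),
           "Provide either `sim` or a `cohort`.")
  abort_if(nrow(model_grid) == 0, "`model_grid` must have at least one row.")
  abort_if(length(train_grid) == 0, "`train_grid` must not be empty.")
  abort_if(any(lambdas <= 0), "`lambdas` must be positive.")
  structure(list(sim = sim, cohort = cohort, schema = schema, grid = grid,
                 lambdas = lambdas, model_grid = model_grid,
                 train_grid = train_grid, restriction = restriction,
                 knn = knn, ope = ope,
                 max_missing_fraction = max_missing_fraction,
                 train_fraction = train_fraction, top_n = top_n,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

config_digest <- function(cfg) {
  stripped <- cfg[setdiff(names(cfg), "out_dir")]
  rlang::hash(stripped)
}

#' Run the end-to-end experiment
#'
#' Simulate/load -> build trajectories -> exclude low quality -> split ->
#' shape rewards per lambda -> train the model grid -> derive two policies
#' per model -> round-1 OPE -> cross-OPE -> rank -> top-N inspection bundle.
#' Deterministic given the config seed. When `out_dir` holds a manifest of a
#' completed run with the same configuration, it is reloaded instead of
#' recomputed; a manifest from a *different* configuration is refused.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-stage progress.
#' @returns A `run_manifest`: list with `models`, `policies`, `cross`
#'   (the [cross_ope()] matrix), `summary`, `counts`, `inspection` and
#'   `config_digest`.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  digest <- config_digest(cfg)
  manifest_path <- if (!is.null(cfg$out_dir)) {
    file.path(cfg$out_dir, "manifest.rds")
  }
  if (!is.null(manifest_path) && file.exists(manifest_path)) {
    prev <- readRDS(manifest_path)
    abort_if(prev$config_digest != digest,
             sprintf("Run directory holds a manifest for a different configuration (%s vs %s); use a fresh directory.",
                     prev$config_digest, digest),
             class = "ventrl_resume_conflict")
    return(prev)
  }
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- cfg$cohort %||% simulate_cohort(cfg$sim)
  say("cohort: %d patients", nrow(cohort$outcomes))

  trajs <- build_trajectories(cohort$events, cohort$outcomes,
                              schema = cfg$schema, grid = cfg$grid)
  excl <- exclude_low_quality(trajs, cfg$max_missing_fraction)
  split <- split_train_test(excl$kept, cfg$train_fraction,
                            seed = derive_seed(cfg$seed, "split"))
  # freeze training-set normalisation statistics on both splits
  train_stats <- local({
    raw <- dplyr::bind_rows(lapply(split$train, function(tr) {
      tibble::as_tibble(tr$raw)
    }))
    sds <- vapply(raw, function(x) stats::sd(x, na.rm = TRUE), numeric(1))
    mus <- vapply(raw, function(x) mean(x, na.rm = TRUE), numeric(1))
    sds[!is.finite(sds) | sds == 0] <- 1
    mus[!is.finite(mus)] <- 0
    zs <- normalized_columns(attr(trajs, "schema"), names(raw))
    mus[!zs] <- 0
    sds[!zs] <- 1
    tibble::tibble(feature = names(raw), mean = mus, sd = sds)
  })
  renorm <- function(set) {
    out <- lapply(set, function(tr) {
      states <- sweep(sweep(tr$raw, 2,
                            train_stats$mean[match(colnames(tr$raw),
                                                   train_stats$feature)]),
                      2, train_stats$sd[match(colnames(tr$raw),
                                              train_stats$feature)], "/")
      states[is.na(states)] <- 0
      tr$states <- states
      tr
    })
    structure(out, class = "trajectory_set", schema = attr(set, "schema"),
              grid = attr(set, "grid"), stats = train_stats)
  }
  train <- renorm(split$train)
  test <- renorm(split$test)
  say("split: %d train / %d test (of %d kept)", length(train), length(test),
      length(excl$kept))

  versions <- reward_version_grid(cfg$lambdas)
  train_rewards <- lapply(versions, function(rc) {
    shape_cohort_rewards(train, versions = list(v = rc))
  })

  spec_dim <- ncol(train[[1]]$states)
  model_rows <- list()
  candidates <- list()
  model_i <- 0L
  for (ai in seq_len(nrow(cfg$model_grid))) {
    for (hi in seq_along(cfg$train_grid)) {
      for (v in names(versions)) {
        model_i <- model_i + 1L
        model_id <- sprintf("m%03d_a%d_h%d_%s", model_i, ai, hi, v)
        spec <- qnetwork_spec(input_dim = spec_dim,
                              n_hidden_layers = cfg$model_grid$n_hidden_layers[ai],
                              width = cfg$model_grid$width[ai],
                              n_actions = cfg$grid$n_actions)
        tc <- cfg$train_grid[[hi]]
        tc$seed <- derive_seed(cfg$seed, "train", model_i)
        model <- train_q(train, train_rewards[[v]], spec = spec, cfg = tc,
                         reward_version = v)
        say("trained %s (final loss %.4g)", model_id,
            mean(utils::tail(model$loss_trace, 50)))
        model_rows[[model_i]] <- dplyr::mutate(glance(model),
                                               model_id = model_id,
                                               arch = ai, hyper = hi,
                                               seed = tc$seed)
        for (kind in c("greedy", "king_knight")) {
          pol <- if (kind == "greedy") greedy_policy(model) else
            restricted_policy(model, cfg$restriction)
          candidates[[length(candidates) + 1L]] <- list(
            id = paste0(model_id, "_", kind),
            policy = soften(pol, cfg$ope$eps),
            model = model, reward_version = v, kind = kind,
            model_id = model_id)
        }
      }
    }
  }

  train_states <- do.call(rbind, lapply(train, `[[`, "states"))
  train_actions <- unlist(lapply(train, `[[`, "actions"))
  k_eff <- min(cfg$knn$k, nrow(train_states))
  behaviour <- knn_behaviour_policy(train_states, train_actions,
                                    k = k_eff, alpha_s = cfg$knn$alpha_s,
                                    n_actions = cfg$grid$n_actions)

  say("cross-OPE over %d candidates x %d versions", length(candidates),
      length(versions))
  cross <- cross_ope(candidates, test, behaviour, versions = versions,
                     gamma = cfg$ope$gamma, threshold = cfg$ope$threshold,
                     rank_rule = cfg$ope$rank_rule, J = cfg$ope$J,
                     n_bootstrap = cfg$ope$n_bootstrap,
                     ci_level = cfg$ope$ci_level,
                     seed = derive_seed(cfg$seed, "ope"))
  summ <- glance(cross)

  policies <- tibble::tibble(
    policy_id = vapply(candidates, `[[`, "", "id"),
    model_id = vapply(candidates, `[[`, "", "model_id"),
    kind = vapply(candidates, `[[`, "", "kind"),
    reward_version = vapply(candidates, `[[`, "", "reward_version"))

  top_ids <- summ$policy_id[order(summ$final_rank)][
    seq_len(min(cfg$top_n, sum(!is.na(summ$final_rank))))]
  inspection <- lapply(top_ids, function(pid) {
    cand <- candidates[[match(pid, vapply(candidates, `[[`, "", "id"))]]
    rec <- delta_q_records(cand$model, cand$policy, test)
    list(policy_id = pid,
         records = rec,
         surface = aggregate_surfaces(rec, cfg$grid),
         by_outcome = action_distribution_by_outcome(rec, cfg$grid))
  })
  names(inspection) <- top_ids

  manifest <- structure(list(
    config_digest = digest,
    n_models = model_i,
    n_policies = length(candidates),
    models = dplyr::bind_rows(model_rows),
    policies = policies,
    cross = cross,
    summary = summ,
    counts = list(
      n_models = model_i,
      n_policies = length(candidates),
      n_round1_pass = sum(summ$round1_pass),
      n_round2_pass = sum(summ$round2_pass, na.rm = TRUE)),
    inspection = inspection,
    exclusion_report = excl$report,
    seed = cfg$seed
  ), class = "run_manifest")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(manifest, manifest_path)
    utils::write.csv(cross, file.path(cfg$out_dir, "cross_ope.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest$counts,
                         file.path(cfg$out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d models, %d policies; round 1 pass %d, round 2 pass %d\n",
              x$counts$n_models, x$counts$n_policies,
              x$counts$n_round1_pass, x$counts$n_round2_pass))
  invisible(x)
}

#' Manifest stub from headline counts
#'
#' Builds a minimal `run_manifest` from externally known counts so the
#' report arithmetic can be exercised or audited without a full run.
#'
#' @param n_models Number of trained models.
#' @param n_round1_pass Policies passing round 1.
#' @param n_round2_pass Policies passing round 2.
#' @param n_policies Number of evaluated policies (two per model).
#' @returns A `run_manifest` with `counts` only.
#' @export
manifest_stub <- function(n_models, n_round1_pass, n_round2_pass,
                          n_policies = 2 * n_models) {
  structure(list(
    config_digest = NA_character_,
    n_models = n_models,
    n_policies = n_policies,
    counts = list(n_models = n_models, n_policies = n_policies,
                  n_round1_pass = n_round1_pass,
                  n_round2_pass = n_round2_pass)
  ), class = "run_manifest")
}

#' Summarise a run
#'
#' Recomputes the headline arithmetic from the manifest's raw counts:
#' evaluated policies (two per model), round-1 and round-2 pass counts and
#' percentages, plus — for full manifests — the relative-value histogram
#' tables by reward version and round, and the top-N listing.
#'
#' @param manifest A `run_manifest` (full or [manifest_stub()]).
#' @param top_n Rows in the top listing.
#' @returns A `run_report`: list with `counts` (tibble) and, when available,
#'   `histograms` and `top`.
#' @export
report <- function(manifest, top_n = 100) {
  stopifnot(inherits(manifest, "run_manifest"))
  cn <- manifest$counts
  counts <- tibble::tibble(
    n_models = cn$n_models,
    n_policies = cn$n_policies,
    policies_per_model = cn$n_policies / cn$n_models,
    n_round1_pass = cn$n_round1_pass,
    round1_pass_pct = 100 * cn$n_round1_pass / cn$n_policies,
    n_round2_pass = cn$n_round2_pass,
    round2_pass_pct = 100 * cn$n_round2_pass / cn$n_round1_pass,
    round2_fail_pct = 100 * (cn$n_round1_pass - cn$n_round2_pass) /
      cn$n_round1_pass
  )
  out <- list(counts = counts, complete = !is.null(manifest$cross))
  if (!is.null(manifest$cross)) {
    out$histograms <- manifest$cross |>
      dplyr::group_by(.data$eval_version, .data$round) |>
      dplyr::summarise(n = dplyr::n(),
                       mean_relative = mean(.data$relative_value),
                       sd_relative = stats::sd(.data$relative_value),
                       frac_positive = mean(.data$relative_value > 0),
                       .groups = "drop")
    out$relative_values <- manifest$cross[
      , c("policy_id", "eval_version", "round", "relative_value")]
    summ <- manifest$summary
    ranked <- summ[!is.na(summ$final_rank), ]
    ranked <- ranked[order(ranked$final_rank), ]
    out$top <- utils::head(ranked, top_n)
  }
  structure(out, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cn <- x$counts
  cat(sprintf("<run_report> %s models -> %s policies (%g per model)\n",
              format(cn$n_models, big.mark = ","),
              format(cn$n_policies, big.mark = ","),
              cn$policies_per_model))
  cat(sprintf("  round 1: %s passed (%.1f%% of policies)\n",
              format(cn$n_round1_pass, big.mark = ","), cn$round1_pass_pct))
  cat(sprintf("  round 2: %s passed (%.0f%% of round-1 passers; %.0f%% failed)\n",
              format(cn$n_round2_pass, big.mark = ","), cn$round2_pass_pct,
              cn$round2_fail_pct))
  if (!isTRUE(x$complete)) cat("  (partial report: counts only)\n")
  invisible(x)
}
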