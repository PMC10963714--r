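# ventrl

Safe offline reinforcement learning for ICU ventilator settings.

Intensive-care patients on mechanical ventilation generate hourly decisions
about two settings clinicians always control: positive end-expiratory
pressure (PEEP) and the inspired oxygen fraction (FiO2). ventrl is an R
implementation of an offline-RL pipeline for this problem, aimed at
methods researchers in clinical machine learning: it learns ventilator
policies from logged ICU data and — because naively trained offline
policies are unsafe to trust — puts its emphasis on the evaluation side:
restricting recommendations to clinically plausible moves, estimating
policy value without ever executing a policy, stress-testing policies
against alternative reward formulations, and making individual
recommendations inspectable.

The pipeline:

* **Trajectories** — long-format event tables become hourly state vectors
  via carry-forward imputation with per-variable clinical cut-offs,
  optional trailing-window aggregations, and train-split z-scoring; PEEP
  and FiO2 are binned into a 4 x 4 lattice plus a non-ventilated (NV)
  action (17 actions).
* **Reward** — per-hour gas-exchange improvement (change in P/F ratio
  PaO2/FiO2 and in the Enghoff–Bohr dead-space fraction
  (PaCO2 − ETCO2)/PaCO2, scaled and clipped), plus a terminal component
  combining ICU mortality, length of stay and discharge destination,
  weighted by a factor λ varied over the grid {0.25, 0.5, 1, 2, 4, 8}
  (reward versions v1..v6).
* **Agent** — a dueling double deep Q-network,
  Q(s,a) = V(s) + A(s,a) − mean A(s,·), trained offline with prioritised
  experience replay, double-Q targets, AdamW and feasible-return target
  clipping; implemented natively in vectorised R, bit-reproducible per
  seed.
* **Policies** — greedy argmax, and the "king-knight" restriction: at most
  one lattice step in PEEP and/or FiO2 per hour, ventilation stop only
  from low-support settings, free choice when not ventilated. The
  physician behaviour policy is a smoothed exact k-NN estimate.
* **Off-policy evaluation** — per-decision weighted importance sampling
  (PDWIS), weighted doubly robust (WDR), and MAGIC, which blends
  partial-horizon doubly robust returns g^(j) with simplex weights
  minimising estimated bias² + variance (exact active-set QP, percentile
  bootstrap CIs).
* **Cross-OPE** — two-round selection: a policy trained under one reward
  version must first beat the behaviour policy under its own version, then
  under all five alternative weightings; survivors are ranked by their
  minimum relative value.
* **Inspection** — delta-Q = Q(s, policy action) − Q(s, physician action),
  aggregate action-surface and per-action Q-distribution tables,
  outcome-stratified action heatmaps, per-trajectory signed-log delta-Q
  series and jump alerts.

The real cohort behind this class of study is access-restricted, so the
package ships a seeded synthetic ICU simulator with the statistical
structure the pipeline assumes (hourly steps, realistic missingness,
physician actions concentrated near their previous action, an inverted-U
PEEP response, ICU mortality calibrated to 24.4%), plus a designed
"conflict" configuration in which chasing short-term oxygenation gains
costs lives — the test bed on which cross-OPE demonstrably unmasks
reward-hacking policies.

## Worked example

```r
library(ventrl)

# simulate a small cohort and build trajectories
coh   <- simulate_cohort(sim_config(n_patients = 60, seed = 7, n_aux_features = 4))
mean(coh$outcomes$died)
#> [1] 0.2666667
trajs <- build_trajectories(coh$events, coh$outcomes)
trajs
#> <trajectory_set> 60 trajectories, 11 features
sp <- split_train_test(trajs, 0.7, seed = 1)

# shape rewards (version v3, lambda = 1) and train an agent
rw  <- shape_cohort_rewards(sp$train, reward_version_grid()["v3"])
mod <- train_q(sp$train, rw,
               spec = qnetwork_spec(ncol(sp$train[[1]]$states), 3, 32, 17),
               cfg  = train_config(n_updates = 1000, seed = 2),
               reward_version = "v3")

# king-knight policy, behaviour policy, MAGIC off-policy estimate
kk <- restricted_policy(mod)
st <- do.call(rbind, lapply(sp$train, `[[`, "states"))
bp <- knn_behaviour_policy(st, unlist(lapply(sp$train, `[[`, "actions")), k = 50)
rwt <- shape_cohort_rewards(sp$test, reward_version_grid()["v3"])
ds  <- make_ope_dataset(sp$test, dplyr::select(rwt, -version), bp,
                        soften(kk, 0.01), mod)
magic_estimate(ds, gamma = 0.99, seed = 3)
#> <ope_result> MAGIC: 7.7242 (behaviour 1.5497, relative +6.1745)
#>   90% bootstrap CI [7.0035, 8.4027]

# delta-Q inspection by physician-action cell
rec <- delta_q_records(mod, kk, sp$test)
aggregate_surfaces(rec)[c(6, 7, 10, 11), c("label", "count", "mean_delta_q")]
#>   label                  count mean_delta_q
#> 1 PEEP 6-10, FiO2 40-60     25        0.984
#> 2 PEEP 6-10, FiO2 60-80     31        1.38
#> 3 PEEP 10-14, FiO2 40-60    33        1.63
#> 4 PEEP 10-14, FiO2 60-80    41        0.865
```

The MAGIC relative value (+6.17) is the model-led estimate of how much the
restricted policy would improve on historical practice *under the model's
own reward version* — round 1 of the selection. This untrained-to-convergence
toy model illustrates exactly why round 1 alone is not trusted: the Q-network
is optimistic, so the positive delta-Q means of well-populated cells must be
read together with the cross-OPE screen (`cross_ope()`) and the per-action
Q distributions before a policy is taken seriously. The full two-round
experiment at desk scale is one call: `run_experiment(experiment_config(...))`,
and `crossope_discrimination_experiment()` reproduces the reward-hacking
demonstration.

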