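---
title: "Safe offline reinforcement learning for ventilator settings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe offline reinforcement learning for ventilator settings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ventrl is an offline reinforcement-learning pipeline for ICU ventilator
decision support. From long-format event tables it builds hourly patient
trajectories, shapes a clinical reward, trains dueling double deep
Q-networks on the logged data, restricts the learned policies to clinically
safe moves, estimates their value against the physicians' historical policy
with off-policy estimators, screens them for reward-shaping robustness, and
inspects the survivors with the delta-Q metric. This vignette explains the
models behind each stage, the parameters that matter, the numerical
safeguards, and what the bundled synthetic cohort can and cannot show.

## The decision problem

Each ICU admission is a trajectory: hourly state vectors $s_t$ (ventilator
settings, blood gases, monitor and laboratory channels, all carry-forward
imputed and z-scored), the physician's action $a_t$, and a terminal outcome
(death or discharge, with length of stay and destination). The action space
discretises the two settings clinicians always control — PEEP and FiO2 —
into a 4 x 4 lattice (PEEP 0–6, 6–10, 10–14, 14+ cmH2O; FiO2 21–40,
40–60, 60–80, 80–100 %) plus a single non-ventilated (NV) action, 17
actions in total. Bins are left-closed/right-open with the last bin closed,
so binning partitions the plane; the convention is recorded in
`action_table()`.

The reward has two separable components. Each hour, improvement in gas
exchange is rewarded through the changes in the P/F ratio
($\mathrm{PaO_2}/\mathrm{FiO_2}$) and in the Enghoff–Bohr dead-space
fraction $V_d/V_t = (\mathrm{PaCO_2} - \mathrm{ETCO_2})/\mathrm{PaCO_2}$:

$$r_t = w_{pf}\,\mathrm{clip}\!\left(\frac{\Delta pf}{s_{pf}}\right)
      - w_{vd}\,\mathrm{clip}\!\left(\frac{\Delta (V_d/V_t)}{s_{vd}}\right),$$

with scales $s_{pf} = 50$ mmHg and $s_{vd} = 0.1$ per unit reward and each
term clipped to $\pm 1$ so a single aberrant measurement cannot dominate a
stay. At the final step a terminal component is added with weight
$\lambda$: $-1$ for ICU death, and for survivors a destination multiplier
(home 1, rehabilitation 0.75, other hospital 0.5) minus a length-of-stay
penalty calibrated so a 14-day stay costs half the survival bonus. Missing
gas-exchange values contribute zero to that hour rather than being imputed
into the reward — rewarding imputation artefacts would be worse than
ignoring the hour — and validity flags record which hours contributed.

The weighting $\lambda$ is deliberately not a single number: the study grid
$\lambda \in \{0.25, 0.5, 1, 2, 4, 8\}$ (reward versions v1–v6) spans
intermediate-dominated to terminal-dominated formulations, and the
cross-evaluation below treats the grid, not any single member, as the
object of interest.

## Learning: dueling double DQN with prioritised replay

`train_q()` fits $Q(s, a)$ with a fully connected dueling network: a shared
ReLU trunk (3–5 layers of 32/64/128 units) and two heads combined as
$Q(s,a) = V(s) + A(s,a) - \bar A(s)$, which removes the additive
unidentifiability between state value and advantage. Targets use double
Q-learning — actions selected by the online network, evaluated by a
periodically synchronised target network — with argmax ties broken to the
lowest action index for determinism. Transitions are sampled with
prioritised replay, $P(i) \propto p_i^{\alpha}$ with $p_i = |\delta_i| +
\varepsilon$, and the induced bias is corrected with importance weights
$(N P(i))^{-\beta}$, $\beta$ annealed to 1. Optimisation is Adam with
gradient-norm clipping and a step-decay or reduce-on-plateau learning-rate
schedule. Everything is implemented natively in vectorised R; training is
single-threaded and bit-reproducible given the seed.

Offline Q-learning on logged clinical data sits squarely on the deadly
triad (bootstrapping, function approximation, off-policy data) and in early
experiments soft-diverged: argmax bootstrapping through actions the
physicians rarely took inflated Q without bound. Two standard safeguards
are therefore on by default and exposed in `train_config()`:

* **Target clipping** (`target_clip = "auto"`): bootstrapped targets are
  clipped to the empirical discounted-return range of the training
  episodes (20% margin). Targets outside the observed return support can
  only come from extrapolation. For raw transition lists whose episode
  boundaries are unknown the bound falls back to the loose geometric bound
  $\max|r| / (1-\gamma)$, which only guards divergence.
* **Decoupled weight decay** (`weight_decay = 1e-4`, AdamW-style), which
  shrinks the network's reach on rarely visited state–action pairs.

These are conservatism devices, not fixes: the learned Q remains optimistic
on out-of-distribution actions, which is precisely why the evaluation
stages below never take the model's word for it. The discount defaults to
$\gamma = 0.99$; for short-horizon experiments a discount matched to the
typical stay length (e.g. 0.95 over a few days) keeps the value scale
commensurate with realised returns.

## Policies and the king-knight restriction

`greedy_policy()` is the deterministic argmax over all 17 actions.
`restricted_policy()` implements the king-knight restriction: from a
ventilated action the policy may only move within Chebyshev distance 1 on
the (PEEP, FiO2) lattice — one step up or down in either or both settings,
like a king on a chessboard — may recommend stopping ventilation (NV) only
from the configured low-support actions (default: lowest PEEP bin with the
two lowest FiO2 bins, the region compatible with extubation readiness), and
is unrestricted when the patient is not ventilated. Mask cardinalities are
9/6/4 ventilated neighbours for interior/edge/corner actions; the full mask
table is exported by `mask_table()` for audit.

The physicians' behaviour policy is estimated with a smoothed k-nearest
neighbour rule on the z-scored states,
$\pi_b(a \mid s) = (c_a + \alpha_s)/(k + 17\alpha_s)$ with $k = 100$ and
$\alpha_s = 0.5$ by default; the smoothing keeps every action's probability
positive, which importance sampling requires. The search is exact and
chunked. Deterministic target policies are $\varepsilon$-softened
(`soften()`, mask-aware) before evaluation; recommendations shown to users
remain deterministic.

## Off-policy evaluation

The estimators follow the per-decision weighted importance-sampling family.
With cumulative ratios $\rho^i_t = \prod_{u \le t} \pi_e/\pi_b$, frozen at
termination and self-normalised across trajectories
($w^i_t = \rho^i_t / \sum_j \rho^j_t$), the partial-horizon doubly robust
return is

$$g^{(j)} = \sum_i \Big[ \sum_{t<j} \gamma^t w^i_t r^i_t
  + \gamma^j w^i_{j-1} \hat v(s^i_j)
  - \sum_{t<j} \gamma^t \big( w^i_t \hat q(s^i_t, a^i_t)
  - w^i_{t-1} \hat v(s^i_t) \big) \Big],$$

where $\hat q$ comes from the fitted Q-network and
$\hat v = \sum_a \pi_e(a|s)\hat q(s,a)$. $g^{(0)}$ is the pure model
estimate, $g^{(\infty)}$ the weighted doubly robust (WDR) estimator, and
$\hat q \equiv 0$ recovers plain PDWIS — an identity the tests verify
exactly. The MAGIC estimator blends a set of horizons $J$ with simplex
weights minimising $x^\top(\hat\Omega + b b^\top)x$, where $\hat\Omega$ is
the scaled covariance of per-trajectory contributions and $b_j$ is the
signed distance from $g^{(j)}$ to a percentile-bootstrap interval of
$g^{(\infty)}$. The QP is solved exactly by enumerating supports (at most
$2^{|J|}-1$ equality-constrained solves), verified in tests against a dense
grid search; the confidence interval bootstraps the blended estimate with
the weights held fixed (200 replicates, 90% percentile interval by
default).

On tabular problems with a dynamic-programming oracle, all three estimators
agree with the truth within Monte-Carlo error and the bootstrap interval
achieves nominal-minus-slack coverage; with a deliberately biased model the
bias proxy moves weight off the model head and halves the pure-model error.
Two caveats the user should know: MAGIC's bias detection is only as good as
the $g^{(\infty)}$ interval, so under severe weight degeneracy it will sit
on the lowest-variance (most model-like) horizon; and self-normalised
weights make all estimates implicitly relative to the trajectories that
resemble the target policy.

## Cross-OPE and the evaluation-design rules

Cross off-policy evaluation asks whether a policy trained under one reward
weighting still beats the behaviour policy when *evaluated* under the other
five. Round 1 evaluates each candidate under its own version; passers are
re-evaluated under the remaining versions and pass round 2 only if the
relative value stays positive everywhere; survivors are ranked by their
minimum (optionally mean) relative value across all versions.

Three design rules, applied by `cross_ope()`, came out of failure analysis
on the synthetic cohort and are worth stating because they change results
qualitatively:

1. **Control variates only under the training version.** A Q-network
   trained on version v estimates *that* reward's value; under another
   version its $\hat q$ is not merely uninformative but actively harmful —
   with degenerate weights the control-variate terms fail to cancel and
   contaminate even $g^{(\infty)}$, and MAGIC then reports the wrong
   reward's value for every version. Cross-version evaluations are
   therefore model-free.
2. **Horizons start at the stay length for cross-version evaluation.**
   Model-free truncated returns with $j$ below the typical stay cannot see
   the terminal outcome component that the alternative weightings
   emphasise, and since the shortest horizons also have the smallest
   variance, MAGIC's objective would otherwise collapse onto structurally
   blind one-step comparisons. Cross-version blends use the median stay
   length, twice it, and infinity.
3. **Horizon-matched relative values.** The behaviour policy's
   $g_b^{(j)}$ (same machinery; on-policy weights are exactly $1/n$) is
   blended with the *target's* optimal weights and subtracted. Whatever
   truncation bias the blend retains is then shared by both sides and
   cancels in the difference. The plain empirical behaviour value is still
   reported alongside.

## Policy inspection

Delta-Q is the model's own comparison of its recommendation with the
physician's historical choice,
$\Delta Q = Q(s, \pi(s, a_{prev})) - Q(s, a_{phys})$: zero means agreement,
positive means the model predicts improvement, and under the king-knight
restriction negative values flag hours where the clinical action lay
outside the safety mask. `aggregate_surfaces()` averages physician-Q,
policy-Q and delta-Q by physician-action cell (count-weighted cell means
recover the global mean exactly); `q_distribution_per_action()` exposes
per-action Q histograms, which catch models biased against specific
actions even when their headline OPE numbers look good;
`action_distribution_by_outcome()` contrasts physician and policy action
counts for survivors and non-survivors. Per-trajectory series use a signed
log transform $\mathrm{sign}(\Delta)\ln(1 + |\Delta|/\sigma)$ — odd,
monotone, zero-preserving — with $\sigma$ defaulting to the series'
delta-Q standard deviation, and `clinical_alerts()` fires where delta-Q
jumps more than $\tau$ (default $2\sigma$) away from its trailing
6-hour median; the jump detector operationalises the idea of alerting
clinicians to abrupt changes in model-clinician alignment and all its
parameters are exposed.

## The synthetic cohort: what it emulates and what it does not

Because the source data are access-restricted, the package ships a seeded
simulator (`sim_config()`, `simulate_cohort()`) whose purpose is
statistical, not physiological: it reproduces the data *structure* the
pipeline assumes. A latent severity follows an AR(1) process moved by
treatment: the PEEP response is an inverted U around an optimum
(10 ± 4 cmH2O), FiO2 speeds recovery, and an observable P/F decreases with
severity and squared PEEP distance from the optimum while rising
transiently with FiO2 (shunt); dead-space fraction rises logistically with
severity and supra-optimal PEEP. FiO2 above a 60% safety threshold
deposits a cumulative oxygen-toxicity load that raises the hourly death
hazard and is visible only through a noisy inflammation-marker channel.
The hourly death hazard is logistic in severity and toxicity; its intercept
is inverted from the target cohort mortality (default 24.4%) via geometric
survival at a reference exposure of 16.5 h, a constant calibrated once
against the default configuration (simulated mortality 0.247 ± 0.007
across seeds at n = 2500). Survivors are discharged once severity falls
below a threshold, to a destination drawn from a severity-dependent
categorical.

Physician behaviour is a softmax whose utility prefers higher support for
sicker patients, penalises extreme support levels, and strongly rewards
staying within one lattice step of the previous action — reproducing the
empirical concentration of consecutive settings (the simulated fraction of
consecutive ventilated actions within Chebyshev distance 1 exceeds 95%).
Optionally, each admission draws a persistent practice style — balanced,
aggressive (high FiO2) or moderate — reflecting real centre-level practice
variation; the default configuration uses a single balanced style. Initial
settings are style-neutral, as initial ventilator settings are largely
standardised in practice.

The default horizon is 72 h rather than the multi-week stays of real
cohorts, to keep experiments desk-scale; auxiliary channels are AR(1)
noise correlated with severity rather than 158 real clinical variables;
there is no pharmacology, no ventilator-mode dynamics, and no
measurement-process realism beyond per-variable missingness rates. Passing
tests on this simulator therefore demonstrates that the pipeline's
machinery is correct and that its selection logic discriminates when the
designed signal exists — not that any learned policy would transfer to
patients.

## The reward-hacking discrimination experiment

`crossope_discrimination_experiment()` is the package's standing
demonstration that cross-OPE catches reward-shaping-sensitive policies. It
uses `sim_config_conflict()`, a configuration engineered so that the
short-term gas-exchange reward and terminal mortality genuinely conflict:
high FiO2 both heals the observable severity quickly and deposits lethal
toxicity, and — crucially — the reward clip makes stepwise FiO2 escalation
*bank* asymmetric gains (each one-bin escalation earns an unclipped unit;
the eventual de-escalation repays a single clipped unit). Fixed-policy
Monte-Carlo oracles on the simulator verify the intended true ordering
before any learning: under $\lambda = 0.25$ aggressive escalation beats
moderation beats the behaviour average, while under $\lambda \ge 2$
moderation wins and aggression is far below the average.

Two agents are trained (λ = 0.25 and λ = 2), their king-knight policies
softened and pushed through the full two-round cross-OPE against a
KNN-estimated behaviour policy on a held-out split. In the canonical
seed-101 instance the λ = 0.25 agent passes round 1 under its own reward
version and fails round 2 under every alternative weighting — most
severely under λ = 8 — while the λ = 2 agent stays above the behaviour
policy under all six versions. The experiment's cohort varies with the
master seed; the split, training and bootstrap sub-seeds are fixed
constants of the design. At other cohort seeds the qualitative gap between
the two agents persists but individual cells are noisy; the test suite
verifies the canonical instance, and the acceptance script reports the
outcome at whatever seed it is given, including the robust summary
(the difference between the two agents' minimum relative values).

## Problem sizes and numerical choices

The test suite runs tabular oracle checks at n = 2000 trajectories,
bootstrap coverage at 50 x 400, the chain-control experiment with 400
episodes and 4000 updates, and the discrimination experiment with 1400
simulated admissions and two 4000-update training runs — all sized for a
single CPU. Degenerate inputs are handled explicitly: zero-variance
features z-score to zero (guarded denominator); empty histogram cells are
reported missing, not zero; MAGIC refuses fewer than 10 trajectories;
`pi_b = 0` on a taken action is an error naming the offending step; ties
in argmax always resolve to the lowest action index. All randomness flows
through explicit seeds and the entire pipeline is single-threaded
deterministic.

## Known limitations

The Q-network's optimism on unsupported actions is mitigated, not
eliminated; conservative-Q-learning-style training is out of scope. MAGIC
under severe weight degeneracy leans on its lowest-variance horizon, which
is why the cross-OPE design rules above exist. The simulator's dynamics are
fixtures: every quantitative result on synthetic cohorts should be read as
a statement about the pipeline, not about ventilation medicine. And the
exact functional form of the study's reward supplement is not public; the
implemented family is parameterised so its constants can be entered through
`reward_config()` if available.
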