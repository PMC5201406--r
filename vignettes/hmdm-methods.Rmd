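---
title: "Modeling stop/go driver behavior at signalized intersections with hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling stop/go driver behavior at signalized intersections with hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmdm)
```

## The problem and the model

Drivers approaching a signalized intersection make a sequence of discrete
decisions — accelerate, decelerate, maintain speed, stop — that are not
directly observable, while the vehicle's kinematics and context (speed,
headway to the vehicle ahead, the queue situation, the signal phase) are.
The segment 40–100 m upstream of the stop line is the Type-II dilemma zone:
at yellow onset a substantial share of drivers there can neither comfortably
stop nor clear the intersection, and indecision in that zone is a known
crash precursor.

`hmdm` models this process as a discrete hidden Markov model.  The hidden
state $q_t \in \{\text{accelerate}, \text{decelerate}, \text{maintain},
\text{stop}\}$ (coded 0–3 in data files) evolves as a first-order Markov
chain with transition matrix $A$ ($a_{ij} = P(q_{t+1}=j \mid q_t=i)$) and
initial distribution $\pi$.  At each detection-line crossing the vehicle
emits one of $M = 81$ observation symbols with probability $b_j(k)$, the
rows of the emission matrix $B$.  The model is fitted separately for each
of three approach zones (zone 1: 0–40 m from the stop line; zone 2: the
dilemma zone, 40–100 m; zone 3: 100–135 m) and for the whole approach, and
two scalar summaries per zone carry the behavioral interpretation:

* **stability**, the matrix 2-norm (largest singular value) of $B$ — more
  concentrated emission rows mean more decisive, more predictable behavior;
* **risk**, $\alpha = \sum_k \log_{10} x_k$ over the six dangerous
  observation symbols $k$, where $x_k$ is the emission probability of the
  most likely state for $k$ — a larger (less negative) $\alpha$ means the
  fitted behavior puts more probability on dangerous configurations.

## From video frames to observation symbols

The raw input is a table of detection-line crossings: virtual lines are
spaced $s = 2.92$ m along the approach and each crossing is timed by its
video frame index at $N = 30$ frames per second.  For a vehicle passing
lines $a, b, c$ consecutively, the travel times are $t_{ab} = n_{ab}/N$ and
$t_{bc} = n_{bc}/N$ (frame counts divided by the frame rate) and the speed
at the middle line is

$$v_b = \frac{2s}{t_{ab} + t_{bc}}.$$

Only interior lines receive a speed (both neighbors are needed), so each
track loses its first and last crossing, and vehicles with fewer than three
crossings are dropped.  Accelerations are finite differences of consecutive
line speeds over their time gap (backward differences, with the first
interior line taking the forward difference so every speed-bearing line is
labeled).  A crossing is classified as *stop* when $v \le 0.5$ m/s, else
*accelerate*/*decelerate* when $|a| > 0.3$ m/s², else *maintain*; the stop
test takes precedence.  Both thresholds are configurable
(`kinematics_config()`); the defaults are ordinary urban values chosen once
and used throughout.

Each crossing is then discretized into a four-component tuple:

| component | bin 1 | bin 2 | bin 3 |
|---|---|---|---|
| speed (m/s) | $\le 8$ | $(8, 16)$ | $\ge 16$ |
| headway (s) | head car | $(0, 6)$ | $\ge 6$ |
| queue | head car | no preceding car stopped | others |
| signal | green | red | yellow |

and encoded as a single symbol with the signal varying fastest, then queue,
then headway, then speed:

$$\mathrm{index} = 27(\mathrm{speed}-1) + 9(\mathrm{headway}-1) +
3(\mathrm{queue}-1) + \mathrm{signal} .$$

The alphabet is exactly $3^4 = 81$ symbols, indexed 1–81.  Under this
enumeration the six dangerous configurations — medium or high speed with a
short headway and a stopped vehicle context, i.e. $(2,2,3,\ast)$ and
$(3,2,3,\ast)$ — receive indices 43, 44, 45, 70, 71, 72, which is the
package's fixed `dangerous_symbols()` set.  Boundary conventions are taken
literally from the binning table: 8 m/s falls in bin 1, 16 m/s in bin 3, a
headway of exactly 6 s in bin 3.  Zone assignment is half-open toward the
stop line: $[0,40)$, $[40,100)$, $[100,135]$.

## Estimation

### Baum-Welch (unsupervised)

`hmdm()` trains by multi-sequence Baum-Welch.  The forward and backward
recursions are scaled per step (the forward variables are renormalized and
the log-likelihood accumulated from the normalizers), implemented in C++
for the inner loops; Viterbi decoding runs in log space.  The E-step
numerators and denominators are pooled across all vehicle sequences before
dividing, and $\pi$ is re-estimated as the mean first-step posterior —
the standard multi-sequence extension of the single-sequence update
formulas.  Numerical choices, each configurable through `hmdm_control()`:

* **initialization**: seeded Dirichlet(1) rows; 5 random restarts by
  default, keeping the restart with the highest final log-likelihood (an
  explicit `init` replaces the first restart);
* **smoothing**: $10^{-10}$ is added to every row of $A$, $B$ and $\pi$
  after each update, then rows are renormalized, so held-out sequences
  containing symbols unseen in training never score exactly zero;
* **convergence**: relative log-likelihood improvement below $10^{-6}$, or
  500 iterations;
* **ties** (Viterbi, state inference, next-state prediction) break toward
  the lowest state index;
* a sequence containing a symbol no state can emit has likelihood zero and
  is reported as `-Inf`, not an error;
* an expected-count row for a state never visited is reset to uniform with
  a warning rather than dividing by zero.

Every fit records its log-likelihood trace; EM monotonicity (the trace
never decreases beyond $10^{-9}$) is asserted throughout the test suite.

### Supervised MLE and validation

With state labels available, `hmdm()` uses the closed-form maximum
likelihood estimates instead: row-normalized transition and emission counts
and normalized initial-state frequencies.  The pipeline uses this estimator
on the labeled validation split as the reference against which the
unsupervised fit is scored by MAPE — the mean absolute percentage error
over all entries of $\pi$, $A$ and $B$ whose reference value is at least
0.01 (masking near-zero references keeps the ratios meaningful).  Because
an unsupervised fit identifies states only up to permutation, the pipeline
first relabels the fitted states by the permutation minimizing the total
absolute difference between the two emission matrices
(`align_states()`).  Even so, parameter-level MAPE at desk-scale sample
sizes is dominated by relative noise in the many small emission entries
and is reported for completeness rather than as a pass/fail quantity.

### Identifiability

Parameter recovery is demonstrated (tests) on a well-separated truth —
sticky transitions, near-orthogonal Dirichlet(0.2) emission rows — where
Baum-Welch started near the truth recovers $A$ to a mean absolute error
well under 0.05 from 200 sequences of length 50.  The bundled
driving-behavior fixture is deliberately *not* that well separated: its
moving states (accelerate/decelerate/maintain) emit overlapping speed and
context distributions, exactly as real intersection data would, and under
that overlap the state posteriors — and hence $A$ — carry irreducible
uncertainty at this sample size.  This distinction (estimator correctness
versus fixture identifiability) is intentional and worth keeping in mind
when interpreting fits on real data.

## The synthetic generator

No field data ships with the package; the generator supplies inputs with
the statistical structure the analysis assumes, at two levels of realism.

**Exact-HMM sampling** (`sample_hmm_sequences()`, and the pipeline's
default `observation_source = "hmm"`): sequences drawn directly from a
known ground truth, with true state labels retained.  Each simulated
vehicle contributes 44 observations — 12 in zone 3, 19 in the dilemma
zone, 13 in zone 1, roughly one per detection line given the zone lengths
(35, 60 and 40 m at 2.92 m spacing) — so the default 256 vehicles yield
11,264 records, mirroring the scale of the motivating field study.  This
is the controlled path for estimator and metric validation: fitted
emission matrices estimate the specified truth, so the per-zone metric
ordering is a meaningful recovery target.

**Kinematic simulation** (`simulate_approach()`,
`observation_source = "physical"`): vehicles arrive by a Poisson process
(default 600 veh/h, a per-lane share of a busy through movement), enter
135 m upstream at 8–14 m/s, and carry a hidden state evolving once per
second by the zone-specific transition matrix.  States map to
accelerations (+1.5, −2.5, 0 m/s²; the stop state brakes at −4.5 m/s² to
standstill), positions are integrated at frame resolution, followers never
overtake (held ≥ 5 m behind the leader at no more than its speed), and on
red/yellow the stop line acts as a wall so queues form and dissipate with
the 190 s cycle (35 s green, 3 s yellow — the yellow duration is not a
standard published value for this site and is configurable).  Crossing
frames are rounded to the nearest frame, which is the only measurement
noise in the chain; the frame-count kinematics then reconstruct speeds to
within the rounding bound.  What this path does **not** emulate: lane
changes, turning movements, heterogeneous driver populations, reaction-time
dynamics, or any coupling from the signal into the hidden-state process
itself (the state chain is exogenous; the signal acts only through the
physical wall).  Passing tests on this generator therefore validate the
pipeline machinery, not behavioral realism.

The fixed ground truth (`default_ground_truth()`) encodes the qualitative
dilemma-zone findings as generative structure: the zone-2 emission rows are
more diffuse (mixed toward uniform) and carry an order of magnitude more
mass on the six dangerous symbols than zones 1 and 3, while its transition
matrix is volatile; zone 1 is decelerate/stop-dominated at low speed and
zone 3 is a persistent maintain regime.  On this truth the risk index
orders zone 2 highest and the 2-norm orders zone 2 lowest, and an
end-to-end run recovers both orderings from fitted models.

## Design choices where the design was open

* **Alphabet size.**  The observation combination of four three-level
  factors gives exactly $3^4 = 81$ symbols, and the dangerous-combination
  indices 43–72 confirm the 1-based enumeration; the package fixes the
  alphabet at 81 accordingly.
* **Risk index summands.**  $\alpha = \sum \log_{10} x_{jk}$ leaves the
  index set $(j,k)$ open.  The default takes, per dangerous symbol, the
  emission probability of its most likely state (six summands); a variant
  summing over all states and dangerous symbols (24 summands,
  systematically more negative) is available as `variant = "all"`.
  Probabilities are floored at $10^{-10}$ before the log so unobserved
  symbols contribute a large negative but finite amount.
* **2-norm.**  Read as the spectral norm (largest singular value), the
  standard meaning for matrices; `type = "frobenius"` is provided for
  comparison.  For a row-stochastic $N \times M$ matrix the spectral norm
  lies in $[1/\sqrt{M}, \sqrt{N}]$.
* **Split unit.**  The train/validation split assigns whole vehicles, never
  parts of a sequence (HMM training needs intact sequences); the realized
  record counts are logged since a vehicle-level split cannot hit an exact
  record count.
* **Head car across cycles.**  The head-car flag resets per lane per signal
  cycle when a cycle length is supplied — the first vehicle of a cycle has
  no meaningful predecessor gap.
* **Current-state inference.**  `most_likely_state()` takes the argmax over
  all four states; the stop state is effectively excluded at the
  medium/high-speed dangerous symbols by its negligible emission mass
  there.
* **Severity rule.**  A warning is severe when the predicted next state is
  neither decelerate nor stop while the observed symbol is dangerous — a
  formalization of "accelerating into a short headway is dangerous".
* **Zone of a prediction.**  Warnings for a validation observation use the
  fitted model of the zone that observation lies in.

## Problem sizes

The test suite and the bundled pipeline runs use desk-scale sizes chosen to
exercise every code path quickly: brute-force oracle comparisons on 1000
random 4-state models with sequences up to length 6; parameter recovery on
200 × 50 observations; law-of-large-numbers checks on 2000 × 50 samples;
and end-to-end runs at the study scale of 256 vehicles × 44 records with
2 EM restarts and up to 100 iterations per zone model (the pipeline
default, raisable through `pipeline_config(fit = hmdm_control(...))`).

## Known limitations

* Parameter-level MAPE is inflated by label-switching ambiguity (mitigated
  by alignment) and by small-sample noise in near-threshold reference
  entries; it is not comparable across sample sizes.
* The fitted risk index in low-risk zones is floor-dominated: when a
  dangerous symbol never occurs in a zone's training data its fitted
  emission probability is the smoothing floor, so risk differences between
  two *safe* zones are not interpretable — only the separation of the
  risk-loaded zone is.
* The physical simulator's hidden states are exogenous to the signal and
  traffic, so it cannot generate genuinely *reactive* dilemma-zone
  behavior; it validates measurement and estimation machinery only.
* Real deployments would need the queue descriptor defined operationally;
  here it is provided by the generator's context.
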