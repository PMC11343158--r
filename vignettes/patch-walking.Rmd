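---
title: "Patch-walking: models, scheduling rules and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-walking: models, scheduling rules and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchwalk)
```

## The problem

Paired whole-cell patch-clamp recording is the ground-truth assay for a
chemical synapse: hold two neurons simultaneously, fire one, and look for an
evoked postsynaptic current (PSC) in the other. Because local cortical
connectivity is sparse and falls off with distance, most paired recordings
find nothing, and the throughput of the search is what limits connectomic
studies. In the *traditional* multi-patch strategy, all `p` pipettes patch a
group of `p` cells, every ordered pair is screened, and then every pipette is
retracted, cleaned (or replaced) and advanced to a fresh group.
*Patch-walking* instead retracts only one pipette at a time: the other keeps
its whole-cell recording alive, so every new successful patch immediately
creates a new testable pair, and the pipette pair "walks" across the slice
chaining paired recordings together.

## Yield models

For `n` recorded cells and `p` pipettes the traditional strategy probes

$$C_{trad} = \frac{n}{p}\,(p^2 - p)$$

directed connections (groups of `p`, fully cross-probed), while patch-walking
probes

$$C_{walk} = (p^2 - p) + 2(p-1)(n-p) = (p-1)(2n - p):$$

the initial `p` cells are fully cross-probed and each of the remaining
`n - p` cells is probed bidirectionally against the `p - 1` cells held when
it arrives. All counts are of *directed* probes; paired recordings are half
that. The ratio is

$$\frac{C_{walk}}{C_{trad}} = 2 - \frac{p}{n} \xrightarrow{\;n \to \infty\;} 2,$$

so the fractional improvement is `1 - p/n`: 80% at `(n = 10, p = 2)` and 92%
at `(n = 100, p = 8)`, approaching a doubling for long experiments.

```{r}
yield_comparison(10, 2)
improvement(100, 8)
```

Two counting choices deserve a note. First, `improvement()` defaults to the
idealized formula above, which treats `n/p` as a real number; the alternative
`method = "counts"` forms the ratio of the integer counts, in which the
`n mod p` leftover cells make one smaller final traditional group
(`floor(n/p)(p^2-p) + r^2 - r`). The two agree whenever `p` divides `n`.
Second, `yield_matrix()` makes the walk's sliding-window structure explicit;
its sum always equals the closed form, and the tests verify both against
independent enumeration oracles.

## Distance-dependent connectivity

Connection probability between nearby cortical neurons decays with
intersomatic distance. No functional form is canonical at the scale we need,
so the package adopts a two-parameter exponential,
$P(d) = a\,e^{-d/\lambda}$, because it is monotone, stays in $[0,1]$ after
clipping, and is *exactly identified* by two anchor operating points:
16.9% at 91.6 um (the mean paired-recording distance in the walking regime)
and 10% at 200 um (the distance beyond which pairing is not worthwhile).
Solving gives $\lambda = 206.6$ um and $a = 0.263$ at zero distance. The
model object is pluggable — anything with a `predict(model, distance)`
method can replace it, e.g. a logistic or piecewise fit.

```{r}
m <- default_connectivity_model()
m
connection_probability(c(0, 91.6, 200), m)
```

Yield expectations over a screen are exact binomial computations
(`prob_at_least_k()`, no normal approximation): with 29 paired recordings at
a per-probe probability of 0.169 the chance of at least 3 connections is
89%. One published-style claim needs care: "more than 50% after 3 paired
recordings" does not hold if 0.169 applies per *pair* (that gives 42.6%) but
does if each pair contributes two directed probes (six probes give 67.1%).
Both computations are one call away; the package asserts only the
per-directed-probe reading, which is also how the screen simulation applies
the model.

## The scheduling state machine

The scheduler (`scheduler_init()` / `advance()`) is a deterministic state
machine: it owns no clock and draws no random numbers, consuming completion
events and emitting requested actions. This makes the control flow testable
by scripting event sequences by hand, and makes every simulated run exactly
reproducible. The encoded rules:

* **Nearest-cell assignment.** Cell coordinates live in a queue; an
  available pipette takes the queued cell closest (3D Euclidean) to its home
  position, ties broken by lowest id.
* **Stage/camera arbitration.** Only neuron hunting needs the microscope
  stage and camera, so at most one pipette hunts at a time; a simultaneous
  request is deferred until the stage frees. Sealing, break-in, holding and
  cleaning proceed in parallel.
* **Clean and reuse.** A failed attempt marks the cell consumed, sends the
  pipette through cleaning, and assigns the next closest cell.
* **Pair formation and the walk rule.** When both pipettes hold, the pair is
  screened bidirectionally; afterwards the pipette whose whole-cell
  recording is *older* is released to clean and walk on, keeping the fresher
  recording alive. The traditional strategy instead retracts both.
* **Hold limit.** A recording held 45 min (default) without pairing is
  released.
* **Wind-down.** Queue exhaustion retires a pipette; a holder whose partner
  has retired can never pair again and is released and retired too.

Only the two-pipette apparatus is implemented. The walk rule generalizes on
paper, but for `p > 2` the pairing semantics interact with pipette-collision
geometry, which is out of scope here; the closed-form yield functions cover
general `p`.

An optional minimum tip-separation radius (default off) skips candidate
cells too close to the other pipette's held cell, a coarse guard against
pipette collisions.

With failure probability zero, the walk over `n` cells produces exactly
`n - 1` pairs — the closed form — and the test suite asserts this equality
end-to-end through the simulator.

## Patch-attempt stage rules

The per-attempt criteria are pure functions, reusable on any measurement
stream:

* **Neuron hunting** (`detect_neuron()`): detection when tip resistance
  rises ≥ 0.2 MΩ over 5 consecutive descending 0.1 um steps. The rise is
  evaluated endpoint-to-endpoint over the window (not cumulatively): the
  criterion is then translation-invariant in baseline resistance and robust
  to within-window noise ordering.
* **Gigaseal** (`gigaseal_reached()`): seal resistance ≥ 1 GΩ, read as
  inclusive; the controller waits 5 s before break-in.
* **Break-in** (`break_in_success()`): resistance strictly below 800 MΩ
  *and* holding current at −70 mV not more negative than −200 pA. Suction
  pulses are 100–1000 ms; how many pulses to attempt before giving up is not
  a physical constant, so the simulator folds break-in failure into the
  overall per-attempt success probability.
* **Recording QC** (`qc_evaluate()`): access resistance below 40 MΩ
  throughout → include; any excursion above 50 MΩ → stop recording (keeping
  earlier data); the 40–50 MΩ band marks a degraded seal and defaults to
  exclude-from-analysis while recording continues (configurable, since labs
  differ on whether a degraded seal should also stop the recording).
* **Protocols** (`build_current_clamp_protocol()`): the whole-cell check is
  1 s at 0 pA, 1 s step, 1 s at 0 pA; the f–I family is 16 sweeps of 3 s
  pulses from −20 to +280 pA in 20 pA steps, each preceded by a 2 s −20 pA
  hyperpolarizing step ending 500 ms before the pulse. Waveforms are
  sample-exact at the default 10 kHz (a conventional rate; any rate can be
  passed).

## Connection screening and detection

A screen drives the presynaptic cell to fire five action potentials at
20 Hz while the postsynaptic cell is voltage-clamped at −70 mV; the
protocol is run in both directions and three sweeps are averaged per
direction. The synthetic sweeps use a difference-of-exponentials PSC kernel
(rise 1 ms, decay 10 ms, latency 2 ms after each spike), normalized on the
sampling grid so the sampled trough equals the requested amplitude exactly.

Detection has no universal published criterion, so the package defines one
and makes every constant configurable: baseline mean and SD from the 50 ms
pre-stimulus window; per-spike evoked amplitude as the baseline-subtracted
inward extremum in a 2–20 ms post-spike window; and a decision statistic
equal to the amplitude of the *stimulus-averaged* response — the five
post-spike windows aligned and averaged before taking the extremum — which
must exceed 3 baseline SDs. Averaging across the train matters numerically:
the minimum of a single ~180-sample noise window sits near 2.6 SDs on
average, so a per-window extremum statistic would false-alarm on roughly 9%
of noise-only screens at a 3-SD threshold, while the train-averaged
statistic's noise floor is ~2.6/√5 ≈ 1.2 SDs and its empirical
false-positive rate is below 1% (the suite checks < 5%). A 50 pA PSC at
5 pA noise is detected essentially always.

```{r}
train <- build_stim_train()
sweeps <- lapply(1:3, function(i) {
  synthesize_sweep(train, connected = TRUE, noise_sd_pa = 5, seed = i)
})
classify_connection(average_sweeps(sweeps), train)[c(
  "connected", "mean_evoked_amplitude_pa", "baseline_sd_pa"
)]
```

## The simulator

`simulate_experiment()` layers stochastic outcomes on the deterministic
scheduler: attempt success is Bernoulli (default 0.522, the operating yield
of coordinated two-pipette patching; uncoordinated robots and manual users
span roughly 30–80%), and each directed probe of a formed pair is Bernoulli
at the distance-decay probability of that pair's intersomatic distance.
Stage durations are gamma-distributed, parameterized by mean and SD
(positive support, two parameters — the natural minimal choice). Defaults
are hunt 2 ± 1, gigaseal 3 ± 2, break-in 0.5 ± 0.25, clean 1.5 ± 0.5 and
screen 2 ± 0.5 min, chosen so that the *emergent* time between paired
recordings is of order ten minutes, the regime of a real walking
experiment; time-to-pair is an output of the simulation, never an input.
Screens consume clock time but their count bookkeeping is exact.

```{r}
cfg <- sim_config(n_cells = 9)
log <- simulate_experiment(cfg, seed = 42)
log
cmp <- compare_strategies(sim_config(n_cells = 10, success_prob = 1),
                          n_reps = 5, seed = 1)
cmp
```

`compare_strategies()` uses paired seeds so both strategies face the same
cell map and the same luck; with success probability 1 the empirical
improvement equals the closed form exactly.

## Synthetic data: what it does and does not emulate

`generate_cell_map()` reproduces the geometry of cell selection — 8–10
targets in a ~200 × 200 um field, 20–100 um deep, with a 15 um minimum
separation (about one soma diameter) — by rejection sampling (capped at
10,000 draws). It does not emulate cell-type identity, layer structure,
tissue health gradients, or the tendency of human operators to pick
clustered healthy cells, so simulated distance distributions are somewhat
more uniform than real ones. Likewise the synthetic sweeps have stationary
Gaussian noise and a fixed PSC kernel: no spontaneous synaptic events, no
electrical artifacts, no short-term plasticity across the five stimuli.
Passing tests therefore demonstrate the correctness of the counting,
scheduling and detection logic under controlled conditions — not detector
performance on real recordings.

## Numerical choices and degenerate inputs

* Tie-breaks are always deterministic (lowest cell id; pipette `a` when
  both recordings started simultaneously), so logs are bit-reproducible
  under a seed.
* The gigaseal threshold is inclusive (≥ 1000 MΩ); break-in resistance is
  strict (< 800 MΩ); the holding-current bound is a floor (≥ −200 pA).
* A hunting trace shorter than the 5-step window returns "no detection"
  rather than an error; an empty cell queue is a retirement signal, not an
  error; `prob_at_least_k(m, q, 0)` is 1 and `k > m` gives 0.
* Pair intervals that end before a screen completes leave both directed
  probes marked untested rather than dropping the pair.
* Event logs are JSON lines with a schema-version field; all other formats
  are header-row CSV.

## Problem sizes

The shipped tests enumerate the yield oracles over `2 ≤ p ≤ 8`,
`p ≤ n ≤ 60`, run simulator closed-form checks at `n ∈ {4, 10, 25}`, and
verify detection-rate recovery on 2,000 synthesized pairs (4,000 directed
zero-noise screens) at 91.6 um against the binomial 95% interval. These
sizes were chosen to exercise every code path while keeping a full test run
under a minute of CPU.

## Known limitations

* The scheduler models two pipettes only; `p > 2` walks exist in the yield
  algebra but not in the discrete-event engine.
* Failure is a single Bernoulli per attempt; there is no per-stage failure
  attribution (a hunt that finds nothing versus a seal that never forms).
* Tissue deformation disturbing held pipettes — a real failure mode of
  multi-pipette work — is not modeled; the hook for it would be a per-event
  pair-loss probability.
* The realized pair count of a session depends on per-slice walk lengths and
  failure timing, so only aggregate quantities (counts, rates, closed-form
  comparisons) are reproduced, not any particular session's log.
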