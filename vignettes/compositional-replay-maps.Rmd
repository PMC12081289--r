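---
title: "Compositional maps, constructive replay, and replay-decoding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional maps, constructive replay, and replay-decoding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
data emulate (and do not), and the numerical and design choices that were
genuinely open.

## The model

Hippocampal state spaces are treated as *compositions* of reusable cortical
building blocks. Each object in a world — a reward, a wall end — is
represented by a population code for the vector relation between the agent
and that object. Because every building block path-integrates by the same
relational rule in every environment, a new environment is understood by
recombining codes rather than by relearning transitions.

Discrete worlds are deterministic MDPs on rectangular grids with actions
north, east, south, west, walls as blocked edges between adjacent cells
(each wall carries its two endpoint cells, one per wall-end vector
population), and blocked moves as no-ops so rollouts are total. The
discrete vector code concatenates four one-hot blocks of signed distance
along each action; directions pointing away from the object clamp to −1
regardless of magnitude, so the code stays 4-sparse and decodes uniquely.
Continuous arenas are 1 m × 1 m with line-segment walls, a 5 cm contact
radius and a 5 cm action step; the continuous code evaluates a population
of isotropic Gaussian fields (preferred vectors on a square grid, ±1 m at
10 cm spacing, field s.d. 5 cm) at the current offset. Grid spacing, extent
and field width are free parameters of the population and these defaults
are chosen to tile the arena with ~2 fields per offset dimension — the
source model leaves this geometry open.

A hippocampal conjunction is the outer product of two parent codes. The
agent's memory abstracts the conjunctive attractor as a key-value store:
location is the key, the vector code the value. Online tracking fuses noisy
path integration with retrieval, `s ~ w·p_PI + (1 − w)·p_M` (discrete:
sampled from the mixture; continuous: the weighted point estimate with
softmax-over-cosine retrieval weights, temperature 1), then re-encodes `s`
at the new location. The fusion weight defaults to `w = 0.5` — the source
model does not pin it down, and 0.5 weights the two information channels
equally; it is exposed in every relevant function.

One modelling note on continuous path integration: rotational direction
noise makes the *exact* mean of the noisy step `exp(-σ²/2)` times the
intended step, so the update is unbiased only to first order in the noise.
`pi_step_moments()` gives the exact closed-form mean and variance; tests
check against those rather than against the idealised unbiasedness claim.

## Policies and generalization

A feedforward network `f(s) = a` with rectified-linear hidden layers is
trained by Adam (default hyperparameters) on (state, optimal action) pairs,
where optimal actions minimise steps to reward (breadth-first distances on
grids; Dijkstra on a lattice discretisation with straight-line shortcuts
where the reward is in direct line of sight, in arenas — the continuous
construction is our choice, the source model being silent). Traditional
agents read a one-hot location code; compositional agents read the
concatenated reward-then-walls vector codes with absent objects as zero
blocks.

Evaluation rolls the argmax policy out from each start with a budget of
four times the optimal path length (minimum 30 steps), counting arrivals at
the reward (within 5 cm in arenas). The random baseline in the
generalization experiment is a *deterministic* random policy — one fixed
uniform action per cell — because the evaluated networks are themselves
deterministic; a per-step stochastic policy explores more by construction
and would not be the matched null.

Desk-scale defaults train 64/32-unit hidden layers for 45 full passes on
25 worlds × 200 samples per round over 3–10 rounds; the printed protocol
sizes (1,000/750/500 units, 25 environments resampled 100 times) are
accepted by the same functions when more compute is available. The
generalization asymmetry (compositional held-out success ≈ 1, traditional ≈
deterministic-random baseline) is insensitive to the network size once
training converges, which the capacity test verifies.

## Latent learning and constructive replay

The latent-learning simulation compares an agent that tracked a wall's
vector code before finding reward against one that must rediscover the
wall. Success at a behind-the-wall state is a rollout planned from the
agent's current believed composition, executed on the true world. Because a
single blocked edge often changes no shortest path, worlds are resampled
until blocking the edge actually lengthens some path — otherwise there are
no behind-the-wall states to probe.

Constructive replay imagines a trajectory from the anchor (reward or home),
path-integrates the location key and the vector value with *independent*
noise (nothing is observable during replay), encodes one entry per step,
and never retrieves. With no noise the encoded map is exact and depends
only on the visited-state set, which is why policy success is 1.0 at the
first replay visit to a state for any trajectory ordering. The Q-backup
contrast applies backward Bellman updates (γ = 0.7, α = 0.8) in the
opposite direction of replay; its visit-1 success is 1 only for
reverse-optimal trajectories and takes many visits for random ones.

In the noisy homing task the memory agent replays from home five times
every four steps (the stated schedule); the Q control replays *on-policy*
from its observed location — actions follow argmax Q where informative,
random elsewhere, reward fires on imagined arrival at home, and the
imagined state itself is path-integrated, so credit can land on the wrong
cell. Homing error is the city-block distance from home after a greedy
escape (budget 4× the arena diameter); memory/PI agents stop when their
believed home vector reaches zero, the Q agent when it observes home. Study
conditions: a 9 × 9 grid with home at the centre, noise levels
{0, 0.1, 0.2, 0.4} errors per step, exploration lengths {8, 16, 32, 64},
replay counts {1, 2, 5, 10}, 30 seeds per cell. At the highest noise level
both replay agents sit near their error ceiling and their ordering is
seed-sensitive; the aggregate ordering over noise levels (memory reaches
the PI-only error floor with fewer replays than Q) is the stable statistic
and the one asserted.

## The synthetic population

The home-well simulation builds 10 grid cells (triangular lattice, 120 cm
peak spacing, 6° rotation, random per-cell translation), 20 object-vector
cells (uniform direction, uniform 0–200 cm preferred distance from the home
well) and 40 sensory cells (uniform field centres) on a 2 m × 2 m arena
with 2 cm bins, each class scaled so its population maximum is exactly
20 Hz. Conjunctions (products) give 200 landmark and 400 place cells,
scaled per class to 20 Hz; the landmark/object-vector scale is fixed on day
1 and shared with day 2 so that the day-2 map is exactly the day-1 map
translated with the home well.

Field widths are the one genuinely underdetermined geometry. We use
Gaussian s.d. 14.1 cm for grid/sensory fields and 11.0 cm for object-vector
fields: these are the field sizes typical of open-field rodent recordings,
and they are the *only* reading under which the simulation's two stated
anchors — a ×25 replay rate scaling and a yield of roughly 30 replay spikes
per trajectory — are simultaneously satisfiable. Interpreting the printed
covariances as centimetre-squared entries instead produces millimetre-scale
fields and an essentially silent population (~0.01 spikes per trajectory).
This was settled by a single calibration study before any acceptance
thresholds were written, and not revisited.

Sessions sample 100 replay trajectories (one home replay, then three
elsewhere, repeating) spread evenly over 10–3,000 s; each extends 100–300 cm
in a random direction over 20 steps of 5 ms and is cut at the arena
boundary (elsewhere replays also before entering the 30 cm home exclusion
zone; zero-length trajectories are dropped). Spikes are Poisson with rates
read from the day-1 conjunctive maps at the replayed locations, scaled by
25. A landmark cell may spike in an elsewhere replay only after its first
home-replay spike, whose time `t0` is recorded; the ground-truth change map
of a replay at `t1` is `t0/t1` times the cell's full landmark peak, plus
change noise (standard-normal × 0.5 Hz smoothed with a 4 cm kernel). Place
cell changes are noise only. Day-2 cumulative changes subtract day-1 from
day-2 maps and add the same noise.

What the generator does *not* emulate: theta-paced behavioural spiking,
bursting and refractoriness, cross-day cell-identity drift, ripple-band
LFP, and reward-related rate modulation. Passing tests therefore show the
*pipeline and model logic* are correct under Poisson spiking with known
ground truth — not that real recordings will show effects of the same
magnitude. Between-replay behavioural data, where needed for before/after
rate maps, come from a smooth random-walk foraging generator
(`generate_foraging_track()`), an extension the source model does not
describe.

## The analysis pipeline

Rate maps: 2 cm bins, >5 cm/s speed filter, spike and occupancy maps
smoothed with a 4 cm s.d. Gaussian (kernel renormalised over in-arena bins
so edges are not dragged toward zero), rate = smoothed spikes / smoothed
occupancy, bins under 0.2 s smoothed occupancy masked. The population rate
is a 1 ms histogram of sub-5 cm/s spikes smoothed with a 10 ms kernel; a
replay event starts when that rate exceeds its nonzero mean over the 500 ms
before the ripple and ends when it drops below that mean after the ripple
(the pre-ripple window length is our choice).

Decoding is the memoryless Bayesian posterior computed in log space with
rates floored at 0.01 Hz (so zero-rate bins stay in support with finite
log-likelihood), τ = 20 ms windows slid by 5 ms; the decoded position is
the posterior maximum with exact ties resolved by the tied bins' centroid.
Each neuron that spiked is localised by re-decoding without it and linearly
interpolating its spike times along the decoded trajectory; spikes outside
the decoded span snap to the nearest endpoint and are flagged. Change maps
translate so the interpolated spike sits at the origin; a cell's multiple
spikes in one event are averaged first. Event classification uses the
10/30/40 cm home/elsewhere criteria; time-matched controls keep the best of
10,000 subsamples by 5-bin event-time histogram correlation. Summaries are
the 8 cm-radius origin ROI and 50 × 2 cm radial spokes over 20 angles
(nearest-bin lookup). All directional tests are one-tailed in the model's
predicted direction.

For the synthetic validation, "before/after" maps are not recomputed from
behavioural spiking: the generator supplies each replay's ground-truth
change map directly (the `t0/t1` rule above), and the pipeline contributes
the decoding, localisation, alignment and summaries. This isolates what is
being validated — the analysis — from what is being assumed — the model of
change.

## Problem sizes and determinism

The shipped experiments run at desk scale on one CPU: 25 worlds for visit
curves and generalization tests, 30 seeds per homing grid cell, one
600-cell session with a 10-cell-per-event cap for the decoding validation,
ten sessions for the spike-yield estimate. Every stochastic function draws
from R's global RNG so `set.seed()` makes any run bit-reproducible;
`run_experiment()` records the config hash and seed in its manifest.

## Known limitations

Single-edge walls make latent-learning effects sparse (hence the
conditioned world sampling); the continuous optimal policy is an any-angle
approximation on a lattice; the homing ordering at extreme noise is
seed-sensitive as discussed; per-cell home-shift correlations at the full
0–200 cm object-vector distance range are small in magnitude (many fields
fall outside the arena) even though the population bias is reliably
negative and landmark-driven; and the key-value memory has no capacity
limit, forgetting, or attractor dynamics by design.
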