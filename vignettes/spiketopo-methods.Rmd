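---
title: "From FORCE-trained spiking networks to persistence barcodes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FORCE-trained spiking networks to persistence barcodes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiketopo)
```

`spiketopo` implements a complete computational-neuroscience study as a
reusable pipeline: a recurrent network of leaky integrate-and-fire (LIF)
neurons is trained, by FORCE learning, to autonomously draw a closed planar
curve with its two linear readouts, and the spike trains produced during one
traversal of the curve are then characterized through Victor–Purpura (VP)
distance matrices, a rank-order normalization, and Vietoris–Rips persistent
homology (persistence barcodes and Betti curves in dimensions 0 and 1).
This vignette documents the models, the conventions, and the design choices
that were genuinely open, so results can be interpreted and reproduced.

## 1. The spiking reservoir

Each of the $N$ neurons obeys

$$\tau_m \dot v_i = v_{rest} - v_i + I_{bias} + \sum_j \omega_{ij} r_j,
\qquad \omega = A + U W,$$

with threshold $v_{th}$, reset $v_{reset}$, and an absolute refractory
period $\tau_{ref}$ during which the voltage is clamped and input ignored.
Spikes are filtered by the double-exponential synapse

$$\dot r_i = -r_i/\tau_d + h_i, \qquad
\dot h_i = -h_i/\tau_r + \frac{1}{\tau_r \tau_d}\sum_k \delta(t - t_k^{(i)}),$$

so each spike contributes exactly unit area to $r_i$.  The readouts are
$\hat z = W r$ ($M = 2$ for planar curves) and feed back into the network as
the current $U \hat z$.

**Parameter defaults** (all overridable through `neuron_params()`): $\tau_m$
= 10 ms, $v_{rest} = v_{reset}$ = −65 mV, $v_{th}$ = −40 mV, $\tau_{ref}$ =
2 ms, $\tau_r$ = 2 ms, $\tau_d$ = 20 ms.  These are the standard values for
FORCE-trained LIF reservoirs.  Note that the symbol $\tau_r$ is used in the
literature both for the refractory period and the synaptic rise constant;
the package keeps them as two distinct parameters (`tau_ref`, `tau_rise`),
both 2 ms by default.

**The bias.** The package defaults to $I_{bias} = v_{th} - v_{rest}$ =
25 mV, which places the bias-driven equilibrium exactly at threshold.  With
a bias of zero and the voltage scale above, the network has a globally
attracting subthreshold fixed point: it is permanently silent, cannot be
trained, and cannot produce any firing-rate band.  Putting the equilibrium
at threshold (the convention also used in reference LIF-FORCE
implementations) makes the network excitable — quiescent in isolation but
responsive to any recurrent or feedback fluctuation — which is the regime
in which all results here are produced.  Voltages are quoted in mV, times
in seconds, everywhere in the package.

**Connectivity.** $A$ is sparse with connection probability $p = 0.1$ and
Gaussian weights of standard deviation $g (pN)^{-1/2}$; the diagonal is
drawn like any other entry.  $U$ is dense uniform on $[-q_{fb}, q_{fb}]$.
$W$ starts at zero.  The default feedback strength is $q_{fb}$ = 40 mV per
output unit: strong enough that the feedback loop visibly modulates the
population rate (which is what produces the per-petal rate excursions for
rose targets), while the circle — whose feedback drive has constant
magnitude $R$ — yields a flat rate trace.

**Initial state.** Voltages start uniform on
$[v_{rest},\, v_{th} + (v_{th} - v_{rest})]$, so about half the neurons fire
in the first step.  This kick is necessary: with the bias exactly at
threshold, a network started strictly below threshold never fires.  The
transient decays within a few tens of milliseconds.

**Integration.** Forward Euler for the voltage with $dt$ = 0.05 ms, exact
exponential integration of the $(r, h)$ pair within each step.  Spike times
are recorded at the end of the step in which threshold is crossed, without
interpolation; at the VP cost $q = 1\,\mathrm{s}^{-1}$ used downstream,
sub-step jitter is irrelevant.  A self-convergence test (halving $dt$ on a
small network) is part of the test suite.  Non-finite states abort with a
message suggesting a smaller $dt$ or gain.

## 2. Target curves

Four closed curves are generated by `generate_target()`, all parameterized
so that one full closed traversal takes exactly the trial duration $T$
(1 s by default): a circle of radius $R$; the four-petal rose
$r = R\sin 2\varphi$ over one revolution; the two-petal rose, which is the
same polar curve restricted to $\varphi \in [0, \pi/2] \cup [\pi, 3\pi/2]$,
with the excluded intervals skipped by a continuous time mapping (the curve
passes through the origin between petals); and the three-petal rose
$r = R\sin(3\varphi/2)$.  For the latter, one revolution already returns
the trace to its starting point (the origin) and draws exactly three
petals with three radius maxima per trial — the configuration that matches
the three rise–fall rate excursions the trained networks produce.
Traversing two revolutions instead would re-trace three more lobes and
double the number of radius maxima, so the package deliberately uses the
single revolution.  $R$ defaults to 1 (dimensionless output; the readout
weights absorb any scale).

## 3. FORCE training

Every $\Delta t$ = 2 ms (after a 0.1 s settle period), with $r$ the current
filtered-rate vector and $z(t)$ the teacher value,

$$e = W r - z, \qquad
P \leftarrow P - \frac{P r r^\top P}{1 + r^\top P r}, \qquad
W \leftarrow W - e\, (P r)^\top,$$

with $P$ initialized to $I/\alpha$.  The error is computed with the
pre-update $W$; the weight update uses the post-update $P$, which makes
every step a contraction of the instantaneous error.  $P$ is re-symmetrized
after each rank-one update because floating-point drift otherwise breaks
positive definiteness over $10^5$ updates.  $P$ converges to the
regularized inverse $(\alpha I + \sum r r^\top)^{-1}$, an identity the test
suite checks directly against a matrix-inverse oracle.

Defaults: $\alpha$ = 20, total training time 4 s (four traversals of the
teacher), chosen because the readout change per period is negligible after
3–4 periods at $N \geq 500$; an early-stop tolerance on $\|\Delta W\|$ per
period is available (`tol_dW`).  During training the feedback carries the
network's *own* readout $\hat z$ (classic FORCE); full teacher forcing is
available behind `teacher_feedback = TRUE`.  Because RLS clamps the error
from the first update onward, the two modes behave nearly identically here.
The teacher is sampled with zero-order hold at the update instants.  $A$
and $U$ are never modified; the trained network differs from the naive one
only through the rank-$M$ perturbation $U W$ of the effective coupling
$\Omega = A + UW$.

**Gain calibration.** The recurrent gain $g$ is the one free parameter
without a printed value but with a printed consequence: the population
rate of the trained networks (72–84 Hz for the circle, within 20–80 Hz
with per-petal excursions for the roses).  `calibrate_gain()` therefore
runs short teacher-forced simulations ($W = 0$, target fed back through
$U$) and bisects $g$ (geometrically) until the mean population rate hits a
target — 78 Hz for the circle and 50 Hz for the roses, the mid-points of
those bands.  The trained autonomous network closely tracks the
teacher-forced rate because its feedback reproduces the teacher.

## 4. Victor–Purpura distances and the rank-ordered matrix

`vp_distance()` implements the spike-time edit metric: insertion or
deletion of a spike costs 1, shifting a spike by $t$ costs $qt$, and the
distance is the minimal total cost, computed by the standard dynamic
program.  $1/q$ is the temporal precision of the implied coincidence
detector; at $q \to 0$ the metric degenerates to the spike-count
difference.  The package default is $q = 1\,\mathrm{s}^{-1}$ with spike
times in seconds over 1 s trials.  The tests verify the dynamic program
against exhaustive enumeration of all edit sequences for short trains and
the metric axioms (including the triangle inequality) on large random
suites.

`rank_order()` replaces the above-diagonal entries of $D$ by their ranks
$0, 1, \dots, N(N-1)/2 - 1$, mirrors them, normalizes by $N(N-1)/2$, and
reindexes neurons by descending firing rate.  Two conventions exist for
the rank direction, and the source descriptions of this construction are
not mutually consistent; the package default (`"descending"`) assigns rank
0 to the *largest* distance, so the larger the VP distance the smaller
$M_{ij}$ — the variant consistent with the produced matrices, where
low-rate neuron pairs (similar, nearly empty trains) carry the largest
entries.  The literal ascending variant is available via
`convention = "ascending"`.  Exact ties in $D$ are broken by lexicographic
pair order, and rate ties in the top-$k$ selection by the lower neuron
index, so the pipeline is deterministic.  The diagonal is excluded from
ranking and set to the convention-consistent extreme (1 under the default),
representing zero self-distance; the filtration ignores it either way.
Ranking is performed on the full $N \times N$ matrix first and the top-100
most active neurons are selected afterwards, matching the order of the
stages in the study design.  The same matrix $M$ that the rank stage
produces is fed to the filtration unchanged.

## 5. Persistent homology

`rips_persistence()` computes the Vietoris–Rips barcode of $M$ up to
dimension 1: vertices $i, j$ are joined once the filtration parameter
$\rho \ge M_{ij}$, and a triangle enters at the maximum of its three edge
values.  Dimension 0 is computed by union-find over the sorted edges —
all $n$ bars are born at 0, the $n-1$ finite deaths are exactly the
minimum-spanning-tree edge values, and one bar is essential (infinite).
Dimension 1 uses GF(2) column reduction of the triangle boundary matrix in
the edge basis: the reduced pivot edge (a cycle-creating edge) gives the
birth, the triangle the death.  A literal reading of "$\beta_1$ counts the
edges" would have no death events at all; what the barcodes and Betti
curves of one-dimensional features denote — here and in the TDA literature
this construction comes from — is homology of the clique filtration, with
cycles killed by triangles, and that is what is implemented.

Conventions: a bar is alive on $[\rho_b, \rho_d)$, so $\beta_0(0) = n$
whenever no off-diagonal entry equals 0.  (For a rank-ordered matrix one
pair has $M_{ij} = 0$ exactly, so the component count at $\rho = 0$ under
the half-open convention is $n - 1$ while the barcode still contains $n$
dim-0 bars, one of them zero-length; "bars alive at 0" in the endpoint
checks counts closed intervals.)  Zero-length dim-1 bars are dropped.
Betti curves are evaluated by default on 512 evenly spaced points of
$[0, 1]$, the range of the normalized $M$.  Infinite deaths are written to
CSV as the sentinel `inf`.

Correctness is established against two independently written oracles: a
full boundary-matrix GF(2) reduction of the whole clique filtration in
plain R, compared bar-for-bar on random 12–15 point matrices, and a
rank-based computation of $\beta_1(\rho) = E - n + \beta_0 -
\operatorname{rank}\partial_2$ at arbitrary filtration values, plus
hand-reduced cases (the unit square's single $H_1$ bar $[1, \sqrt2]$).

## 6. Surrogate rasters

`petal_modulated_raster()` generates rasters that emulate the statistical
structure of the trained networks without running training: $n$ neurons,
1 s trials, per-neuron inhomogeneous Poisson rates

$$\lambda_i(t) = \text{base} + \text{depth} \cdot
\max\!\big(0, \cos 2\pi (t - c_i)/T\big)^{c},$$

where each neuron's bump center $c_i$ sits on one of the $k$ petal windows
(cyclic assignment plus small phase jitter) and the concentration exponent
$c = 2k^2$ keeps the $k$ petal populations active in distinct phases.  The
depth is scaled so the population-averaged rate spans exactly the
configured band (20–80 Hz by default, baseline at the bottom, peak at the
top), giving exactly $k$ rise–fall excursions per trial.  Spikes are drawn
by thinning.  What the surrogates deliberately do *not* reproduce:
refractoriness (off by default, available for the homogeneous generator),
spike-timing correlations between neurons beyond shared rate modulation,
and the fine VP-matrix statistics of trained networks.  Tests that pass on
surrogates therefore validate the metric and topology stages, not the
training dynamics; the trained-network tests cover those separately.

## 7. Problem sizes, runtimes, determinism

The package's study configuration uses $N = 1000$ neurons (the
`pipeline_config()` default), which reproduces the qualitative and
quantitative observations — circle rates within 72–84 Hz, rose rates lower
with one excursion per petal, normalized circle RMSE well below 0.2 —
at about two minutes per trained network on one CPU.  The test suite
trains at $N = 1000$ once per shape where a trained network is required
and uses much smaller networks elsewhere; the acceptance script averages
three seeds per target.  All randomness flows through explicit seed
arguments (connectivity, initial state, training, surrogates); the C++
simulation core contains no random numbers, so identical configurations
and seeds give byte-identical rasters and CSVs.  Raster CSVs store spike
times with `%.17g`, so re-analysis of a stored raster reproduces distance
ranks exactly.

## 8. Known limitations

* Multi-petal roses can drift in phase during long autonomous generation;
  the pointwise RMSE then overstates the error even when the drawn figure
  is clean.  The circle does not drift appreciably.
* The three-petal rose's petals overlap as drawn (a fan on one side of the
  plane); this is a property of its defining equation, not of the
  implementation.
* Homology is computed only up to dimension 1, on the clique complex up to
  triangles; witness/alpha complexes and higher dimensions are out of
  scope.
* The multi-unit VP metric with a neuron-relabeling cost is out of scope;
  only the basic single-train metric is implemented.
* The gain calibration targets the mean teacher-forced rate; it does not
  constrain the rate *modulation*, which emerges from the feedback
  strength $q_{fb}$.
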