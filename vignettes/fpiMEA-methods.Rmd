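---
title: "Field potential imaging analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field potential imaging analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fpiMEA)
```

## The measurement model

Field potential imaging treats a dense CMOS MEA recording — hundreds of
thousands of 10.52 µm electrodes at ~10 µm pitch under a brain organoid
— as a spatiotemporal image of the extracellular potential. One
recording is a matrix `V[electrode, sample]` in µV, with a sampling
rate (2 or 10 kHz), a rectangular grid geometry, and, for assembloids,
a region label per electrode. `MEARecording` stores exactly this;
`ElectrodeGrid` fixes the index convention once for the whole package:
indices are **1-based and row-major** (the natural R convention; the
bijection `e ↔ (row, col) ↔ (x, y)` is property-tested), positions are
electrode centers in µm with the origin at electrode 1, and all
internal units are seconds, Hz, µV and µm.

Each analysis stage assumes the stage before it: detrending before
event detection, the 100 Hz high-pass before spike thresholding,
detected spikes before soma merging, soma trains before connectivity.
`runPipeline()` wires the stages in that order.

## Baseline stabilization and filtering

Slow drift is removed segment-wise: the trace is cut into consecutive
500-sample segments, the least-squares line is removed from each, and
the segment mean is subtracted. The trailing partial segment is
processed the same way (a single trailing sample is zeroed by the
offset step). The operation is idempotent and removes any
piecewise-linear baseline exactly; both properties are tested to
1e-9 µV.

All filters are linear-phase FIRs applied in their zero-phase
realization: the output equals a forward-backward pass (overall
response |B(ω)|², phase 0), computed as one FFT convolution with the
filter's autocorrelation after reflect-padding the trace by one filter
length. This keeps event peak times unbiased, which matters because
peak times *are* the propagation measurement. Corner frequencies are
taken as inclusive passband edges; the transition bandwidth defaults to
20% of the lower corner (minimum 0.5 Hz) and sets the tap count by the
Hamming-window rule `taps ≈ 3.3·fs/Δf` (odd, capped at 8191). A pure
in-band sinusoid passes with gain error < 10% and zero sample lag;
one octave outside the band attenuation exceeds 20 dB — both asserted
in the test suite rather than assumed.

For the low bands (delta/theta/alpha) at 2 kHz the Hamming rule would
demand >10⁴ taps, so traces are first decimated to ~200 Hz (zero-phase
anti-alias low-pass at 0.4 × the new rate, then integer subsampling)
and band-filtered at the reduced rate. This is a numerical-stability
choice, not a scientific one; band RMS values agree with analytic
sinusoid RMS to within the filter's passband ripple.

## Spike detection and soma identification

Spikes are threshold crossings of the 100 Hz high-passed trace at
**±5.0σ**, where σ is the baseline noise SD — the plain SD over a
user-supplied quiescent interval when one is given, otherwise the
robust estimate `median(|x|)/0.6745` (insensitive to the spikes
themselves). Each supra-threshold excursion yields one event at its
absolute peak (earliest sample on ties), with a 41-sample waveform
(20 before, 20 after, zero-padded at trace edges). Waveforms whose SD
is below 13 µV are discarded as noise.

Somas are reconstructed by merging electrodes that see the same cell:
for every electrode pair closer than 50 µm, coincidences are counted as
a **maximum one-to-one matching** of cross-electrode spikes with
|Δt| < 10 ms. A pair qualifies when the count is ≥ 5 *and* ≥ 15% of the
smaller train; qualifying pairs are edges of a merge graph and
connected components become somas ("same soma" is an equivalence, so
the < 50 µm rule is closed transitively). The soma position is the
spike-count-weighted centroid of its member electrodes, and its train
is the member union with events within 1 ms collapsed to the earliest
(the same action potential reaches neighboring electrodes with sub-ms
jitter). Three choices here were genuinely open and are this package's:

* the "15% of all possible pairs" denominator is `min(nA, nB)` — the
  maximum achievable matched count, which keeps the fraction in [0, 1];
* coincidences use one-to-one matching rather than all-pairs counting,
  so a burst cannot inflate the count quadratically;
* somas arise **only** from qualifying pairs. Only when no pair
  qualifies anywhere does the stage fall back to singleton somas
  (spiking electrodes with ≥ 5 events). A blanket per-electrode
  singleton rule was rejected: electrodes at the rim of a spike
  footprint collect a handful of noise-assisted threshold crossings and
  would masquerade as extra cells.

Network bursts — windows where nearly all cells fire together — would
likewise create spurious coincidences between distinct neurons, so
spikes inside detected burst windows are excluded from pairing. The
burst detector is deliberately simple: a 100 ms population-rate
histogram, burst seeds where the count exceeds mean + 3 SD, extension
across contiguous above-mean bins, windows shorter than 2 bins dropped.

The matcher itself is the sorted-time two-pointer sweep. For a
symmetric window this attains the maximum possible one-to-one matching
(ties always resolve toward earlier spikes and cannot reduce the
count), it is symmetric in its arguments, and the tests verify exact
agreement with an independent maximum-bipartite-matching oracle on
hundreds of random train pairs. A "closest-|Δt|-first" greedy was
rejected because it is not maximal (two trains {0, 3} and {2, 5} with a
2 s window match once under it, twice optimally).

## Surrogate-based connectivity

Synchrony between two soma trains is the matched-coincidence count
within ±100 ms — symmetric, because the connection graph is undirected.
Its null distribution comes from **ISI-preserving surrogates**: a
surrogate train is the first spike time plus the cumulative sum of a
random permutation of the original inter-spike intervals, so length,
span, and the exact ISI multiset are preserved while spike timing
relative to the partner is destroyed. Both trains are shuffled each
iteration (the stricter null). With 100 surrogates,
`z = (observed − mean)/SD`; `z ≥ 3` defines a functional connection.
When the surrogate SD is zero (perfectly regular trains), z is
reported as +∞/0/−∞ by the sign of the deviation and flagged
degenerate. Per-pair RNG substreams are derived from
`(seed, idA, idB)` so results do not depend on iteration order; an
optional pair cap subsamples reproducibly when the soma count makes
all-pairs computation (O(N²)·100 surrogates) unreasonable.

Calibration is tested, not assumed: on independent stationary Poisson
trains the fraction with z ≥ 3 stays ≤ 5%, and planted couplings
(probability 0.5, delay ≤ 50 ms) are detected in ≥ 90% of pairs.

Connection strength normalizes the synchronous count by the pair's
mean spike count, `count/((nA+nB)/2) ∈ [0, 2]`, and
`regionStrengths()` averages it over within-region and between-region
pairs of a labeled assembloid, the summary used for inter-regional
coupling effects.

## Propagation velocity and area

Network-wide slow oscillations are detected on the population trace
`mean(|V|)` smoothed over 50 ms: events are excursions above
median + 4·MAD lasting ≥ 0.2 s, extended outward to the flanking
sub-median crossings (the detector itself is this package's
construction; its parameters are exposed). Within an event,

* electrodes reaching **≥ 30 µV** are *propagating*, the rest are
  noise electrodes;
* each propagating electrode's **peak time** is the time from event
  onset to its absolute-voltage maximum (earliest sample on ties;
  absolute rather than signed, since slow waves may be
  negative-going);
* the **recruitment series** bins peak times at 5 ms and its counts
  sum to the electrode count by construction.

Velocity is read off the cumulative recruitment curve C(t). Counts in
a single 5 ms bin alias badly when wavefronts cross whole electrode
columns at near the bin period, so the primary estimate is the maximum
*windowed* secant slope of C inside the 10–90% recruitment range, with
window width one quarter of that range (at least one bin); the mean
slope over the same range is reported alongside, and a single-bin
recruitment degenerates to `total/bin` with a flag. On planted plane
waves this recovers wavefront speeds over a 4× range within ~4% and is
strictly monotone in the planted speed (tested at 0.5×/1×/2×).
Velocity is reported in electrodes/s — the natural unit of the
recruitment curve; conversion to µm/s requires a front-geometry model
and is therefore left to the caller.

Area is simply `n_propagating × electrode_area/10⁶` mm² (110.67 µm²
per electrode by default, 26.21 mm² for the full 236,880-electrode
array).

## Band maps and spatial clustering

Per electrode and band, amplitude is the RMS of the zero-phase
band-filtered trace over the analysis window ("amplitude" admits
several readings; RMS is stated once here and used everywhere). Bands
with fewer than 3 cycles of their lower corner in the window are
flagged unreliable; under one cycle the band is skipped with a
warning. Electrodes may be pre-filtered by a broadband RMS floor
(default 1 µV) so dead electrodes do not dominate the z-scaling; the
remaining amplitudes are standardized per band with the **sample** SD
(mean 0, SD 1 across electrodes, enforced to 1e-9). k-means in 5-band
z-space (default k = 9, 20 restarts, best inertia, fixed seed) assigns
each electrode a cluster; ids are relabeled by descending cluster size
so output is stable, and per-cluster mean profiles summarize the
spatial frequency structure. No automatic k selection is attempted —
k is an analysis choice, not an estimate.

## The synthetic generator as the validation instrument

Because FPI recordings of organoids are not publicly deposited, every
stage is validated against `simulateRecording()`, whose output is a
pure function of (config, seed):

* per-electrode Gaussian noise (default σ = 3 µV, a realistic baseline
  for platinum microelectrodes after detrending) plus optional linear
  and slow-sinusoid drift — exactly the structure the detrending stage
  removes;
* planted neurons with Gaussian spatial footprints (default σ = 15 µm,
  a soma-scale footprint spanning a handful of 10.52 µm electrodes),
  biphasic difference-of-Gaussians spike templates (~1.2 ms wide,
  negative peak exactly −peakAmp at the soma electrode; default
  18 µV = 6× the noise σ), Poisson firing (default 2 Hz) with
  multiplicative gain inside shared burst windows;
* propagating oscillation events: each electrode in the extent mask
  plays a *translated copy* of one carrier-times-Hann waveform delayed
  by distance/speed, so planted peak times are exactly affine in
  position and velocity recovery can be checked analytically;
* per-band spatial fields: band-limited unit-RMS noise carriers scaled
  by per-electrode amplitude maps generated from a planted partition —
  a recoverable target for the clustering stage;
* two-region assembloids: the grid split at a row into labeled halves,
  with directed couplings that convert pre-synaptic spikes into
  post-synaptic ones with probability `couplingProb` after
  `delayMs ± jitterMs`, parentage recorded.

Per-neuron RNG substreams make the voltage superposition property
testable (a two-neuron field equals the sum of the single-neuron
fields under zero noise). What the generator does **not** emulate —
and what passing tests therefore cannot certify on real data —
includes electrode-tissue coupling variability across the organoid
surface, correlated biological noise, bursting structure beyond shared
rate gain, spike waveform diversity across cell types, and volume
conduction. The generator validates the *algorithms*, not the biology.

## Statistics layer

Concentration-response endpoints are normalized per organoid to the
pre-treatment baseline (`100·value/baseline`) and compared with
one-way ANOVA (`F = MSbetween/MSwithin`, `η² = SSbetween/SStotal`)
followed by a two-sided Dunnett many-to-one test. The Dunnett adjusted
p is computed by Monte Carlo on the joint null of the k comparisons —
group means N(0, 1/n), a shared pooled variance χ²ν/ν, per-draw
maximum |T| — with 200,000 draws by default (MC SE ≤ ~0.0011) and a
precomputable null sample for repeated designs. The estimate is
clipped from below at the unadjusted two-sided t p-value so the
multiplicity inequality cannot be violated by MC noise. With a single
comparison the statistic reduces exactly to |t|, which the tests use
as one oracle; a reference Dunnett implementation is the second.
Cohen's d uses the pooled-SD definition and returns signed infinity
when the pooled SD vanishes with unequal means. Group sizes of n = 3
organoids are accepted but trigger a warning that variance estimates
at that size are unstable — the layer computes what is asked rather
than substituting a different design.

Type-I calibration is part of the suite: with four n = 3 groups drawn
from one normal distribution, the familywise rejection rate at
α = 0.05 stays ≤ 7% over 2000 replicates (MC tolerance included).

## Problem sizes and numerical conventions

The validation suite runs at desk scale by design: detection
recall/precision on a 32×32 grid, 60 s at 2 kHz with 30 planted
6σ neurons; soma recovery on 40×40 with 16 neurons ≥ 100 µm apart;
velocity on 40×40 plane waves sweeping the grid in 0.1–0.4 s; band
clustering on 18×18 at 500 Hz for 20 s. The full 420×564 default grid
is supported by the data structures but is never simulated in tests.
Degenerate inputs are contracts, not accidents: zero-σ traces refuse
thresholding, empty trains refuse z-scores, zero surrogate SD and
single-bin recruitment are flagged, zero baselines yield missing
normalized values, and empty groups are reported missing rather than
zero.

## Limitations

Spike sorting proper (separating multiple units on one electrode by
waveform shape) is out of scope, as are directed/causal connectivity,
propagation pathway reconstruction, vendor raw-file ingestion and
online analysis. The velocity unit is electrodes/s; physical front
speed requires geometric assumptions the package does not impose. All
calibration statements above are statements about the synthetic
conditions the suite actually runs.
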