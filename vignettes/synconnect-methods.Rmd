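---
title: "Methods: network inference and synthetic validation in synconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network inference and synthetic validation in synconnect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: what is being
modeled, which choices were genuinely open and how they were resolved, and
what the synthetic validation does and does not establish about real
recordings.

## 1. The analysis model

### Correlation networks

Functional connectivity is defined statistically: two neurons are
"connected" when their fluorescence time series co-vary more than chance
allows. The package uses Spearman's rank correlation because calcium
fluorescence is a nonlinearly compressed, indicator-filtered readout of
spiking — rank correlation is invariant to any monotone distortion of each
trace, so the inferred network does not depend on the normalization
pathway (`normalize_traces()` is provided for display, and a test asserts
the invariance).

For traces of length $n$, each pair gets $\rho_{ij}$ (mid-ranks for ties,
then Pearson on ranks) and a two-sided p-value from the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ df — the behaviour of common
statistical `corr` routines. Edges are kept at $p < \alpha$ (default
0.05) with no multiple-testing correction, mirroring common practice in
this literature; Benjamini–Hochberg is available behind
`p_adjust = "BH"`. Fields with fewer than four neurons are excluded
(strictly: a 4-neuron field is retained).

Two caveats are deliberate properties of this default, not oversights:

* **Autocorrelation.** The t approximation assumes exchangeable frames.
  Real (and synthetic) transients are autocorrelated at the indicator
  timescale, which inflates significance: in our simulations, control
  fields of independent *pacemaking* neurons show ~9–10% edge density at
  $\alpha = 0.05$, while fields of white-noise traces calibrate at the
  nominal 5% (the package's null-calibration test). A circular-shift
  permutation null (`p_method = "permutation"`) preserves each trace's
  autocorrelation and is the conservative alternative; it is not the
  default because the asymptotic p is what the common tooling computes.
* **Edge weights.** Binary adjacency is what significance gating natively
  produces, yet the standard weighted metric definitions expect
  nonnegative weights. The default `weighted_positive` mode carries
  $\rho$ on significant positive edges (negative significant correlations
  are excluded); `weighted_signed` and `binary` modes exist. Both the
  weighted and binary readings of each metric are computable, and
  `network_metrics()` reports density on A and strength/clustering/
  efficiency on W.

### Graph statistics

All metrics follow the standard brain-connectivity definitions:

* **Normalized node degree** divides by $N$, the total number of nodes —
  not $N-1$ — so it reads as "average connections per neuron". This is a
  deliberate convention choice (the `n_minus_1` option gives the textbook
  normalization); with it, the maximum attainable value is $(N-1)/N$.
* **Clustering** defaults to Onnela's weighted geometric-mean form with
  weights rescaled to $[0,1]$ by the network maximum; the binary triangle
  form is available.
* **Global efficiency** uses lengths $L_{ij} = 1/W_{ij}$ and Dijkstra
  shortest paths; disconnected pairs contribute 0 (the standard
  convention when a network fragments).
* **Above-mean strength fraction** uses a strict inequality, so a
  perfectly regular network (all strengths equal) has fraction 0.

Every metric is checked against an independent brute-force oracle
(edge-list summation, triangle triple-enumeration, Floyd–Warshall) —
exhaustively over all labelled graphs on 3–4 nodes and on random 5–6-node
graphs — and cross-checked against igraph where applicable.

### The spatial control

If functional edges merely reflected optical crosstalk or shared
neuropil, correlation would decay with inter-ROI distance. The control
pairs every unordered neuron pair's Euclidean centroid distance with its
$\rho$ and tests the association by a two-sided Spearman correlation. One
subtlety matters for interpreting it: the $N(N-1)/2$ pairs share neurons
and are therefore not independent, so at small $N$ the association
statistic is noticeably heavier-tailed than its nominal null — even for
fields that are spatially random by construction. The package's
validation therefore runs this control on 40-node fields (the upper end
of realistic per-field ROI counts), where the diagnostic behaves
nominally; on very small fields a "significant" distance association
should be read with this caveat in mind.

### Statistical unit

Group comparisons (`compare_conditions()`, default equal-variance
two-sample t-test; Welch and one-way ANOVA available) treat the **node**
as the unit of inference, matching how such data are commonly reported.
Nodes within a field are not independent — this is pseudo-replication,
acknowledged rather than hidden; per-field summaries are available from
`glance()` on each `network_metrics` object for a conservative
field-level analysis.

## 2. The synthetic generator

The generator is first-class, tested code: it defines the study
conditions under which every end-to-end claim in the test suite is
evaluated.

### Fluorescence kernel

The indicator impulse response is a double exponential
$h(t) = A\,(1-e^{-t/\tau_r})\,e^{-t/\tau_d}$ — only the half-rise
(6.6 ms) and half-decay (87 ms) times of the fast indicator are published
constraints, and the double exponential is the minimal form with
independent rise and decay limbs. Since the half-times are coupled
functions of both constants, `calibrate_kernel()` alternates 1-D root
solves until both measured half-times are within 0.1% of target; an
independent dense-grid measurement (`kernel_half_times()`, 0.01-ms grid)
verifies calibration to 1% in the tests. The calibrated constants come
out near $\tau_r \approx 16$ ms, $\tau_d \approx 104$ ms; the peak is
normalized to 1, which fixes the fluorescence unit.

### Spiking and correlation structure

Background activity is jittered-periodic pacemaking: gamma-renewal
inter-spike intervals with mean $1/r$ and CV `jitter_cv` (default 0.2).
Per-neuron rates default to Uniform(1, 5) Hz — the imaged populations'
rates are not published, and this brackets typical midbrain dopamine
pacemaking. Correlation is injected *only* through shared latent events:
each ensemble's events arrive as a Poisson process and each member fires
one extra spike per event with its participation probability (10-ms
timing jitter). Event-driven correlation was chosen over common-input
Gaussian noise because the downstream analysis operates on event-driven
fluorescence transients; it produces realistic positively correlated
transients rather than correlated baselines.

The default **hyperconnected** condition partitions the field into
ensembles of ~5 neurons, each with shared-event rate 0.5 Hz and
participation 0.6; the **control** condition has no ensembles. Under the
default pipeline this yields gated densities of roughly 0.25 versus 0.10
— a clear but not saturated contrast. ROI centroids are placed uniformly
at random in a 300 µm field, independent of ensemble membership, so any
distance–correlation association in synthetic data is spurious by
construction.

### Rendering

Spike trains are convolved with the kernel at 0.5-ms internal resolution,
bin-averaged down to the frame rate (20 fps default; the internal rate
must be an integer multiple, so 20 and 25 fps both work), and i.i.d.
Gaussian noise (default sd 0.1, i.e. 10% of a single-transient peak) is
added per frame. A conservation test checks that noise-free fluorescence
mass equals spike count × kernel integral. Not modeled, deliberately:
photobleaching, baseline drift, movement artifacts, ROI segmentation
errors, and spike-to-fluorescence nonlinearity (indicator saturation).
Passing tests on this generator therefore validate the *analysis* under
its stated assumptions; they do not certify robustness to those
real-data pathologies.

### Patch-clamp sweeps

Current-clamp sweeps place a stylized action potential — a biexponential
spikelet, time-rescaled so its full width at half maximum equals the
requested half-width, peak-normalized — on a flat resting potential. Only
threshold-crossing detection and flank geometry need to work on it; no
conductance-based model is attempted. The hyperpolarization-challenge
sweep is 30 s free firing, 30 s clamped at −100 mV, 30 s recovery at
`recovery_multiplier` times the baseline rate (with `jitter_cv = 0` the
planted spike counts are exact, giving exact percent-change values). The
capacitance-ramp sweep integrates the single-compartment RC cell
$I = C_m \dot V + (V - V_\mathrm{rest})/R_m$ under the triangular
command; with series resistance the cell voltage is integrated with an
exact exponential update against the midpoint command value (a naive
end-of-step update biases the ramp plateau by half a sample, which is
measurable at these tolerances).

## 3. Electrophysiology analysis choices

* **Spike criterion**: upward crossing of −20 mV, 2-ms refractory. No
  published criterion exists for these recordings; this is a
  conventional, conservative choice for broad dopamine-neuron spikes.
* **Half-width baseline**: the *median* of the 10 ms preceding the
  threshold crossing. A mean is biased upward when the window clips the
  foot of the rising flank; the median recovers exact geometry on planted
  triangular spikes.
* **Capacitance factor of 2**: the printed estimator form
  $C_m = \Delta I/(dV/dT)$ recovers $2C_m$ when $\Delta I$ is the full
  rising-minus-falling current separation, because the capacitive current
  reverses sign between limbs while the leak, identical at matched
  voltages, cancels. The implementation uses
  $C_m = \Delta I / (2\,dV/dT)$, which recovers simulated ground truth
  exactly; whether the original formula intended $\Delta I$ as the
  half-separation is not decidable from its statement, so the package
  documents the factor rather than silently matching either reading.
* **Central portion**: currents are averaged over the central 50% of each
  limb ("central" is otherwise unquantified); by then clamp transients
  (time constant $R_s C_m \sim 1$ ms for typical values) have settled.
  The resulting estimate is leak-invariant to <1% across
  $R_m \in \{100\,\mathrm{M\Omega}, 1\,\mathrm{G\Omega}, \infty\}$ and
  shifts <5% under 10 MΩ of series resistance for high-$R_m$ cells. For
  leaky cells the residual sensitivity scales as $(R_m/(R_m+R_s))^2$ —
  an intrinsic property of ramp estimators, worth remembering when
  $R_m$ is low.
* **Resilience**: percent change is undefined when the baseline is
  silent ($f_\mathrm{pre}=0$); such records are flagged, never imputed.

## 4. Numerical and degenerate-input conventions

* Constant traces: rank correlation undefined → recorded as
  $\rho = \mathrm{NA}$, $p = 1$ (never significant), with a warning; the
  neuron stays in the field.
* Min-max normalizing a constant trace maps it to zeros (flagged).
* Raster bins are half-open $[lo, hi)$; the final partial bin is kept
  (250 s at 100-s bins → bins of 100, 100, 50 s); an event exactly on an
  edge belongs to the later bin.
* Degenerate group comparisons (both groups constant) return $t = 0$,
  $p = 1$ when equal, $\pm\infty$, $p = 0$ when not, rather than erroring
  mid-pipeline.
* Both-constant distance-control vectors → NA association, flagged
  non-significant.
* All simulation randomness descends from one integer seed through fixed
  substreams; identical configurations are bit-identical, and simulation
  calls restore the caller's RNG state.

## 5. Validation problem sizes

The test suite evaluates: kernel calibration on a 0.01-ms grid;
hyperconnectivity recovery on one control + one hyperconnected 20-neuron,
250-s field; null edge-rate calibration on 50 ten-neuron noise fields
(2,250 pairs, 99% binomial band around 0.05); metric-oracle equivalence on
all 3–4-node graphs plus 60 random 5–6-node weighted graphs; capacitance
recovery across three leak settings; resilience power over 20 replicate
cohorts of 10 impaired (multiplier 0.4) vs 10 intact sweeps; and the
distance control over 20 hyperconnected 40-neuron fields. These sizes are
the package's validation design: large enough for each check's stated
statistical bound, small enough to run routinely.

## 6. Known limitations

* Events are threshold-defined; no deconvolution or spike inference is
  attempted, and event times inherit frame-rate resolution.
* The asymptotic edge p-values are anticonservative under autocorrelation
  (see §1); group contrasts of *differences* between conditions are
  affected much less than absolute densities.
* Node-level inference pseudo-replicates within fields.
* The generator's noise model is additive white Gaussian; conclusions
  about robustness to drift, bleaching, or segmentation artifacts are out
  of scope.
* GraphML/GEXF export encodes the gated network only (no layout,
  no per-node metric attributes).
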