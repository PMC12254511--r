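# synconnect

Functional connectivity and single-neuron physiology of midbrain dopamine
networks, from calcium-imaging traces and patch-clamp sweeps.

## The problem

Midbrain dopamine neurons of the substantia nigra pars compacta (SNc) fire
spontaneously (pacemaking) and degenerate selectively in Parkinson's
disease, while their neighbors in the ventral tegmental area (VTA) are
largely spared. Before any cell death is detectable, α-synuclein burden
changes how these neurons fire and how coordinated their population
activity is. Quantifying those early changes requires two kinds of
analysis:

* **Population level** — from somatic calcium-indicator recordings
  (neuron-by-frame fluorescence matrices with ROI centroids), infer a
  functional connectivity network per imaged field and compare its graph
  statistics between conditions.
* **Single-neuron level** — from current- and voltage-clamp sweeps,
  measure spontaneous firing frequency, action-potential half-width,
  membrane capacitance, and the ability to resume pacemaking after a
  prolonged hyperpolarization.

`synconnect` implements both pipelines, plus a fully seeded synthetic-data
generator that emulates the recording conditions (250-s fields at
20–25 frames/s, fast-indicator kinetics, stylized patch protocols) so
every stage can be validated against known ground truth without any
experimental data.

## The model

**Networks.** For every neuron pair the Spearman rank correlation
ρ<sub>ij</sub> of the fluorescence traces is computed (mid-ranks for ties,
Pearson on ranks), with the two-sided p-value from
t = ρ√((n−2)/(1−ρ²)) on n−2 df (a circular-shift permutation null is
available). An edge is kept when p < α (default 0.05) and ρ > 0; the
weight matrix W carries ρ on kept edges, the adjacency A its binary
support. Fields with fewer than four neurons are excluded. From the gated
network the package computes, per the standard brain-connectivity
definitions:

* degree k<sub>i</sub> = Σ<sub>j</sub> A<sub>ij</sub> and **normalized
  node degree** k<sub>i</sub>/N (division by N, not N−1),
* node strength s<sub>i</sub> = Σ<sub>j</sub> W<sub>ij</sub> and the
  fraction of nodes above mean strength,
* clustering coefficient (binary triangle form, or Onnela's weighted
  geometric-mean form on max-rescaled weights),
* network density D = Σ<sub>i<j</sub> A<sub>ij</sub> / (N(N−1)/2),
* global efficiency E = mean over pairs of 1/d<sub>ij</sub>
  (Dijkstra shortest paths on lengths 1/W<sub>ij</sub>; disconnected
  pairs contribute 0),

and a spatial control: the Spearman association between inter-centroid
distance and pairwise correlation, which should be null when connectivity
is not a spatial artifact.

**Electrophysiology.** Spikes are upward crossings of −20 mV with a 2-ms
refractory; half-width is measured at half of (peak − local baseline) with
linear interpolation on both flanks. Resilience to a hyperpolarization
challenge (30 s baseline, 30 s at −100 mV, 30 s recovery) is the percent
change 100·(f_post − f_pre)/f_pre. Membrane capacitance comes from a
triangular voltage ramp (−70 → −80 → −70 mV, 50 ms per limb): the current
separation ΔI between the two limbs, averaged over each limb's central
portion, cancels the leak and gives C_m = ΔI / (2·dV/dT).

## Worked example

Simulate a control and a hyperconnected field under the default study
conditions (20 neurons, 250 s at 20 fps) and run the whole pipeline:

```r
library(synconnect)

ctrl <- sim_config(seed = 11, n_neurons = 20, condition = "control")
hyp  <- sim_config(seed = 12, n_neurons = 20, condition = "hyperconnected")
bundle <- run_pipeline(ctrl, hyp)
bundle
#> <synconnect_bundle>
#>   a (control): 20 neurons, 18 edges, density 0.095
#>   b (hyperconnected): 20 neurons, 50 edges, density 0.263
#>   degree_norm: mean a 0.0900 vs b 0.2500, t = 9.080, p = 4.65e-11
```

The hyperconnected field — whose neurons share latent activation events in
small ensembles — shows a mean normalized node degree of 0.25 versus 0.09
in the control field, a difference the node-level t-test calls highly
significant. The spatial control confirms connectivity is not a proximity
artifact:

```r
glance(bundle$distance_controls$b)
#> # A tibble: 1 × 4
#>   estimate p_value n_pairs significant
#>      <dbl>   <dbl>   <int> <lgl>
#> 1 -0.00586   0.936     190 FALSE
```

Single-neuron tools work the same way on synthetic sweeps with known
ground truth — here a 100-pF cell with a 100-MΩ leak is recovered exactly,
and a neuron whose recovery rate is 40% of baseline shows the expected
collapse in the resilience statistic:

```r
estimate_capacitance(simulate_sweep("capacitance_ramp", cm_pf = 100, rm_mohm = 100))
#> # A tibble: 1 × 6
#>   cm_pf di_pa dv_mv dt_ms dvdt_v_per_s central_fraction
#> 1 100.0  40.0    10    50          0.2              0.5

challenge_resilience(simulate_sweep("hyperpolarization_challenge",
                                    seed = 5, rate_hz = 2,
                                    recovery_multiplier = 0.4))
#> # A tibble: 1 × 6
#>   f_pre_hz f_post_hz percent_change n_pre n_post flagged
#> 1     1.97       0.8          -59.3    59     24 FALSE
```

Every result type has `tidy()` / `glance()` accessors returning tibbles
and an `autoplot()` method (stacked traces, binned rasters, adjacency
heatmaps, metric histograms, distance-control scatterplots).

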