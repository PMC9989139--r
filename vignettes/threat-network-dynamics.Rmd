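---
title: "Dynamic oscillatory network analysis of threat processing: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic oscillatory network analysis of threat processing: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`threatnets` implements a pipeline for studying how large-scale brain
networks reorganize during instructed threat processing, starting from
epoched source-level EEG time series. The data model is a cohort of subjects,
each observed under two conditions — a threat-conditioned stimulus (CS+) and
a safe stimulus (CS−) — with multiple trials per condition. Each trial is a
region-of-interest (ROI) × time matrix sampled at 250 Hz over an epoch from
−0.25 to 1.5 s around stimulus onset. The default parcellation has 90 ROIs
(45 bilateral pairs) grouped into six anatomical baseline communities
(frontal, sensorimotor, temporal, occipital, subcortical, parietal), with
membership lists for the three functional networks that emerge after
stimulus onset: the central executive (CEN), salience (SN) and default mode
(DMN) networks.

One transcription note: the parcellation table we work from lists 56
bilateral pairs (112 labels) while the pipeline is defined for 90 ROIs. The
package resolves this deterministically: `roi_table()` drops the lateral
ventricle (not a neural source) and ten fine gyrus-subdivision pairs,
keeping one representative division per gyrus and every CEN/SN/DMN member;
`roi_table(full = TRUE)` exposes the complete transcription.

The analysis proceeds in stages, each usable on its own:

1. **Preprocessing** — zero-phase fourth-order Butterworth band-pass
   (default 3–45 Hz), window bookkeeping, condition contrast, and an
   inter-trial phase coherence (ITPC) quality check.
2. **Connectivity** — band-limited power-envelope correlation matrices per
   window (theta 4–8 Hz, alpha 8–12 Hz), proportionally thresholded over a
   20-point density grid spanning 0.1–0.6.
3. **Communities** — consensus Louvain modularity maximization at baseline,
   a resolution (γ) sweep, and dynamic assignment across time-window layers
   with an inter-layer coupling ω.
4. **Topology** — flexibility, clustering coefficient, global and local
   efficiency per window, condition and density.
5. **Effective connectivity** — time-resolved partial directed coherence
   (TPDC) from a dual-Kalman time-varying MVAR fit, with time-reversal
   surrogate significance and uni/bi-directionality classification.
6. **Inference** — paired t-tests, two-way within-subject ANOVA
   (condition × time) with Mauchly/Greenhouse–Geisser handling, post hoc
   window contrasts, and Bonferroni-corrected Pearson correlations with
   behaviour (threat ratings, heart rate).

## Window conventions

Windows are the baseline (−250 to 0 ms) and six contiguous 250-ms windows
T1–T6 covering 0–1500 ms. At 250 Hz neither 250 ms nor 50 ms is an integer
number of sample periods, so a convention is fixed once: a time t relative
to stimulus onset maps to the sample offset `round(t * fs)` and windows are
half-open `[start, end)`. Under this rule the baseline holds 62 samples, the
six post-stimulus windows partition 375 samples with no gaps or overlaps,
and each 250-ms window splits exactly into five 50-ms subwindows (12–13
samples each). Those five subwindows are the layers on which dynamic
community assignment — and hence flexibility — is computed within each
window (T = 5 layers, 4 transitions).

## Connectivity construction

"Power" is the squared modulus of the analytic signal of the band-filtered
series — the standard source-level envelope construction. Envelope
correlation is Pearson correlation over a window's samples. Two pooling
modes exist because 50-ms subwindows contain only 12–13 samples: the default
concatenates per-trial demeaned samples across trials before a single
correlation (`pool_trials = TRUE`), which stabilizes the tiny per-window
estimate; the alternative averages per-trial correlations through Fisher's
z. The absolute value is taken before thresholding — proportional density
thresholding of signed weights is otherwise ill-defined, and envelope
anticorrelations are rare. Proportional thresholding keeps the
`ceiling(d · N(N−1)/2)` largest edges; ties at the cut are broken by (row,
column) lexicographic order so the edge sets are exactly nested across the
density grid, which in turn makes global efficiency and clustering
monotone along the grid by construction.

## Community detection

Single-layer detection maximizes Newman–Girvan modularity with resolution γ
via the Louvain algorithm (igraph backend), with the node order randomized
per seed. Because Louvain is stochastic, every partition we report is a
*consensus* over repeated runs (the reference regime is 5000 iterations;
tests and examples use 30–200): runs are aligned to the highest-modularity
run by greedy maximal-overlap matching on the contingency table, the
consensus label is the per-node mode, per-node *stability* is the modal
fraction, and the *module allegiance* matrix accumulates how often node
pairs share a community. Labels are renumbered by descending community size
for reproducibility; singleton communities are allowed.

Dynamic assignment across layers supports two regimes. With ω = 0 each
layer is partitioned independently and labels are matched across
consecutive layers. With ω > 0 we optimize a categorical multilayer
modularity: the quality matrix contains each layer's Newman–Girvan block on
the diagonal and an identity coupling of weight ω between every pair of
layer copies of a node, and the coupling deliberately does **not** enter
the degree-based null term. This matrix is optimized by a generalized
Louvain (greedy local moves plus aggregation) written for this package,
because the adjacency-based Louvain in igraph cannot exclude coupling edges
from its null model — a distortion we measured to be severe. Larger ω
favours temporally consistent labels; ω = 1 is the default and ω ≈ 0.5 is a
good operating point for strongly modular layers (planted-switch
simulations recover 10/10 switching nodes there, while ω ≥ 2 freezes
genuine switches).

Detected communities are named by Jaccard overlap against the fixed
CEN/SN/DMN and anatomical membership lists (`name_communities()`).

## Topology metrics

All four metrics are bounded in [0, 1] and computed on the binarized
thresholded graphs (density-grid comparability requires fixed edge
counts):

* **Flexibility** f_i is the fraction of inter-layer transitions at which a
  node changes community; 0 is maximal rigidity, 1 maximal flexibility. The
  network statistic F is the node mean.
* **Clustering** C_i = triangles_i / (k_i(k_i−1)/2), with C_i = 0 for
  degree < 2.
* **Global efficiency** is the mean inverse shortest-path length over
  ordered pairs; disconnected pairs contribute 0.
* **Local efficiency** of a node is the global efficiency of the subgraph
  induced on its neighbours (node excluded), 0 for degree < 2. We compute it
  on the induced subgraph only, the common convention.

Graphs whose largest component covers less than 90% of nodes are flagged
fragmented but kept, so the density grid always yields 20 rows per metric.

## Time-resolved effective connectivity (TPDC)

A time-varying MVAR model x_t = Σ_r A_r(t) x_{t−r} + e_t is estimated by a
dual Kalman filter: a state filter over the stacked signal vector whose
transition is the companion form of the current coefficients, coupled with
a weight filter over vec(A) under random-walk dynamics with process noise
q. The innovation covariance is adapted online by exponential smoothing.
Partial directed coherence is then evaluated per sample:
π_ij(f, t) = |Ā_ij(f, t)| / sqrt(Σ_k |Ā_kj(f, t)|²) with
Ā(f, t) = I − Σ_r A_r(t) e^{−i2πfr/fs}, so squares sum to one over targets
for every source, frequency and time — an identity the tests verify to
1e−10.

Numerical choices that matter:

* **q (default 4e−5)** sets the tracking/variance trade-off. Because PDC is
  a magnitude, zero-mean estimation wander folds into a *positive* bias on
  truly-absent links; we therefore apply a centred moving average (default
  101 samples) to the coefficient trajectories. With these defaults a
  planted coefficient step 0 → 0.5 is crossed at half-height within ~150
  samples and settles within ±0.15, while on stationary data the
  time-averaged TPDC agrees with the PDC of an ordinary-least-squares MVAR
  fit to ≈0.05 RMS. Raising q tracks faster at the cost of a higher noise
  floor.
* **Model order** defaults to 5 at 250 Hz; `select_order()` offers BIC/AIC
  selection, and simulations with known AR(2) generators recover order 2.
* **Operating regime**: single epochs are short (438 samples), so TPDC is
  intended for small ROI subsets (the 4–10 nodes of a named network), fitted
  per trial and averaged at the summary stage; fitting all 90 ROIs jointly
  is out of scope.
* A burn-in of 5·order samples after the initial lags is treated as
  transient.

Significance uses **time-reversal surrogates**: reversal preserves spectra
but destroys directed temporal structure. With multiple trials each
surrogate reverses and bootstrap-resamples the trials; with a single trial,
distinct null draws are produced by independent per-channel circular shifts
of the reversed series (this also removes zero-lag coupling, which PDC does
not measure anyway). A directed pair is significant when
p = (1 + #{null ≥ observed}) / (n_surrogates + 1) falls below α (reference
setting 1000 surrogates at α = 0.001; calibration simulations use 200 at
0.05, where the measured false-positive rate is ≈0.05 and power for a
planted 0.5 coupling over 400 samples is >0.9 with correct orientation).
Pairs are then classified none / uni-directional (with orientation) /
bi-directional.

## Statistics

The behavioural layer is a paired t-test (two-sided, α = 0.01 by
convention) with explicit degenerate handling (zero-variance differences
return an NA t flagged degenerate rather than an error or a fake
significance). Network metrics enter a two-way within-subject ANOVA with
factors condition and time via the multivariate linear-model route
(`car::Anova`), reporting Mauchly's sphericity p and Greenhouse–Geisser
corrected p for effects with more than one numerator df. Metric values are
averaged across the 20 densities per cell before testing; treating density
as a replicate is possible by passing the per-density rows directly, but is
not the default because the density grid is a robustness sweep, not
independent replication. Shapiro–Wilk normality is reported, non-gating.
Post hoc window contrasts (consecutive pairs, or each window versus
baseline — six contrasts either way) are Bonferroni-corrected, as are the
behaviour correlations. The condition contrast is defined CS+ − CS− (threat
minus safe) throughout, and per-condition tables are always retained
because the ANOVA needs the condition factor.

## The synthetic cohort generator

No deposited data exist for this design, so the generator is a first-class
module that plants every feature the analysis is supposed to recover:

* **Oscillations**: each ROI is a sum of damped AR(2) oscillators, one per
  band (theta centred at 6 Hz, alpha at 10 Hz, pole modulus 0.95), giving
  controllable band power and a valid MVAR ground truth. Amplitudes are in
  innovation units and carry no physical scale; we deliberately do not
  re-normalize, so stationary least-squares fits recover planted coupling
  coefficients exactly rather than up to a variance ratio.
* **Directed coupling**: lagged cross-terms between same-band components
  with a configurable time profile. Stability is checked at generation time
  via the companion spectral radius of the worst-case configuration, and an
  unstable specification is refused with the offending coupling named. Note
  that purely feed-forward (triangular) coupling can never destabilize the
  system; instability requires reciprocal loops.
* **Stimulation**: an optional perturbation multiplies coupling
  coefficients transiently (default onset 1000 ms), a mechanistic stand-in
  for a single TMS pulse at the physiologically relevant latency.
* **Community dynamics**: planted label timelines start from the six-block
  anatomical partition; at each layer a node switches with the condition's
  probability to a *different* label, so expected nodal flexibility equals
  the switching rate exactly. Defaults are 0.4 under CS+ and 0.2 under CS−,
  with a quiet baseline (0.05).
* **Behaviour**: ratings and heart rate share a latent factor (planted
  correlation 0.5), carry a CS+ − CS− shift (2.0 rating points, 5 bpm), and
  load on the subject's switching-rate deviation with coefficient 0.6 so a
  behaviour–flexibility correlation is plantable and recoverable.
* **Design sizes**: 36 CS+ and 24 CS− trials per subject, epochs of 438
  samples.

What the generator does **not** emulate: sensor-level EEG, volume
conduction and source leakage, artefacts (ocular, muscle, stimulation
ringing), non-stationary noise floors, and anatomically realistic
connectivity profiles. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under their own model
assumptions — not robustness to the full messiness of real recordings.

## Validation strategy and problem sizes

Every metric with an exact combinatorial definition is tested against an
independent brute-force oracle (transition counting, triangle enumeration,
BFS shortest paths, modularity double sums) on hundreds of random
instances, alongside analytic fixed points (complete graphs, paths,
disconnected triangles). Estimators are validated by planted-ground-truth
simulation: 60-node six-block graphs for consensus recovery (adjusted Rand
index ≈0.96, mean stability ≈0.99 at 200 iterations), switching-rate
recovery to ±0.03 over 500 seeds, and a 20-subject cohort recovery of the
condition effect on flexibility (p < 0.01 in ≥80% of replicate cohorts) and
of the planted behaviour–flexibility correlation. These sizes were chosen
as the smallest that make the statistical assertions stable; the reference
regime of the full design (5000 consensus iterations, 1000 surrogates) is
configurable but not exercised by the default test run.

## Known limitations

* The ω > 0 multilayer optimizer is a greedy local-move scheme; like all
  Louvain-family methods it finds local optima, which the consensus step
  mitigates but does not eliminate.
* Coupling across *subjects* (as opposed to across time layers) is not
  implemented; the per-subject pipeline couples layers in time.
* TPDC assumes an (locally) linear MVAR generating process; strong
  nonlinearity or unmodelled common input can produce spurious directed
  links, only partly guarded against by the surrogate test.
* The surrogate null in the single-trial regime relies on circular shifts
  for variability; with very short series the null can be conservative.
* Weighted-graph metric variants, participation coefficients and
  small-world indices are out of scope.
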