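# threatnets

Dynamic oscillatory brain-network analysis of instructed threat processing,
for researchers studying how large-scale cortical–subcortical networks
reorganize when a stimulus predicts threat. The package takes epoched
source-level EEG time series (ROI × time per trial, two conditions CS+/CS−)
and quantifies:

* **Band-limited connectivity** — theta (4–8 Hz) and alpha (8–12 Hz)
  power-envelope correlation matrices per 250-ms window, proportionally
  thresholded over 20 densities in [0.1, 0.6];
* **Community dynamics** — consensus Louvain modularity maximization
  (resolution γ, inter-layer coupling ω optimized by a generalized Louvain
  over the categorical multilayer quality matrix), with per-node stability
  and module-allegiance matrices;
* **Topology** — flexibility
  `f_i = (1/(T−1)) Σ_q 1[Q_{i,q} ≠ Q_{i,q+1}]`, clustering coefficient
  `C_i = 2·triangles_i / (k_i(k_i−1))`, global efficiency
  `GE = (1/n(n−1)) Σ_{i≠j} d_ij⁻¹` and neighbourhood local efficiency;
* **Effective connectivity** — time-resolved partial directed coherence
  `π_ij(f,t) = |Ā_ij(f,t)| / sqrt(Σ_k |Ā_kj(f,t)|²)`, with
  `Ā(f,t) = I − Σ_r A_r(t) e^{−i2πfr/fs}` and the time-varying coefficients
  `A_r(t)` estimated by a dual Kalman filter (coupled state and weight
  filters, random-walk coefficient dynamics), significance by time-reversal
  surrogates, and uni/bi-directionality classification;
* **Inference** — paired t-tests, two-way within-subject ANOVA
  (condition × time) with Mauchly/Greenhouse–Geisser handling, Bonferroni
  post hocs, and behaviour correlations (threat ratings, heart rate).

Because no public dataset exists for this design, the package ships a
first-class synthetic cohort generator (`synthetic_config()`,
`generate_cohort()`) that plants oscillatory bands, directed coupling,
per-window community switching with condition-dependent rates, an optional
stimulation-like perturbation at 1000 ms, and correlated behavioural
covariates — with full ground truth, so every estimator is validated by
recovery tests.

## Worked example

The numbered scripts under `analysis/` run the full workflow at desk scale
and narrate what they find. `analysis/01_simulate.R` generates a 6-subject,
20-ROI cohort and tests the planted behavioural effects:

```
    variable mean_csplus mean_csminus    t       p significant
1     rating        7.15         5.12 4.94 0.00431        TRUE
2 heart_rate       74.42        71.31 1.85 0.12379       FALSE
rating-heart correlation within CS+: r = 0.87 (planted ~0.5, n = 6)
```

(the heart-rate effect is real but under-powered at n = 6 — by design for a
quick demonstration). `analysis/03_topology_stats.R` measures flexibility
from the planted community timelines (switch rates 0.4 under CS+ vs 0.2
under CS−) and runs the condition × time ANOVA:

```
          effect     F df_num df_den      p
1      condition 13.53      1      5 0.0143
2           time  1.37      5     25 0.2681
3 condition:time  1.17      5     25 0.3496
behaviour-flexibility correlation (CS+): r = 0.77 (planted 0.6)
```

The threat condition raises network flexibility (F(1,5) = 13.5), with no
spurious time or interaction effect, and the planted behaviour–flexibility
coupling is recovered. `analysis/04_tpdc.R` estimates TPDC on the planted
coupled pairs (theta-band coefficients 0.4 from node 1→2 and 3→4):

```
theta T1 mean TPDC for the planted pairs (1->2, 3->4) vs reverse:
  1->2: 0.726   2->1: 0.102
  3->4: 0.764   4->3: 0.091
```

The planted directions dominate their reversals by a factor of ~7, and the
time-reversal surrogate test classifies both pairs as uni-directional with
the correct orientation.

See `vignettes/threat-network-dynamics.Rmd` for the model assumptions,
parameter defaults (γ, ω, the density grid, the Kalman process noise q and
coefficient smoothing) and the validation strategy.

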