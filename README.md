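# thfish

Quantification and analysis of single-molecule FISH (smFISH) data for
early T-helper-cell differentiation, built around the observation that
naive CD4 T cells co-express the antagonistic lineage transcription
factors *Tbx21* (Th1) and *Gata3* (Th2) while their hallmark cytokines
*Ifng* and *Il4* fire in rare, strongly bursting cells.

The package is aimed at quantitative biologists who want to

* turn 3-D fluorescence image stacks into per-cell transcript counts
  (marker-guided watershed segmentation of bright-field images,
  Laplacian-of-Gaussian spot detection with automatic threshold
  selection, and fluorescence-based extrapolation of cells too crowded
  to resolve),
* characterize joint transcription-factor states with a
  polar-coordinate statistic, and
* infer transcriptional burst parameters under the two-state
  (telegraph) model of transcription,

with a synthetic-data generator that renders full microscopy scenes
with known ground truth, so the entire pipeline is testable without any
external data.

## The statistics at the core

**Polar cell-state statistic.** Each cell's joint counts *(t, g)* of
*Tbx21* and *Gata3* are mapped to *r* = √(t² + g²) and
θ = arctan(g/t) ∈ [0, π/2]. θ near 0 is Th1-like, near π/2 Th2-like.
Cells with *r* < 10 are excluded because θ is not robust at low counts.
A uniform θ distribution means cells populate every intermediate state
(no mutual exclusion); a U-shaped distribution (density at 0 and π/2)
means mutually exclusive expression. Distributions are compared with
Kolmogorov–Smirnov tests.

**Two-state transcription model.** A promoter switches OFF→ON at rate
k_on and ON→OFF at k_off, transcribes at k_tx while ON, and transcripts
degrade at k_deg. In the bursty limit (k_off ≫ k_on, k_deg) the
steady-state transcript count is approximately Gamma-distributed with
shape a = k_on/k_deg (bursts per mRNA lifetime) and scale
b = k_tx/k_off (mean burst size). `simulate_two_state()` is an exact
Gillespie simulator (C++ core), `two_state_pmf()` an independent
master-equation solution, and `fit_gamma()` a Gamma maximum-likelihood
fit (Newton iteration on the digamma equation) whose fitted scale
estimates the mean burst size.

**Population statistics.** ON-cell fractions (strictly more than 20
*Ifng* / 50 *Il4* transcripts), knockout percent reductions, Pearson
correlations, nearest-producer distances and stratified
(conditional-invariance) KS comparisons.

## Worked example

```r
library(thfish)

# 1. synthetic count table under the non-biased ("mixed") regime
tab <- make_count_table(regime_params(seed = 1), 5000)

# 2. polar-coordinate state statistic
pol <- to_polar(tab$counts$tbx21, tab$counts$gata3)
fr  <- filter_r(pol, r_min = 10)
theta_summary(fr$kept$theta, n_excluded = fr$n_excluded)
uniformity_test(fr$kept$theta)

# 3. burst inference from a bursty-limit simulation
cnt <- simulate_two_state(k_on = 1, k_off = 100, k_tx = 100 * 159,
                          k_deg = 1, n_cells = 5000, seed = 1)
fit_gamma(cnt, on_threshold = 0)

# 4. knockout percent reductions from the printed means
percent_reduction(33, 1.6)
percent_reduction(35, 2.3)
```

prints

```
Synthetic count table: 5000 cells (mixed regime)
  ON cells: Ifng 212, Il4 92
theta summary: 4138 cells kept, 862 excluded
  median theta 0.7876 (pi/4 = 0.7854), u_index 0.506
KS vs Uniform(0, pi/2): D = 0.0158, p = 0.253
Gamma fit (n = 4968 above threshold 0):
  shape 1.032 (burst frequency / mRNA lifetime)
  scale 151.7 (mean burst size)
  log-likelihood -30071.57
[1] 95
[1] 93
```

Reading: of 5000 cells, 862 fall below the r ≥ 10 radius and are
excluded; the remaining angles have median within 0.003 of π/4 and are
statistically indistinguishable from uniform (p = 0.25) — the mixed,
non-exclusive state. The telegraph simulation parameterized for a mean
burst of 159 transcripts is recovered by the Gamma fit at scale ≈ 152
with shape ≈ 1 burst per mRNA lifetime, and the knockout comparisons
give 95% and 93% reductions.

An image-based session works the same way from TIFF stacks:

```r
ts  <- make_scene(scene_params(n_cells = 20, seed = 1),
                  true_counts = data.frame(tbx21 = rpois(20, 8)))
out <- write_scene(ts, "scene/")
res <- run_image_pipeline(run_config(
  images = list(brightfield = out$brightfield,
                channels = list(tbx21 = out$tbx21))))
head(res$cells)
```

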