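---
title: "Methods: smFISH quantification and stochastic-expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smFISH quantification and stochastic-expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`thfish` analyzes single-molecule FISH measurements of early CD4
T-helper-cell differentiation. The biological picture it serves: after
activation without polarizing cytokines, individual cells co-express the
antagonistic master regulators *Tbx21* and *Gata3* at high levels, while
the hallmark cytokines *Ifng* and *Il4* are transcribed only in a rare
cell population, in large stochastic bursts. The package provides

1. a synthetic-data module (count tables and fully rendered microscopy
   scenes with ground truth),
2. an image-quantification module (segmentation, spot detection,
   fluorescence, high-expresser extrapolation),
3. the polar-coordinate cell-state statistic and its distributional
   tests,
4. two-state transcription-model simulation and Gamma burst inference,
5. population statistics, and
6. a pipeline layer (validated configuration, two entry points,
   JSON reports).

# The synthetic generator: what it emulates

`make_count_table()` draws per-cell counts under two regimes. Joint
transcription-factor counts are generated in polar form: a radius from
an exponential distribution with mean `r_scale` and an angle that is
uniform on $[0, \pi/2]$ (*mixed* regime — cells populate every
intermediate Th1/Th2 state) or drawn from an equal mixture of
$\tfrac{\pi}{2}\mathrm{Beta}(1,c)$ and
$\tfrac{\pi}{2}(1-\mathrm{Beta}(1,c))$ (*exclusive* regime — two
symmetric modes at the axes whose sharpness grows with the
concentration $c$). Counts are rounded continuous draws, hence integers
and never negative. Cytokines are zero except in a rare ON fraction,
whose counts are rounded Gamma draws.

Defaults are the study conditions the analysis assumes:

* `r_scale = 53`: with a uniform angle the mean count per axis is
  $r_{\mathrm{scale}} \cdot 2/\pi$, so 53 reproduces mean
  transcription-factor counts of ~33–35 per cell at 24 h after
  activation.
* `theta_conc = 8`: under cytokine deprivation most cells sit near an
  axis; a Beta(1, 8) component puts ~90% of each mode's mass within
  $\pi/8$ of its axis.
* `p_on_ifng = 0.04`, `p_on_il4 = 0.02`: ON fractions of a few percent.
* ON-cell Gamma scales 159 (*Ifng*) and 176 (*Il4*): the mean burst
  sizes the burst module is anchored to. The shapes default to 1 and are
  configurable, since only the burst sizes (scales) are anchored by the
  analysis; shape 1 corresponds to about one burst per mRNA lifetime.

`make_scene()` renders a monolayer of non-overlapping disk cells of 7 µm
diameter: a bright-field reference (light interior, dark ~2-px rim, so
that edge detection recovers closed boundaries) and one 3-D stack per
gene in which every transcript is a 3-D Gaussian spot (lateral width
`psf_sigma_px = 1.5` px, axial width one z-slice) at a uniform random
position inside its cell, plus additive Gaussian camera noise. The
default spot amplitude/noise ratio is 10, the z-step 0.4 µm, the pixel
size 0.2 µm.

What the generator does **not** emulate: irregular cell shapes, optical
aberrations and depth-dependent PSFs, autofluorescence structure,
hybridization chemistry, or cytokine diffusion. Consequently, passing
planted-truth tests demonstrates the correctness of the algorithms
under their stated assumptions (disk-like cells, Gaussian spots,
well-separated signals), not performance on real micrographs.

Two renderer details matter for oracle tests. First, spots can be given
a minimum separation (`min_sep_px`; z distance counted double to
reflect the coarser axial sampling). Connected-component spot counting
merges spots closer than the optical resolution — in real data as in
synthetic data — so exact-recovery oracles are only meaningful below
the merge limit; separation is best-effort, and cells too crowded to
separate (intentionally unresolvable high expressers) fall back to
unconstrained placement. Second, scenes intended for fluorescence
calibration should include zero-count cells: the background estimate is
the minimum per-cell mean fluorescence, and without true negatives that
minimum sits on a positive signal and biases every total low.

# Image quantification

**Segmentation** (`segment_cells()`): Sobel gradient magnitude on the
central bright-field slice; hysteresis thresholding (weak-edge
components kept only if they contain a strong pixel; thresholds are
fractions 0.4/0.2 of the maximum gradient); morphological closing
(radius 3 px) to close boundary gaps; one marker per region enclosed by
the boundaries; marker-guided watershed on the distance transform of
the boundary image (EBImage's `propagate`), restricted to the enclosed
area. The whole enclosed region seeds the flooding — a single centroid
pixel can leak across shallow ridges between touching cells, while
region seeding splits them at the neck. Mis-segmentations are removed
by area bounds (`min_area_px` default 300, suited to ~7 µm cells at
0.2 µm/px) instead of manual curation, which keeps the pipeline
deterministic and automated. Blank or constant images return zero
labels without error.

**Spot detection** (`detect_spots()`): a scale-normalized, negated
Laplacian-of-Gaussian filter (default σ = 1.5 px, matching the rendered
spot width) per optical slice; voxels above threshold form 3-D
connected regions (26-connectivity), one spot per region at its
regional response maximum. Connecting across z means a spot spanning
slices is counted once; the per-slice filtering with volumetric
grouping resolves the ambiguity between slice-wise and volumetric
counting in favor of not double-counting.

**Threshold selection** (`select_threshold()`): the spot count is swept
over 40 log-spaced thresholds spanning a 100-fold range below the
response maximum. The count falls steeply while noise is thresholded
out, is constant over a wide plateau, then decays as true spots are
lost; the selected threshold is the geometric midpoint of the longest
constant-count run (ties broken toward the higher threshold, which is
farther from the noise floor). This is reproducible, parameter-free,
and equivariant to global intensity scaling because the sweep bounds
derive from the response maximum. A curve with no plateau (at least 3
consecutive equal counts) returns the sweep midpoint with a warning.

**Fluorescence** (`quantify_fluorescence()`): on the slice at the cell
mid-plane, the background is the minimum over cells of the mean pixel
value inside a cell; each cell's total is the sum of (pixel −
background) over its area, clamped at zero. The total is invariant to
adding a constant to the image.

**Extrapolation** (`extrapolate_counts()`): above ~200 transcripts
individual spots are unresolvable, but total fluorescence stays linear
in content. A least-squares line through the origin is fitted on
(count, fluorescence) over calibration cells with 0 < count <
`resolvable_max`; unresolvable cells get count = fluorescence / slope.
Because the component counter collapses a crowded cell into few regions,
its *computed* count is small, so unresolvability is also flagged by
fluorescence exceeding `slope * resolvable_max`, and the calibration is
two-stage (a robust median-ratio pre-fit screens out cells whose
fluorescence is far beyond the resolvable range before the
least-squares fit).

# Polar statistic and its tests

`to_polar()` maps counts to $(r, \theta)$ with
$\theta = \mathrm{atan2}(g, t) \in [0, \pi/2]$; at the origin θ is set
to 0 by convention and the cell is excluded by any sensible radius
filter. `filter_r()` drops cells with $r < 10$ (strict: $r = 10$ is
kept) because the angle of a low-count cell is dominated by shot noise.
Uniformity of θ is assessed by a one-sample Kolmogorov–Smirnov test
against Uniform$(0, \pi/2)$; condition comparisons use the two-sample
KS with the asymptotic p-value, on raw (unbinned) angles. The histogram
summary uses 10 equal-width bins by default, and a U-shape index — the
fraction of cells within $\pi/8$ of either axis — quantifies "most
cells near 0 or π/2" (0.5 expected under uniformity, → 1 under mutual
exclusion); both are configurable conventions rather than inferential
statistics.

A quantization limitation worth knowing: because counts are integers, a
cell can sit exactly on an axis (e.g. 30 *Tbx21*, 0 *Gata3*), which
places small atoms of probability at θ = 0 and θ = π/2 — roughly 1% of
kept cells each at the default generator settings. At large sample
sizes (n ≈ 10,000) these atoms inflate the one-sample KS statistic, so
the uniformity test rejects a truly mixed regime somewhat more often
than its nominal level; the calibration tests in this package run at
that scale and account for it by testing across 100 replicate seeds.

# Two-state model and burst inference

`simulate_two_state()` is an exact Gillespie simulation per cell
(compiled core, driven by R's RNG so results are reproducible under
`set.seed`): promoter OFF↔ON at rates $k_{on}, k_{off}$, transcription
at $k_{tx}$ while ON, degradation at $m \cdot k_{deg}$. The promoter is
initialized from its stationary law, mRNA at zero, and the copy number
is sampled after a burn-in of $10/k_{deg}$ — ten mRNA lifetimes, ample
relaxation in this rate regime. The closed-form stationary mean
$k_{tx} k_{on} / (k_{deg}(k_{on} + k_{off}))$ and a truncated
master-equation solution (`two_state_pmf()`, sparse generator solved as
a linear system, truncation at the mean plus twelve overdispersed
standard deviations) serve as independent cross-checks.

In the bursty limit ($k_{off} \gg k_{on}, k_{deg}$) the stationary
density approaches Gamma(shape $k_{on}/k_{deg}$, scale
$k_{tx}/k_{off}$): the scale is the mean geometric burst size, the
shape the burst frequency per mRNA lifetime. `fit_gamma()` implements
the Gamma MLE with Newton iteration on the profile equation
$\log a - \psi(a) = \log \bar x - \overline{\log x}$ (closed-form
start, relative tolerance $10^{-12}$); the scale is $\bar x / a$, so
the fitted mean equals the sample mean exactly. Degenerate inputs
(fewer than 20 ON cells, zero variance) are errors, not guesses.

Zero handling is a genuine modeling choice, so both options are
exposed. The default fits the counts above `on_threshold` (0: all
expressing cells) as continuous observations, matching the convention
of fitting "expressing cells" — but on discrete counts this truncates
the small-count mass and biases the fitted scale low, appreciably so
for small bursts (around 10% at scale 18). With `continuity = TRUE`
each count enters as the midpoint of its unit interval (count + 0.5)
and `include_zero = TRUE` lets the zero class enter at half a count;
this removes most of the truncation bias, and the package's recovery
tests use it when the question is parameter recovery rather than
protocol replication. A related discreteness note: the Gamma is a
continuous approximation to an integer law, with an irreducible
zero-class gap of order $P(0) \approx 0.05$ at shape 1, scale 20, so
distributional KS checks of the bursty limit are run at sample sizes
(n ≈ 300) where KS resolution exceeds that gap — larger samples would
reject the approximation for being an approximation.

# Population statistics

ON fractions use strict thresholds (more than 20 *Ifng*, more than 50
*Il4* transcripts; a count equal to the threshold is OFF). Percent
reductions are $100(1 - \bar x_{test}/\bar x_{ref})$, rounded to whole
percent for reporting. "No correlation" between transcription-factor
level and distance to the nearest cytokine producer is operationalized
as $|R| < 0.1$ (configurable), since a well-mixed milieu predicts
independence but a sample correlation is never exactly zero.
Conditional invariance stratifies cells by cytokine count (default
strata: the zero class, then [1, 20), [20, 100), [100, 1000),
[1000, ∞)), drops strata under 20 cells with a warning, compares all
stratum pairs by two-sample KS and adjusts with Bonferroni — the
simplest correction that cannot overstate significance. Time-course
correlations use per-time-point summary statistics (ON fraction versus
mean factor count), not pooled cells.

# Pipeline and reproducibility

Configurations are YAML (or in-R lists) validated against the full
default tree — unknown keys are rejected before any computation — with
defaults mirroring the analysis conventions: exclusion radius 10, ON
thresholds 20/50, resolvable maximum 200, cell diameter 7 µm, z-step
0.4 µm. `run_image_pipeline()` chains segmentation → threshold
selection → detection → assignment → fluorescence → extrapolation →
count statistics and records every stage's parameters in the JSON
report; `run_counts_pipeline()` runs the count-level statistics on an
existing table. Reports contain no timestamps, so identical
configurations produce byte-identical reports.

Every stochastic component takes an explicit seed and is evaluated
without disturbing the caller's RNG stream. Test problem sizes are
chosen to exercise each claim at informative scale while staying
desk-sized: planted scenes of 8–24 cells with 3–12 spots per cell,
simulation samples of 5000 cells (50,000 for distribution-level
comparisons), 20–100 replicate seeds for calibration rates.

# Known limitations

* Segmentation assumes closed, roughly convex boundaries from a clean
  bright-field rim; heavily textured or overlapping cells are out of
  scope, as is any learned segmentation.
* Spot counting is connected-component based; above the merge limit it
  undercounts by design, and the fluorescence extrapolation is the
  intended remedy.
* The Gamma burst description is the bursty-limit approximation of the
  telegraph model; outside that limit the fitted scale is a summary
  statistic, not the mechanistic burst size.
* The exclusive-regime angle law is a phenomenological Beta mixture
  chosen for its two tunable symmetric modes; the underlying regulatory
  network is deliberately not modeled dynamically.
* Pearson correlations on highly skewed counts (rare large cytokine
  bursts) are dominated by the few ON cells; they are reported because
  they are the field's convention, but rank correlations would be more
  robust.
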