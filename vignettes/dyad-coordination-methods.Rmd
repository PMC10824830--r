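---
title: "Measuring dyadic movement coordination with lagged cross-correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic movement coordination with lagged cross-correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsync)
```

## The measurement problem

When two people interact — here, a storyteller narrating to a seated child —
their body movements tend to become coordinated without either party being
instructed to move. `dyadsync` quantifies that spontaneous coordination from
optical motion capture of the two torsos, as a function of the time delay
between the storyteller's movement and the child's, and provides the
inferential machinery to aggregate it over a sample of dyads and to contrast
experimental groups.

The unit of analysis is the **dyad**: one child–storyteller pair recorded at
a fixed frame rate (120 fps in the intended setting), with reflective
markers on each interactant's upper and lower back, plus a rigid identifier
constellation that serves labeling only.

## From markers to one speed signal per interactant

Preprocessing reduces each interactant to a single scalar signal, in this
fixed order:

1. **Torso centroid.** The four back markers are averaged, per frame, into
   one 3D position. Frames where some markers are occluded use the mean of
   the remaining ones.
2. **Projection on the proximity axis.** The axis is the unit vector joining
   the two interactants' *time-mean* centroids. The axis is estimated once
   per analysis segment, not per frame: the interactants are seated and the
   geometry quasi-static, while a per-frame axis would leak the partner's
   motion into one's own coordinate. Each interactant's projection is
   oriented so that **motion toward the partner is positive**. This
   convention is what gives downstream signs their meaning: a positive
   correlation means mirror-like (*symmetric*) coordination — both approach
   or both retreat together — and a negative one means *asymmetric*
   coordination, one approaching while the other retreats. (A shared
   world-axis orientation, which inverts this reading, exists only as a
   debug flag of `project_axis()`.)
3. **Discrete speed.** First differences of the projected position,
   `s[t] = pos[t] − pos[t−1]`, in mm/frame. Speed, unlike position, is
   zero-mean around rest, which is what justifies the *uncentered*
   correlation below. Because that statistic is scale-invariant, mm/frame
   is kept throughout; no conversion to mm/s is needed.
4. **Low-pass filter.** A single-pole recursive smoother with a 10 Hz
   cutoff removes recording artifacts:
   `y[t] = y[t−1] + α (s[t] − y[t−1])`, `α = Δt / (RC + Δt)`,
   `RC = 1/(2π f_c)`. At 120 fps and 10 Hz, `α ≈ 0.3437`. The filter is
   applied in a single causal pass — a one-pole filter is not the
   forward–backward zero-phase kind — and is initialised `y[1] = s[1]`,
   which avoids a startup transient; these two choices (direction and
   initialisation) are this package's own, since a one-pole specification
   leaves them open.

### Occlusion handling

Missing marker runs up to `max_gap_s` (default 0.25 s) are linearly
interpolated per coordinate; longer runs stay missing and are listed in a
gap report. Dyads with more than 10 % of frames still missing after filling
are excluded and logged with a machine-readable reason. Both thresholds are
package policy for quality control, configurable in `analysis_config()`;
they are deliberately conservative defaults rather than estimates of any
particular study's exclusion rule.

## The correlation statistic

For two speed signals `a`, `b` of common length `n`, the coordination
statistic is the uncentered correlation

$$ r_{ab} = \frac{\sum_i a_i b_i}{\sqrt{\sum_i a_i^2 \sum_i b_i^2}} , $$

computed in the time domain with **no mean centering** (`xcorr_coef()`, with
a `center` flag for sensitivity analysis only). Delayed coordination is
probed by holding the storyteller's series fixed and offsetting the child's
by each grid delay, trimming the non-overlapping ends
(`xcorr_at_lag()`): a positive delay asks whether the child moved as the
storyteller had done that long before. The default grid is zero-lag plus
fifteen delays from 100 to 1500 ms in 100 ms steps, converted to whole
frames by round-to-nearest (exact at 120 fps). Each dyad/segment yields a
curve of pairs `(r_i, m_i)`, where `m_i` is the number of sample pairs at
that delay; lags where the statistic is undefined (an all-zero segment) are
recorded as missing, never fabricated, and excluded from pooling.

## Aggregation and inference

Correlations are pooled across dyads per delay in Fisher space
(`pool_curves()`):

* transform: `x_i = atanh(r_i)` (values numerically at ±1, possible on tiny
  noiseless segments, are clamped to ±(1 − 10⁻¹²) with a warning first);
* pool: the **unweighted** mean `X` of the `x_i` — the definitional grand
  average. An inverse-variance-weighted mean sits behind the `weighted`
  flag for sensitivity analysis, because the standard-error derivation
  below formally assumes similar `m_i`;
* standard error: `σ ≈ 1/√(Σ m_i)` — the error of a single transformed
  correlation whose length is the sum of all contributing lengths;
* back-transform: `R = tanh(X)`.

Confidence bands (`confidence_band()`) multiply `σ` by the two-sided normal
quantile at the Bonferroni-corrected level `α/k` and map the limits back
through `tanh`. The defaults are `α = 0.001` and `k = 41` comparisons,
giving a corrected per-comparison level of about 2 × 10⁻⁵; `k` is an
explicit parameter rather than being derived from the grid because the
comparison count one wants to protect may exceed the plotted grid (41
protects, e.g., a symmetric ±2000 ms grid). A delay is flagged significant
when its interval excludes zero, and labeled `symmetric` (interval entirely
positive) or `asymmetric` (entirely negative).

**A calibration caveat that matters.** `σ = 1/√(Σ m_i)` treats the samples
as serially independent. Speed signals smoothed by postural dynamics or by
the low-pass filter are autocorrelated, which inflates the sampling
variance of `r` well beyond `1/m`; the bands are then anti-conservative in
absolute terms. The package's null-calibration property is therefore
demonstrated on serially uncorrelated signals — the regime in which the
derivation holds — and aggregated curves on smooth signals should be read
comparatively (contrast against a baseline), which is how the within-dyad
design uses them. Surrogate-pair permutation nulls, which would calibrate
the autocorrelated case, are a documented extension, not part of this
package.

## Contrasts

`subtract_fisher()` forms differences in Fisher space, with standard errors
combined in quadrature. Three contrast families are built by
`run_analysis()`:

* **within-dyad**: the pre-climax curve of a group is the baseline
  subtracted from its post-climax curve, isolating the change created by
  the narrative climax (each segment is re-preprocessed independently,
  including its own axis estimate, and lagging trims within the segment —
  it never crosses the climax boundary). The direction is post − pre by
  default, with a `contrast_direction` switch;
* **between ages**: 6-year-old minus the 3-year-old baseline;
* **between conditions**: predominantly affective (PAI) minus the
  predominantly intellectual (PII) baseline.

Contrasts are formed aggregate-then-subtract: between-group contrasts
involve different dyads on each side, so subtraction can only happen after
pooling, and the within-dyad contrast uses the same path for consistency.
The resulting curves are comparative, not absolute, levels of coordination.

## The synthetic dyad generator

No raw recordings ship with the package, so `simulate_dyad()` generates
mocap-like dyads with *known* coupling structure, which is what makes every
pipeline stage testable:

* the storyteller's approach-axis speed is a stationary AR(1) process with
  configurable sd (default 1 mm/frame) and smoothness (default φ = 0.95,
  roughly 1 Hz postural-sway bandwidth at 120 fps);
* the child's speed is a lag-and-gain linear function of it plus white
  noise, `c[t] = Σ_k g_k s[t − L_k] + ε[t]`, with separate coupling sets
  before and after the climax frame. Coupling acts on **speeds**, because
  the correlation statistic does; positive gain produces symmetric
  coordination under the sign convention, negative gain asymmetric. For a
  single coupling, the expected correlation at its lag has the closed form
  `ρ = g σ_s / √(g² σ_s² + σ_ε²)` (`theoretical_rho()`);
* speeds are integrated to positions with a mild mean reversion
  (coefficient 0.999 per frame) so seated posture does not random-walk
  away; the torsos are embedded facing each other 1.5 m apart and expanded
  into four back markers plus a three-marker identifier constellation with
  0.5 mm Gaussian jitter (just above an optical system's resolution floor);
* defaults describe a five-minute session with a mid-session climax;
  the test-suite and example studies use 20–60 s sessions — scaled-down
  problem sizes chosen so the full suite runs in minutes — which leaves
  per-dyad pair counts of 2400–7200 per lag, ample for the effects
  simulated.

What the generator does *not* emulate: biomechanically realistic posture,
gesture or facial expressiveness, nonstationary engagement drift, or any
claim about the true amplitude/spectrum of children's torso motion. Tests
passing on this generator validate the pipeline's arithmetic and sign
conventions, not the psychological findings one might obtain on real data.

## Numerical choices and degenerate inputs

* Axis estimation fails informatively when mean centroids are closer than
  1 mm (degenerate geometry).
* `lag_grid()` refuses grids in which two ms-delays round to the same
  frame.
* Correlation is undefined when either trimmed segment is all zero; such
  lags are reported missing and dropped from pooling.
* Pooled curves with zero defined dyads at a lag stay missing at that lag.
* Peak finding is plateau-tolerant and reports endpoint extrema (a
  monotone curve peaks at its boundary).
* All RNG use is seed-controlled per dyad (`base_seed + index`), so group
  datasets regenerate byte-identically.

## Worked example

```{r example, eval = FALSE}
tpl <- dyad_sim_config(duration_s = 60, climax_time_s = 30,
                       coupling_pre = coupling(),
                       coupling_post = coupling(500, 1))
man <- simulate_group(group_sim_config(n_per_cell = 2, template = tpl,
                                       base_seed = 31415L), "study_data")
res <- run_analysis(analysis_config("study_data", man$metadata_path,
                                    man$labels_path, "study_out"))
res$contrasts[["3y.PII.post-pre"]]   # climax contrast: peak at 500 ms
plot_curves(res$contrasts)
```

The run writes per-dyad curves, per-group aggregated curves with bands,
contrast curves, peak tables, a QC/exclusion log and figures into the
output directory; rerunning on the same inputs reproduces the CSVs
byte-for-byte.
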