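# dyadsync

Lag-resolved cross-correlation analysis of spontaneous movement
coordination in child–storyteller dyads (or any seated two-person
interaction) recorded with optical motion capture.

When a storyteller narrates to a child, their torso movements become
coordinated without instruction. `dyadsync` measures that coordination for
researchers in developmental and social interaction science: it turns
labeled marker trajectories into one *approach-positive* speed signal per
interactant along the proximity axis (the line between the two torsos),
computes zero-lag and delayed cross-correlation curves per dyad, pools them
across dyads in Fisher z space, attaches Bonferroni-corrected confidence
bands, and forms within-dyad (pre/post story-climax) and between-group
contrasts. A synthetic dyad generator with known lagged coupling makes every
stage testable without raw recordings.

## The statistic

For speed signals `a` (storyteller) and `b` (child), coordination at a given
delay is the uncentered time-domain correlation on the trimmed overlap,

```
r = Σ aᵢbᵢ / √(Σ aᵢ² · Σ bᵢ²)
```

with no mean centering (speed is zero-mean around rest). Delays run over
zero-lag plus 100–1500 ms in 100 ms steps; positive delays ask whether the
child moved as the storyteller had done that long before. Per delay, dyad
correlations `rᵢ` with pair counts `mᵢ` are pooled as

```
X = mean(atanh rᵢ),    σ ≈ 1/√(Σ mᵢ),    R = tanh X
```

and the band `tanh(X ± z* σ)` uses the two-sided normal cutoff at the
Bonferroni-corrected level `α/k` (defaults `α = 0.001`, `k = 41`, corrected
p ≈ 2×10⁻⁵). Under the approach-positive sign convention, positive `R`
reads as **symmetric** (mirror-like, both approach/both retreat)
coordination and negative `R` as **asymmetric** (one approaches, the other
retreats). Contrasts (post-climax − pre-climax baseline; 6y − 3y; PAI − PII)
are differences in Fisher space with errors combined in quadrature.

## Worked example

Simulate a small study (two dyads per age × condition cell, 60 s sessions)
in which the child's speed is coupled to the storyteller's at a 500 ms delay
*only after* the story climax, then run the full analysis:

```r
library(dyadsync)
tpl <- dyad_sim_config(duration_s = 60, climax_time_s = 30,
                       coupling_pre = coupling(),        # no coupling before
                       coupling_post = coupling(500, 1)) # 500 ms echo after
man <- simulate_group(group_sim_config(n_per_cell = 2, template = tpl,
                                       base_seed = 31415L), "study_data")
res <- run_analysis(analysis_config("study_data", man$metadata_path,
                                    man$labels_path, "study_out"))
res$contrasts[["3y.PII.post-pre"]]    # within-dyad climax contrast
```

The climax contrast for the 3-year-old PII cell prints (abridged):

```
   lag_ms        R  ci_low ci_high significant morphology
1       0 -0.05678 -0.1265  0.0135       FALSE       none
4     300  0.23125  0.1633  0.2970        TRUE  symmetric
6     500  0.90004  0.8857  0.9127        TRUE  symmetric
8     800  0.09307  0.0220  0.1632        TRUE  symmetric
10    900  0.01520 -0.0562  0.0864       FALSE       none
```

The injected post-climax coupling surfaces exactly where it was planted:
the subtracted (post − pre) curve peaks at 500 ms with `R = 0.90` and a
symmetric label — the band excludes zero there — while zero-lag and delays
beyond ~900 ms show no coordination change. `res$peaks` confirms the global
maximum:

```
             label lag_ms       R type morphology global
93 3y.PII.post-pre    500  0.9000  max  symmetric   TRUE
```

Neighbouring delays (300–800 ms) are partially elevated because the
simulated base motion is smooth (AR(1), φ = 0.95), so the echo bleeds into
adjacent 100 ms bins. `run_analysis()` also writes per-dyad curves,
per-group aggregated curves, contrast curves, peak tables, a QC/exclusion
log and figures into the output directory, byte-identically across reruns.

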