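# gaitsym

Whole-body gait symmetry from a single trunk-worn accelerometer.

Healthy human walking is nearly — but not perfectly — left/right
symmetric, and the degree of symmetry changes over the life span and under
speed stress. `gaitsym` implements a whole-body Symmetry Index (SI)
computed from triaxial acceleration recorded at the lower back (around
S1/S2, close to the body's center of mass) during straight-line walking,
together with everything needed to study it at cohort scale: a
ground-truthed synthetic gait-signal generator, anthropometric
normalization of walking speed, and the group-level statistical battery.

## The symmetry index

For one trial the pipeline:

1. low-pass filters the raw signal (10 Hz cutoff, two-pass 4th-order
   Butterworth, zero phase);
2. estimates the static sensor tilt from the trial-mean acceleration,
   rotates the signal into the earth frame and subtracts gravity;
3. extracts the anterior-posterior (AP) component;
4. detects initial contacts as AP peaks (adaptive threshold, spectral
   step-period gating, sub-sample refinement) and assigns left/right sides
   from the mediolateral sway;
5. splits the AP series into left and right gait cycles (contact to next
   ipsilateral contact), time-normalizes each onto a 0–100% grid and
   averages per side.

With `r` the Pearson correlation between the mean left-cycle and mean
right-cycle AP waveforms,

    SI = (r + 1) × 100 / 2

so SI = 100 means identical side waveforms and SI = 0 exact
anti-correlation. Walking speed is normalized by dividing each observed
speed by the value predicted from body weight and height under a
per-condition OLS regression. The cohort statistics cover Shapiro–Wilk
and Levene checks, split-plot (between-group × repeated speed-condition)
ANOVA with Greenhouse–Geisser correction, Bonferroni post hocs, and
canonical discriminant analysis with Wilks' Λ and the structure matrix.

## Worked example

```r
library(gaitsym)

params <- gait_sim_params(asymmetry_alpha = 0.28)  # pronounced asymmetry
sim <- simulate_trace(params, seed = 42)
res <- compute_trial_si(sim$trace)
res
#> <gait_si> SI = 94.253 (r = 0.88507), 7 left / 7 right cycles
plot(res)   # overlaid left/right mean AP waveforms
```

An asymmetry knob of 0.28 (alternate steps amplitude-scaled by 1 ± 0.28)
under the default sensor noise yields SI ≈ 94: the side-mean waveforms
correlate at r ≈ 0.885. A symmetric noiseless trial returns SI = 100 to
nine decimals.

At cohort scale:

```r
groups <- gait_groups(c("Children", "Young Adults", "Elderly"), n = 4)
des <- cohort_design(groups = groups, trials_per_condition = 2)
coh <- simulate_cohort(des, seed = 7)
out <- process_cohort(coh)
out
#> <gait_results> 72 trials, 36 participant x condition rows
#> mean SI by group and condition:
#>         group Comfortable  Fast  Slow
#>      Children       98.18 94.67 98.24
#>       Elderly       97.20 91.83 97.42
#>  Young Adults       97.56 97.78 97.88

mixed_anova(out$table, dv = "si")
#> Split-plot ANOVA on 'si' (12 subjects, 3 within levels)
#> Greenhouse-Geisser epsilon = 0.5733
#>
#>   group            F(2, 9) = 13.7160, p = 0.001851
#>   condition        F(1.1, 10.3) = 143.6878, p_GG = 1.444e-07
#>   group:condition  F(2.3, 10.3) = 42.3383, p_GG = 7.692e-06
```

The default asymmetry profile elevates asymmetry only during fast walking
for the developmentally/degeneratively affected groups, so children and
elderly lose symmetry in the Fast condition while young adults stay flat —
which is exactly what the interaction term picks up. `analysis_report()`
renders the full battery (omnibus ANOVAs, pairwise matrices per condition
and per group, per-condition LDA) as CSV files plus a text report, and
`run_pipeline()` drives simulate → process → analyze end to end with a JSON
run manifest. A command-line wrapper lives in `inst/scripts/gaitsym.R`.

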