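# tagmove

Quantifying the effect of tracking-tag weight on insect movement from arena
video-tracking trajectories.

Attaching a radio-telemetry or RFID tag to an insect adds load — sometimes
approaching the animal's own body mass — and the load can bias the very
movement the tag is meant to record. `tagmove` implements the full
quantitative workflow used to measure that bias in laboratory arena
experiments with ground-dwelling crickets: per-frame trajectories of
tagged and untagged individuals recorded at several temperatures are
segmented into behavioural bouts, summarised into movement properties, and
compared statistically. A seeded trajectory generator emulating the whole
experimental design makes the pipeline testable end-to-end without video
data.

## What it computes

**Bout segmentation.** Each calibrated track (metres, 24 fps) is split into
an alternating sequence of *movement bouts* (continuous locomotion with
path length > 2 cm) and *resting periods* (speed ≤ 1 cm/s, including
sub-2-cm micro-movements, which are absorbed as noise). Per-frame speed is
smoothed over a 0.25-s centred window; bout durations partition the
recording exactly.

**Movement properties** per individual-recording: mean / maximum / total
movement-bout path length (`movementLength`, `movementLengthMax`,
`movementSum`), mean per-bout speed (`movementSpeed`), mean resting
duration and resting count (`restingDuration`, `restingFrequency`).

**Comparison battery.** Each tagged group (light / medium / heavy) is
compared to control with two-sided Mann–Whitney tests for every property ×
day, pooled over temperatures (54 tests) and per temperature stratum (162),
with Benjamini–Yekutieli FDR adjustment across each run and effect sizes as
percent changes of medians; plus per-individual day slopes compared across
groups and paired Wilcoxon tests of body-mass change.

**Mixed model.** Distance travelled is modelled as

```
movementSum ~ temperature * tag_weight + temperature * animal_weight + (1 | cricket)
```

(REML, Satterthwaite df, intermediate temperature as reference), and the
derived tag-load effect `|β_tag + β_temp:tag| × 100` gives metres of
distance lost per 100 mg of tag per 10-minute recording.

## Worked example

Simulate a reduced cohort (one group of 20 per temperature: 5 controls plus
5 per tag class, 3 days, 10-min recordings), compute properties and compare
against controls:

```r
library(tagmove)

design <- experiment_design(n_groups_per_temperature = 1,
                            individuals_per_group = 20)
sim   <- simulate_experiment(design, seed = 42)
props <- properties_table(sim$tracks, sim$metadata)
head(props[c("cricket_id", "weight_category", "day",
             "movementSum", "movementSpeed", "restingFrequency")], 4)
#>   cricket_id weight_category day movementSum movementSpeed restingFrequency
#> 1       c001         control   1    21.46837    0.06489752              165
#> 2       c001         control   2    22.32301    0.06451280              156
#> 3       c001         control   3    21.32783    0.06590878              143
#> 4       c002         control   1    25.07486    0.07592778              142

cmp <- compare_to_control(props, "pooled")
subset(cmp, significant,
       select = c(property, day, weight_category, median_control, median_tag, p_adjusted))
#>            property day weight_category median_control median_tag p_adjusted
#> 21      movementSum   1           heavy       18.56847    9.96790  0.0055071
#> 23      movementSum   2          medium       17.74191   10.41679  0.0469460
#> 24      movementSum   2           heavy       17.74191    8.08128  0.0055071
#> 27      movementSum   3           heavy       17.01645    9.29056  0.0055071
#> 29    movementSpeed   1          medium        0.06230    0.05339  0.0033784
#> 30    movementSpeed   1           heavy        0.06230    0.05000  0.0002793
#> ...
#> 42  restingDuration   2           heavy        2.41667    5.13786  0.0081070
#> 51 restingFrequency   2           heavy      131.00000   87.00000  0.0047014
```

The default effect model — tags slow walking, shorten bouts and lengthen
rests, multiplicatively in tag mass — shows the expected dose response:
medium and heavy tags are flagged on speed and distance travelled on every
day (heavy ≈ 759 mg tags walk ~20 % slower and travel ~half the distance of
controls here), the heavy tag additionally roughly doubles resting
durations, while the light tag stays below the detection threshold at this
cohort size.

The published summary tables of the reference cricket experiment ship with
the package, so its reported effect sizes are one call away:

```r
med <- reference_medians()
sub <- med[med$property == "movementSpeed" & med$day == 2, ]
percent_change(sub$control, sub$medium)
#> [1] -16.66667        # medium tags: ~17 % slower

distance_reduction_per_100mg(reference_coefficients(), "low")
#> [1] 1.4              # metres lost per 100 mg of tag at 19.5 °C
```

A full run — simulation, analysis and the CSV/JSON report bundle — is one
call (`run_pipeline(pipeline_config(...), mode = "full")`), or from a
shell via the thin wrapper `inst/scripts/tagmove.R` with subcommands
`simulate`, `analyze`, `full`.

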