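# fmassess

Automated upper-limb motor-function assessment from multi-sensor movement
recordings.

Standard post-stroke motor assessments such as the Fugl-Meyer Assessment
(FMA) require a clinician to watch a patient perform ~33 predefined
upper-limb movements and rate each one 0 (cannot perform), 1 (partial) or
2 (faultless); the ratings are summed into a total impairment score. That
takes about half an hour of clinician time per patient. `fmassess`
implements the sensor-to-score pipeline that automates the bulk of this
process from low-cost sensors: a depth-camera skeleton stream (30 Hz joint
positions), a wrist-worn IMU (100 Hz accelerometer in g, gyroscope in
deg/s), a five-channel flexion glove and a grip-pressure sensor.

The pipeline per test movement:

1. **Segmentation** — the recording is trimmed at the first instant after
   which wrist speed (skeleton) or gyroscope magnitude (IMU) stays below a
   rest threshold for a quiet period.
2. **Speed normalization** — frames where the wrist moved less than a
   threshold from the previously retained frame are deleted, then the
   sequence is resampled to a fixed per-test frame count by deleting or
   repeating frames at even intervals, so movement speed cannot influence
   the score.
3. **Feature extraction** — each test has a declarative recipe over seven
   primitives: limb orientation (unit vector **v** = (distal − proximal) /
   ‖distal − proximal‖, 3 dims); joint angle θ = arccos(**S**ᵀ**I**) between
   superior and inferior limb vectors (1 dim); supination/pronation range =
   max − min of the median-filtered Z accelerometer, which tracks gravity as
   the forearm rotates (1 dim); movement smoothness = Σ |raw − median-
   filtered| over the accelerometer channels (1 dim); amount of movement =
   ∫ max(0, |gyro| − resting baseline) dt (1 dim); grip strength = max of
   the filtered pressure series (1 dim); finger state = the five filtered
   glove channels at the most-flexed or most-extended instant (5 dims).
4. **Classification** — one scorer per test maps the feature vector to
   {0, 1, 2}: either linear-kernel soft-margin SVMs composed by pairwise
   voting (LIBSVM via `e1071`, default settings apart from the kernel, no
   feature scaling) or a from-scratch 3-layer backpropagation network
   (hidden width ≈ halfway between feature dimension and the 3 output
   nodes).
5. **Aggregation** — per-test scores are summed; agreement with a clinician
   total c is reported as (1 − |auto − c| / c) × 100.

Because no public recordings exist for these sensors, the package ships a
seeded movement simulator (`simulate_movement()`, `simulate_cohort()`) that
generates all four streams from forward kinematics of a two-segment arm at
three impairment levels, with tremor, position noise and occlusion dropouts.
Every stage of the pipeline is tested against it.

## Worked example

Simulate a small cohort, validate a per-test scorer subject-wise, and score
a fresh recording:

```r
library(fmassess)

co <- simulate_cohort(n_subjects = 4, reps_per_score = 1,
                      preset = "low_noise", seed = 42,
                      tests = c("elbow_flexion", "forearm_supination"))

cv <- crossval_by_subject(co$datasets$forearm_supination, "svm",
                          instances_per_class = 5, seed = 42)
round(cv$per_subject, 3)
#> S01 S02 S03 S04
#>   1   1   1   1

m <- train_svm(co$datasets$forearm_supination)
b <- simulate_movement("forearm_supination", score = 1, seed = 7)
extract_features(b)
#> <feature_vector> test=forearm_supination dim=3
#>  rotation_range movement_amount      smoothness
#>        1.593665      125.079927        5.399151
score_movement(b, m)
#> [1] 1
score_agreement(29, 30)
#> [1] 96.67
```

Each per-subject entry is the accuracy of a model trained on the other
subjects (leave-one-subject-out, five training instances per class). The
partial (score-1) supination shows a Z-accelerometer sweep of ~1.6 g —
between the ~0 g of a score-0 trial and the ~2 g of a full 180° rotation —
and the scorer recovers the generating score. A shell entry point with
`simulate` / `extract` / `train` / `crossval` / `score` / `assess`
subcommands ships as `inst/cli/fma`.

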