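# clawtrack

Markerless tracking of claw-waving fiddler crabs in field-style video,
and quantification of their group synchrony.

Male fiddler crabs court by rhythmically waving an enlarged claw, often
in synchrony across a lek. Field recordings of this behavior defeat
appearance-based animal trackers: the animals are a dozen pixels across,
camouflaged, and filmed over cluttered substrate. `clawtrack` tracks
*motion* instead of appearance:

1. **Dense optical flow** between consecutive frames (a
   polynomial-expansion estimator with a multi-resolution pyramid);
2. **grid downsampling + thresholding** of the flow field, leaving a
   sparse field of significant motion;
3. **DBSCAN clustering** (epsilon = 30 px, minpts = 2) of the surviving
   motion cells into individuals;
4. **centroid ID tracking** across frames under a maximum-displacement
   threshold;
5. **wave and synchrony analysis**: per-ID speed traces are smoothed,
   wave peaks detected, each peak treated as oscillator phase zero, phase
   interpolated linearly between peaks, and group synchrony summarized by
   the Kuramoto order parameter R = |mean_j exp(i θ_j)| over the
   individuals actively waving, with a Monte-Carlo chance baseline.

The package also ships a ground-truthed synthetic scene generator (many
small wavers with planted periods, phases and wave-peak times) so the
whole pipeline is testable end to end without field footage, plus the
detection-accuracy statistics used to validate counts against human
annotation (net error, relative error, agreement accuracy) and wave-event
recovery.

## Worked example

```r
library(clawtrack)

cfg <- scene_config(width = 320, height = 240, n_frames = 240,
                    n_wavers = 3, noise_sigma = 0, seed = 7)
scene <- generate_scene(cfg)              # frames + ground truth
tracks <- filter_tracks(run_tracking(scene$frames))
tracks
#> TrackSet: 3 tracks over 240 frames (30 fps)

res <- analyze_tracks(tracks)
str(res$summary)
#> List of 4
#>  $ mean_R  : num 0.883
#>  $ chance_R: num 0.531
#>  $ n_ids   : int 3
#>  $ n_waves : int 7
```

The three planted wavers are recovered as three persistent IDs. Their
waves (7 complete cycles in these 8 seconds) yield a time-averaged
Kuramoto `mean_R` of 0.88 — these three planted phases are fairly
aligned — against a chance level of 0.53 expected for three independent
oscillators. `tracks_to_df(tracks)` gives the tidy per-frame table
(`frame, time_s, id, x_px, y_px, x_m, y_m, speed_px_per_frame`) for
export.

The same pipeline is available from the shell (see
`inst/cli/clawtrack`):

```sh
clawtrack simulate --out-dir scene --n-wavers 10 --seed 1
clawtrack track    --frames scene --out tracks.csv
clawtrack analyze  --tracks tracks.csv --out-dir analysis
clawtrack evaluate --n-alg 23 --n-hum 27 --out metrics.json
```

The last command reproduces the count-agreement arithmetic for a video
with 23 algorithm-detected and 27 human-annotated individuals: net error
−4, relative error 15%, agreement accuracy 85%.

## Configuration

Every method parameter is exposed in one nested configuration
(`default_config()`, YAML-overridable in the CLI): flow pyramid/window,
grid cell size and speed cutoff, DBSCAN epsilon/minpts, tracking
max-distance/patience, wave smoothing/peak parameters, and chance-level
replication. Defaults and their rationale are documented in
`vignettes/claw-wave-tracking.Rmd`.
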