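# mostrack

Multi-object tracking of insect flight in laboratory video.

Behavioural studies of mosquitoes (and other small, fast insects) need
per-individual flight trajectories from standard laboratory footage:
grayscale frames of a light-walled cage, ~1040 x 1024 px at 60 frames/s,
with up to five visually identical, ~12-pixel insects that maneuver
quickly and occasionally occlude one another. `mostrack` turns such
footage into evaluated trajectories:

1. **Detection** — a built-in intensity-threshold blob detector for
   dark-on-light footage, or externally produced detections read from
   `frame,x,y,w,h,conf` text files; confidence filtering and greedy
   non-maximum suppression.
2. **Tracking** — per-identity constant-velocity Kalman filters on
   `(cx, cy, a, h)`; Hungarian association of predictions to detections
   with a cosine appearance cost and a chi-square Mahalanobis gate
   (0.95 quantile, 4 d.o.f.), run as a matching cascade with a
   distance-based recovery stage; Max-Age track lifecycle with tentative
   confirmation.
3. **Post-processing** — removal of identities present in < 5% of frames
   (reflections and other transients), then cubic-spline interpolation of
   interior missing frames.
4. **Evaluation** — mean absolute error
   `MAE = (1/n) Σ_f |x_f − x̂_f| + |y_f − ŷ_f|`, tolerance accuracy
   (both axis errors strictly below 6 px), IoU > 0.25 occlusion-event
   extraction, and identity preservation across occlusions.
5. **Synthesis** — a seeded generator of flight videos with exact ground
   truth (smooth stochastic paths, forced crossings, dropouts, reflection
   blobs) so the whole chain is testable without any recorded data.

The five user-facing parameters are Image Size (1040, auto-adjusted up to
a multiple of the stride 32 — i.e. 1056), Confidence (0.05), NMS IoU
(0.05), Max Age (30 frames) and Filtration (5%).

## Worked example

Simulate a five-agent video at the native recording regime, run the
pipeline, and score it against the generator's ground truth:

```r
library(mostrack)

cfg <- synth_config(duration = 3, seed = 1)      # 1040 x 1024, 60 fps, 5 agents
sim <- simulate_flight_video(cfg)
write_dataset(sim$traj, sim$frames, "demo/flight1")

run <- process_video("demo/flight1/frames", pipeline_config(overlay = FALSE),
                     out_root = "demo/Results", name = "flight1")
print(run)
#> Pipeline run 'flight1': 180 frames, 5 identities, 0.00% interpolated
#>   results in demo/Results/flight1

ev <- evaluate_run(run, sim$traj)
print(ev)
#> Trajectory evaluation
#>   frames evaluated: 900
#>   MAE: 0.344 px
#>   accuracy (tolerance 6 px): 100.00% (0 inaccurate frames)
#>   occlusions: 0/0 identities preserved
```

All five insects are tracked for all 180 frames under one identity each
(no fragmentation, nothing interpolated); the mean absolute error of
~0.34 px is sub-pixel detector jitter, and every frame is within the
6-pixel tolerance of the ground truth. `demo/Results/flight1/` contains
`positions.csv` (`frame,id,x,y,interpolated`), `boxes.csv`, trajectory
plots before and after interpolation, and `run.log` with the effective
configuration (including the 1040 → 1056 image-size adjustment).

A shell front end with the same parameters is installed at
`inst/cli/mostrack` (`track`, `simulate`, `evaluate` subcommands).

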