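# btx — multi-animal tracking with posture, visual fields, and visual identification

`btx` is an R toolbox for tracking many visually similar animals in
grayscale video and keeping their identities straight. It is aimed at
behavioural researchers who need per-individual trajectories — positions,
body posture, and what each animal could see — from top-down laboratory
recordings of fish, insects, or anything else that moves against a static
background.

Kinematic tracking alone inevitably swaps identities whenever animals
cross, merge, or leave the frame; over a long video the labels shuffle
completely. `btx` implements the full correction pipeline around that
problem:

* **Segmentation** — background models (pixelwise min / max / mode / mean
  over sampled frames), luminance equalization, thresholded
  background-difference blobs with 8-connected components, or external
  binary masks. Results stream into a seekable `.pvs` blob container
  (random frame access, optional lossless deflate).
* **Tracking** — per-frame data association by maximizing the sum of
  assignment probabilities
  `p = exp(-d²/2σ²)·0.5^(gap/T)`, `σ = v_max·Δt/3`, over local cliques,
  with an exact tree search (branch-and-bound), a Hungarian fallback, and
  a greedy approximation; merged animals are re-separated by raising the
  threshold on the background-difference image until similarly sized
  components emerge, with watershed-style pixel regeneration.
* **Posture** — pixel-corner outline tracing (shoelace area equals the
  pixel count exactly), elliptic Fourier or weighted smoothing, head/tail
  detection by pointedness, midlines with a body-thickness profile, and
  pose-normalized crops (head anchored, body axis aligned).
* **Visual fields** — per-eye ray casting against all outlines, 260° per
  eye, with occluder identity, distance, and body-part channels over
  multiple occlusion orders.
* **Visual identification** — the uniqueness-guided training loop: split
  trajectories at every problematic event, find *global segments* where
  every individual is simultaneously inside one switch-free segment, rank
  them by spatial coverage, train a classifier (initial unit → guided
  accumulation → final unit) and monitor per-frame *uniqueness*
  `U = (|uids|/n)·E(mean p)`, `E(v) = (1+e^-π)/(1+e^-πv)`; contested
  assignments resolve by `S(p,x) = sig(p) + sig(x)`,
  `sig(x) = (1+e^{2π(0.5-x)})^{-1}`, deferring near-ties (probability
  ratio > 0.6) to the kinematics.
* **Synthetic scenes** — a ground-truthed generator (correlated random
  walks, teardrop bodies with per-identity textures, scheduled pass-through
  crossings, disappearances) so every stage can be tested against known
  truth, plus `score_identity_accuracy()` implementing the standard
  1%-of-video-width agreement score.

## Worked example

Simulate a 12-second scene of four textured agents with frequent
crossings, track it, then let visual identification repair the switches:

```r
library(btx)

cfg <- scene_config(n_agents = 4, n_frames = 300, frame_size = c(320, 320),
                    agent_length = 30, agent_width = 10,
                    overlap_rate = 4, disappear_prob = 0.002, seed = 42)
d <- generate_dataset(cfg)

bg <- estimate_background(d$frames[seq(1, 300, by = 15)], "mode")
blobs <- lapply(d$frames, segment_frame, background = bg,
                config = seg_config(threshold = 25, blob_size_range = c(40, 8000)))
tracks <- track_frames(blobs, (0:299) / cfg$fps,
                       tracker_config(track_max_individuals = 4,
                                      track_max_speed = 500),
                       background = bg, seg_threshold = 25)
tracks
#> <tracks: 4 individuals over 300 frames>

raw <- score_identity_accuracy(tracks_table(tracks),
                               d$truth[d$truth$visible, ], width = 320)
#> kinematic tracking alone: 51.5% of (frame, individual) pairs correct

vid <- run_visual_id(tracks, 320, 320, N = 4, id_config(seed = 1),
                     posture_config(normalized_zoom = 1.6))
vid
#> <visual id: mean uniqueness 0.867, 48 segments>
corrected <- score_identity_accuracy(vid$table,
                                     d$truth[d$truth$visible, ], width = 320)
#> after visual identification:  99.0% correct (mean uniqueness 0.87)
```

At this crossing density the kinematic tracker keeps only half of the
(frame, individual) assignments on the right animal; the identification
stage, trained purely on automatically selected switch-free stretches,
restores 99%. Posture is available per blob:

```r
po <- blob_posture(blobs[[1]][[1]], posture_config(normalized_zoom = 1.6))
#> blob 1: 188 px, midline length 27.7 px, max thickness 10.2 px
```

and `compute_visual_field()` turns the postures of a frame into per-eye,
per-occlusion-order angular images.

## Command line

The same pipeline runs headless through `exec/btx`, staging artifacts in
an output directory:

```sh
btx simulate  --out run1 -s n_agents=4 -s n_frames=300 --seed 42
btx convert   --out run1      # renders + segments into run1/video.pvs
btx track     --out run1
btx identify  --out run1      # corrected.csv + segment_report.csv
btx export    --out run1      # per-individual trajectory tables
btx evaluate  --out run1      # prints the similarity-vs-truth JSON
```

Parameters come from `-s key=value` flags or a plain-text config file
(`-c`), with command line > file > defaults precedence; every run appends
to a machine-readable `run_log.jsonl`.

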