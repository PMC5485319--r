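# mrartefact

Simulation and automated detection of motion artefacts in magnetic
resonance (MR) images.

MR data are acquired sequentially in *k*-space (the spatial-frequency
domain), so a subject who moves during the scan leaves the recorded data
internally inconsistent; the reconstructed image then shows ghosting,
smearing, blurring, or streaking whose character depends on the sampling
geometry. `mrartefact` is for researchers studying automated image-quality
control: it synthesizes realistic motion artefacts by corrupting *k*-space
according to a motion trajectory, and detects corrupted images with a
supervised decision forest.

The core pipeline:

1. **k-space simulation** — Cartesian, radial, and spiral trajectories with
   a forward transform `s(k) = Σ_x I(x)·exp(−2πi k·x)` (exact FFT on-grid;
   Kaiser–Bessel gridding NUFFT off-grid, accurate to < 1e-6 per sample
   against a direct sum) and a density-compensated adjoint reconstruction.
2. **Motion synthesis** — bulk rigid motion (6 degrees of freedom;
   translation norm ≤ 3.64 mm, rotations within ±5°): part of the clean
   *k*-space, whole readouts at a time, is exchanged for the *k*-space of
   the rigidly moved subject, parameterized by the exchanged *fraction* and
   its *offset* into the scan. Respiratory motion: a sinusoidal
   superior–inferior heart translation of up to 7 mm,
   `d(t) = max·(1 − cos(2π·cycles·t/n))/2`, with successive readouts drawn
   from successive breathing positions.
3. **Features** — box (patch mean/variance), line-profile (sd/range),
   histogram (mean, variance, skewness, kurtosis, entropy, energy), and
   Haralick texture features (13 GLCM statistics averaged over the four 2D
   directions), from a frozen random specification applied identically to
   every image inside a heart-centered (or full-image) ROI.
4. **Detection** — balanced one-image-per-subject datasets and a
   100-tree decision forest evaluated with subject-disjoint 5×3 nested
   cross-validation.

Seeded brain-like and cardiac-like phantom generators make the whole study
reproducible from integer seeds with no external data.

## Worked example

Simulate a subject who moved to a new position after 20% of a Cartesian
scan and stayed there for another 20%:

```r
library(mrartefact)

vol  <- make_brain_phantom(1, c(128, 128, 32))   # seeded synthetic head
traj <- make_cartesian_trajectory(128)
move <- sample_bulk_transform(2)                  # random 6-DOF transform
move
#> <rigid_transform> rot (deg): -4.0558 -0.3544 -3.2528  trans (mm): 0.04423 -3.56114 0.75229

rec <- simulate_bulk_artefact(vol, move, traj, offset_fraction = 0.2,
                              exchange_fraction = 0.2)
sqrt(sum((rec$corrupted$data - rec$clean$data)^2) / sum(rec$clean$data^2))
#> [1] 0.1518572
```

The corrupted reconstruction differs from the clean one by ~15% in
relative L2 — smearing along the phase-encoding direction. Exchanging the
same readouts in a radial acquisition spreads the inconsistency across
diagonal streaks of much lower energy, which is why detection difficulty
depends on geometry.

Run a small detection experiment (60 subjects, box features only):

```r
cfg <- list(phantom = "brain", shape = c(128, 128, 32),
            trajectory = list(geometry = "cartesian", n_lines = 128),
            motion = list(type = "bulk", offsets = 0.2, fractions = 0.2),
            features = list(counts = c(box = 200)),
            n_subjects = 60, cv = list(outer_k = 5, inner_k = 3),
            seed = 11)
ex <- run_experiment(cfg)
ex$results
#>   dataset_seed accuracy offset fraction
#> 1            1        1    0.2      0.2
```

A fraction of 0.2 near the scan start is detected perfectly; a single
exchanged line at the outermost *k*-space fringe drops to ~0.7–0.77, and a
no-exchange null experiment sits at chance — the difficulty gradient that
motivates geometry-aware quality control.

A command-line interface wraps the same functions
(`inst/cli/mrartefact phantom|simulate|experiment ...`), writing NIfTI
volumes, side-by-side PNGs, and a JSON manifest sufficient to replay any
run.

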