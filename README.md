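# minicircle

Detecting sequence-dependent **poloidal orientation** in DNA minicircles.

When a ~105-bp duplex is ligated into a covalently closed circle, bending
anisotropy (roll is cheaper than tilt) makes the helix prefer particular
rotational registers about its own axis — the *poloidal* angle. A label at a
fixed sequence position then sits preferentially inside or outside the ring,
and the preference rotates with the ~10.5-bp helical period as the label is
moved along the sequence. This package provides the full computational
pipeline for that measurement, for structural biophysicists working with
coarse-grained minicircle models and AFM colocalization images:

* **Geometry** — ideal three-site (sugar/phosphate/base) duplex models on
  perfect helices, `quantize_twist()` to an integer number of turns,
  `circularize()` into a planar uniformly twisted minicircle
  ((x, y, z) → (x, y·cos(z/R), y·sin(z/R)), R = n·Δz/2π), and
  `close_topology()` adding the 6 bonds + 6 angles + 16 dihedrals that seal
  the junction. MD data / dump file IO included (no dynamics — building and
  analysis only).
* **Poloidal analysis** — per-frame global-morphology poloidal angle
  `atan2(ŷ·(P₀−O), x̂·(P₀−O))` from four equidistant phosphates and a 10-bp
  centroid origin O; signed horizontal displacement x (positive = inside);
  circular statistics (mean direction, R̄, σ = √(−2 ln R̄)).
* **AFM analysis** — polynomial flattening, threshold + connected-component
  segmentation, deterministic DNA/protein/complex classification, offset
  distance δ = ‖r_centroid − r_COM‖ (nm), and relative affinity
  **α = N_DP / (N_D · N_P)**.
* **Phase fitting** — fixed-period (10.5 bp) sinusoid fits weighted by 1/sd²,
  peak positions, `peak_lag()`, `lag_to_degrees()` (5.5 bp → 188.6° ≈ 189°).
* **Synthetic data** — generators with ground truth for all of the above:
  minicircle ensembles with a *prescribed* (calibrated) von Mises poloidal
  law, AFM scenes of rings/spots/complexes, and noisy δ series.

## Worked example

```r
library(minicircle)

## build a closed 105-bp minicircle
set.seed(1)
seqc <- paste(sample(c("A","C","G","T"), 105, replace = TRUE), collapse = "")
mini <- build_minicircle(seqc)
mini
#> DNA minicircle: 105 bp, 630 atoms, R = 5.682 nm, topology closed
closure_gap(mini)            # 7.5e-15 nm -- seamless at quantized twist
sum(mini$dihedrals$closure)  # 16 junction dihedrals
write_md_data(mini, "mini.data")   # LAMMPS-dialect data file + type-map JSON

## a synthetic ensemble with prescribed poloidal law VM(189 deg, kappa = 10)
tr <- simulate_poloidal_trajectory(n_bp = 105, frames = 500, mu_deg = 189,
                                   kappa = 10, noise_sd = 0.05, seed = 1)
trajectory_stats(tr)$angle
#> Circular stats (n = 500): mean 188.34 deg, std 19.07 deg, Rbar 0.9461
# mean x = -0.981 nm: the reference phosphate sits *outside* the ring

## two delta series one half-turn apart -> lag and phase shift
rep <- run_workflow(list(workflow = "phase",
  series_a = list(peak = 1.3, amplitude = 0.4, offset = 1.6, noise_sd = 0.05,
                  n_per_pos = 50, seed = 1),
  series_b = list(peak = 6.8, amplitude = 0.4, offset = 1.6, noise_sd = 0.05,
                  n_per_pos = 50, seed = 2)), out_dir = "out_phase")
#> lag: 5.51 bp   phase: 188.9 deg    (truth: 5.5 bp = 188.6 deg)

## an AFM scene: 5 minicircles, 3 free proteins, 2 complexes
sc <- simulate_afm_scene(n_rings = 5, n_spots = 3, n_complexes = 2,
                         size_px = 256, noise_sd = 0.1, seed = 3)
img  <- flatten_image(sc$image, 2)
blobs <- classify_blobs(segment_blobs(img, 0.5, min_area_px = 4),
                        area_range = c(25, 200), intensity_range = c(0.9, Inf))
attr(blobs, "counts")
#> Scan counts: N_D = 5, N_P = 3, N_DP = 2
relative_affinity(attr(blobs, "counts"))$alpha
#> 0.1333333
# median delta of the complexes (markers outside): 1.92 nm
```

Interpretation: the ensemble's circular mean (188.3°) recovers the
prescribed 189° within sampling error, and its negative horizontal
displacement says the phosphate faces outward, consistent with
cos(189°) < 0. The two series, generated with peaks 1.3 and 6.8 bp, yield a
5.5-bp lag — a 188.6° phase shift at the 10.5-bp helical period, i.e. the
two sequences hold their labels on nearly opposite poloidal faces.

## Command line

```sh
Rscript inst/cli/minicircle.R build --sequence circle.fa --out model.data
Rscript inst/cli/minicircle.R simulate traj --config traj.json --out run/
Rscript inst/cli/minicircle.R analyze-traj --dump run/trajectory.dump \
        --atom-map model.data.atom_map.csv --out stats/
Rscript inst/cli/minicircle.R analyze-afm --image scan.txt --out afm/
Rscript inst/cli/minicircle.R fit-phase --series a.csv --series b.csv --period 10.5 --out phase/
```

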