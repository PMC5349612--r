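# rollmap

Label-free mapping of cell-surface adhesion from rolling motion.

Leukocytes (and circulating tumor cells) attach to vessel walls by **rolling
adhesion**: under shear flow, transient selectin–ligand bonds let the cell
roll along the surface. Conventional assays track only the cell centroid,
which says nothing about *where* on the cell surface the adhesive contacts
are. `rollmap` implements two complementary analyses that recover that map:

1. **Rotation tracking.** Bright intracellular scatterers (azurophilic
   granules in dark-field movies) serve as rotational fiducials. From each
   spot's cell-frame trajectory, the raw angle
   `α = arccos(x_cm / R) ∈ [0, π]` is unfolded (alternating intervals
   reflected as `θ' = 2π − α`) into a cumulative rotation angle `θ(t)`.
   While the cell maintains traction, `v = rω`; the dimensionless metric
   `r·dθ/dx` is ≈1 when rolling and ≤0.5 during transient detachment, and
   the slope of `θ` versus `x` measures the circumference (`d = 2/slope`)
   independent of imaging calibration. The **dwell time per unit angle**
   `τ(θ) = 1/ω(θ)` is the adhesion proxy: stacked over 2π periods it gives
   a single-cell adhesion map, and its autocorrelation over cumulative `θ`
   shows peaks at every `2nπ` when adhesion is patchy — peaks that survive
   detachment because rotation, unlike position, never loses registration
   with the cell surface.

2. **Adhesion footprinting.** Rolling on surfaces carrying digital DNA
   tension sensors leaves fluorescent marks wherever adhesive load exceeded
   the ~12 pN rupture threshold. The pipeline flat-fields the tiles
   (`I_corrected = (I0 − Ibg)/I_illumination`), stitches them by overlap
   cross-correlation (integer offsets, no blending), and extracts the track
   periodicity by 2D cross-correlation against a single repeating unit and
   by 1D autocorrelation along the track (lag axis normalized by `πd`).
   The transverse track width gives the contact geometry:
   `area = π(w/2)²`, surface fraction `= area/(πd²)`.

Every stage is testable without experimental data: the package ships
simulators for rolling-cell movies, footprint tiles and a random-microvilli
contact model (all seeded, with ground truth returned alongside), plus a
parallel-plate wall-shear-stress calculator `τ_w = 6μQ/(w0·h0²)`.

## Worked example

```r
library(rollmap)

## a cell with two adhesion patches, two intracellular scatterers
profile  <- adhesion_profile(
  data.frame(center = c(0.7 * pi, 1.5 * pi), width = c(pi / 2, pi / 3),
             multiplier = c(4, 3)), baseline_dwell = 0.25)
geometry <- cell_geometry(14.1, spots = rbind(c(4.5, 1.5, 1.0),
                                              c(-3.0, -1.5, 3.5)))
mv  <- simulate_rolling_movie(profile, geometry, imaging_params(),
                              n_cycles = 5, seed = 42)
res <- run_rotation_pipeline(list(movie_array = mv$movie, pixel_size = 0.53,
                                  frame_interval = 1/30,
                                  output_dir = tempfile()))
cell <- res$results[[1]]
as.numeric(cell$diameter)          # 14.1  (um, from the theta-vs-x slope)
cell$dwell_map$n_cycles            # 5     (2-pi periods stacked)
cell$acf$peaks
#   order    lag value
# 1     1  6.283 0.997
# 2     2 12.566 0.996
# 3     3 18.850 0.993
patch_size_fraction(cell$acf)      # 0.169 (patch size / circumference)
contact_geometry(5.7, 14.1)        # area 26 um2, 4.1 % of the surface
```

The autocorrelation peaks at `2π, 4π, 6π` say the dwell pattern repeats
every full rotation — the signature of fixed adhesion patches on the cell
surface; the peak width converts to a characteristic patch size (here ~1/6
of the circumference for this two-patch cell). The last line is the contact
geometry implied by a 5.7 um contact width on a 14.1 um cell.

A thin command-line front end with subcommands `simulate-movie`,
`simulate-footprint`, `simulate-villi`, `track`, `map`, `footprint` and
`report` is installed at `inst/scripts/rollmap`.

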