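# bpq — quantification of 3D-bioprinted branched epithelial cultures

`bpq` is an R package for designing, simulating and quantifying Y-shaped
3D-bioprinted mammary epithelial cell cultures. It is aimed at groups who
print branched epithelial structures (e.g. MCF10A or DCIS-like cells in a
collagen-I/basement-membrane-extract gel) and want reproducible,
scriptable readouts of where a culture grows, proliferates and invades —
the kind of analysis usually assembled by hand in Fiji.

The package covers five things:

1. **Structure design and toolpath.** A parametric Y (stem + two branches
   meeting at a branch point; default 100 µm stroke, 60° branch angle,
   1 mm arms), rasterization to binary masks, and RepRap-dialect G-code
   generation/parsing for a 4-structure well layout printed at 1 mm/s
   under 5 mbar.
2. **Region partitioning.** Every foreground pixel is assigned to
   `tip_stem`, `tip_left`, `tip_right` or `trunk` by its nearest skeleton
   point: pixels whose nearest point lies within a fraction
   `tip_fraction` (default 0.3) of a segment's free end belong to that
   segment's tip; ties at the branch point go to the trunk.
3. **Image quantification.**
   - growth expansion: per-region area ratio between two segmented
     timepoints, `A_14/A_3`;
   - invasion: morphological opening with a disk erases protrusions
     narrower than twice the radius; the largest component is the main
     structure, the remainder the invasion mask; per region group the
     invasion area is normalized by outline length (µm²/µm);
   - proliferation: Ki67⁺ nuclear area over DAPI nuclear area per
     sub-region, with a shared threshold so the ratio lives in [0, 1];
   - viability: nuclei as DAPI local maxima, propidium-iodide-positive
     fraction, `100·(1 − n_PI/n)`;
   - confluence normalized to the 0-h frame.
4. **AFM stiffness.** The Hertz spherical-indentation model
   `F = (4/3)·E/(1−ν²)·√R·δ^{3/2}`, separable least-squares fitting of
   `E` and the contact offset δ₀, the 3 × (5×5) × 3 = 225-curve sampling
   plan, and a Shapiro–Wilk-checked mean ± SD summary.
5. **Statistics.** The normality-gated two-group procedure: Shapiro–Wilk
   on the data (or paired differences), then paired/unpaired t test or
   Wilcoxon signed-rank / Mann–Whitney, with `ns`/`*`/`**`/`***`/`****`
   labels (`p ≤ 0.05, 0.01, 0.001, 0.0001`).

Because no imaging data are distributed with the package, a seeded
synthetic-data generator produces culture scenes (mask + DAPI/Ki67/PI
channels) and indentation curves with known ground truth; every pipeline
stage is tested against planted parameters.

## Worked example

```r
library(bpq)

# a day-3 / day-14 synthetic timecourse of one printed structure
tc     <- generate_timecourse(day3_scene_params(seed = 1), scene_params(seed = 1))
design <- y_design()
part   <- partition_regions(tc$day14$culture_mask, design, tip_fraction = 0.3)
growth <- growth_expansion(tc$day3$culture_mask, tc$day14$culture_mask, part)
print(growth, digits = 3)
#>      region area_day3_um2 area_day14_um2 expansion_ratio percent_change
#> 1     trunk        225504         269520            1.20           19.5
#> 2  tip_stem         38464          71840            1.87           86.8
#> 3  tip_left         37696          66080            1.75           75.3
#> 4 tip_right         37696          66128            1.75           75.4
#> 5      tips        113856         204048            1.79           79.2
```

The tips expand ~1.8× from day 3 to day 14 versus ~1.2× at the trunk —
the tip-biased growth the synthetic generator plants. Proliferation shows
the same spatial pattern, strongest at the stem tip (the tip farthest
from the branch point):

```r
ki67_ratio(tc$day14$dapi, tc$day14$ki67, part)
#>      region dapi_area_um2 ki67_area_um2 ratio
#> 1     trunk         61376          6640  0.11
#> 2  tip_stem         16768          7232  0.43
#> 3  tip_left         14992          3504  0.23
#> 4 tip_right         15584          4304  0.28
#> 5      tips         47344         15040  0.32
```

Matrix stiffness from 225 simulated indentation curves (ground truth
103.4 Pa, 5% force noise, 4 nN setpoint, 2.25 µm bead radius):

```r
curves <- generate_afm_curves(E_true = 103.4, noise_sd = 0.05, seed = 1)
summarize_modulus(lapply(curves, fit_hertz))
#> <modulus_summary> E = 103.6 +/- 1.16 Pa (n = 225, Shapiro-Wilk p = 8.96e-10)
```

And the comparison procedure on paired per-structure readouts:

```r
compare_groups(c(2.01, 1.93, 1.87, 2.10, 1.78, 1.95),   # tips
               c(1.21, 1.17, 1.25, 1.19, 1.30, 1.08),   # trunk
               paired = TRUE)
#> <comparison_result> paired_t: stat = 11.16, p = 0.0001006 *** (n = 6/6, paired)
```

An end-to-end run (simulate → partition → quantify → compare, with CSV
reports and a manifest) is one call:

```r
run_pipeline(read_run_config(system.file("extdata", "demo_config_dcis.json",
                                         package = "bpq")),
             out_dir = "dcis_run")
```

## Command line

`inst/exec/bpq` exposes the same operations:

```sh
bpq design gcode --out well.gcode
bpq simulate timecourse --out scenes --seed 1 --mode dcis
bpq quantify --scene scenes/day14 --out metrics.csv --radius-um 30
bpq stats compare --in metrics.csv --value-col value --group-col region --out cmp.csv
bpq run --out demo_run --config inst/extdata/demo_config.json
```

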