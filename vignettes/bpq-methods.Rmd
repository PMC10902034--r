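---
title: "Models, parameters and design choices in bpq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in bpq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bpq` quantifies Y-shaped 3D-bioprinted mammary epithelial cultures:
where they grow, where they proliferate, where they invade, and how stiff
the surrounding gel is. This vignette explains the models behind each
readout, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical decisions a
maintainer should know about. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The structure model

A printed structure is a skeleton of three straight segments sharing a
branch point: a stem of length $L_s$ along $+y$ and two branches of
length $L_b$, mirror-symmetric about the stem axis, separated by the
branch angle $\theta$. The printed material occupies all points within
half the stroke width $w/2$ of the skeleton (round caps). Defaults:
$w = 100\,\mu m$ (the minimum nozzle size of the printing protocol),
$\theta = 60^\circ$, and $L_s = L_b = 1000\,\mu m$. The segment lengths
are an assumption — the published design figure prints no lengths — and
are configurable in `y_design()`.

Rasterization marks every pixel whose center lies within $w/2$ of the
skeleton. The grid is laid out so that pixel *edges*, not centers, fall
on multiples of the pixel size in design coordinates. This matters: with
the stem centred on a coordinate axis, an edge-aligned grid makes the
digitized stroke symmetric, and the measured width (twice the median
distance-transform value along the skeleton) is exactly $w$ whenever
$w/\mathrm{pixel\ size}$ is even. A center-aligned grid would bias the
measurement by up to one pixel.

## Tip/trunk partitioning

Biologically, the tips of the Y play the role of terminal end buds; the
paper compares them against the trunk. The published schematic does not
define the regions algorithmically, so `partition_regions()` uses a
nearest-skeleton rule: each foreground pixel belongs to the segment whose
nearest point is closest; if that nearest point lies within
`tip_fraction` of the segment length from the free end, the pixel is that
segment's tip, otherwise trunk. `tip_fraction = 0.3` by default,
reproducing the approximate extent of the schematic's terminal caps while
staying robust when the culture bulges outward.

Two conventions are worth noting. Pixels equidistant between two segments
(the branch-point neighbourhood) are always trunk, so ties never inflate
tip areas. And pixels beyond a free endpoint project to the endpoint
itself (arc position $= L$), so they are tip for *any* positive
`tip_fraction`: as `tip_fraction` $\to 0$ the tip regions shrink to the
three end caps, not to the empty set. This is the correct limit of the
nearest-point rule; tests assert the cap-area limit explicitly.

## Growth expansion

Following the published procedure, the day-3 and day-14 segmented masks
are superimposed and the per-region expansion ratio
$A_{14}/A_3$ reported ("relative change" is ambiguous, so the ratio is
the primary output and percent change is also emitted). Regions with zero
day-3 area yield `NA` with a warning rather than an error, since a
far-flung protrusion can create such regions legitimately.

## Invasion extraction and normalization

Invasions are protrusions out of the main structure. They are extracted
exactly as in the original Fiji workflow: a morphological opening with a
disk erases features narrower than twice the radius; what the opening
removed (minus components smaller than `min_component` pixels, a noise
guard) is the invasion mask. The human step of erasing leftover fragments
is replaced by a reproducible surrogate: keep the largest connected
component of the opening as the main structure. Area bookkeeping is exact
by construction: main + invasion + discarded = original foreground, in
pixels.

The published radii (30 px for day-14, 20 px for day-10 images) are in
the pixel scale of the original transmitted-light images, which is not
stated. `extract_invasion()` therefore takes the radius in pixels, as
printed, while the pipeline configuration carries `opening_radius_um`
(default 30 µm — the printed number read at a 1 µm/px assumption) and
converts using the actual pixel size. At the default 4 µm/px synthetic
scenes this gives 7.5 px, which removes the 20 µm synthetic protrusions
(width $< 2r$) and preserves the $\geq$ 130 µm-wide day-14 strokes.

Each invasion pixel is attributed to the group (tips or trunk) of the
nearest main-structure outline pixel, and each group's invasion area is
divided by that group's **total** outline length, giving µm²/µm. The
source text divides by "the average length of the respective sub-region
outline"; we read "average" as averaging over replicate structures rather
than over the three tip outlines. The alternative reading (divide the
pooled tip area by the *mean* single-tip outline) inflates the tip metric
threefold and would make uniformly seeded invasions appear tip-biased —
under it, even the strongly trunk-weighted invasion pattern of the
DCIS-like scenario would not reliably rank trunk above tips, contradicting
the qualitative finding the metric was built to show. With the total-length
normalization, uniform seeding gives equal tip and trunk densities (the
non-cancerous scenario) and trunk-weighted seeding ranks trunk above tips
on every tested seed. `outline_length()` itself still exposes the
per-sub-region lengths and their tip average for users who want the other
convention.

Outline length uses a 4-direction Crofton (line-intercept) estimator: the
perimeter is $\frac{\pi}{8}(T_0 + T_{90} + (T_{45} + T_{135})/\sqrt{2})$
times the pixel size, where $T_d$ counts foreground/background
transitions along sampling lines in direction $d$. Raw marching-squares
polygon length overestimates smooth boundaries by about 6% on digitized
disks; the Crofton estimator is within ~1.6% at radii of a few tens of
pixels (it slightly underestimates axis-aligned polygons — acceptable,
since outlines here are curved). An independently coded line-walking
implementation serves as the test oracle.

## Proliferation (Ki67/DAPI) and viability (PI)

The proliferation readout is the Ki67-positive nuclear *area* over the
DAPI nuclear area per region, exactly as in the source workflow (no
instance segmentation). Two choices close gaps the source leaves open:
one common threshold — Otsu's on the DAPI channel by default — is applied
to both channels, so a blank Ki67 channel gives a ratio of 0 and
identical channels give 1; and the Ki67 mask is intersected with the DAPI
mask, keeping the ratio in $[0,1]$ (raw channel-area ratios can exceed
1). On synthetic scenes the area ratio recovers planted per-region
Ki67 fractions within ±0.05.

Viability detects nuclei as strict local maxima of the DAPI channel above
a threshold and scores a nucleus dead when the PI signal at its position
exceeds `pi_threshold` (0.5 for the generator's unit-peak channels).
Counting by maxima is reliable only while nuclei are optically resolvable.
The published viability claim concerns cultures imaged immediately after
printing — sparse single cells — so the matching generator preset
(`viability_scene_params()`) renders an undilated design with
0.002 nuclei/µm² (~600 nuclei, mean spacing ≈ 11 µm). In crowded day-14
scenes merged maxima undercount the denominator and bias viability
downward by a point or two; that regime is not used for the viability
claim.

## AFM stiffness

Force–indentation curves follow the Hertz model for a rigid sphere on an
elastic half-space, $F = \frac{4}{3}\frac{E}{1-\nu^2}\sqrt{R}\,
\delta^{3/2}$, with $\nu = 0.5$ (incompressible gel), $R = 2.25\,\mu m$
(a 4.5 µm bead) and a 4 nN setpoint. The sampling plan mirrors the
protocol: 3 regions × 5×5 grid over 100×100 µm² × 3 repeats = 225 curves.

`fit_hertz()` estimates $E$ and a contact offset $\delta_0$ (the data
are modelled as Hertz on $\max(\delta-\delta_0, 0)$). The problem is
separable — given $\delta_0$, the optimal $E$ is closed-form linear least
squares — so $\delta_0$ is found by deterministic golden-section search
on $[0, 0.9\,\delta_{max}]$ with the boundary $\delta_0 = 0$ also
evaluated exactly; there is no random initialization. Points above the
force cap are excluded. A fit is flagged non-converged when the relative
residual $\sqrt{rss/\sum F^2}$ exceeds 20%.

One visible artifact of the non-negativity clamp on $\delta_0$: under
noise the true optimum is sometimes (infeasibly) negative, so the fitted
$E$ distribution across many curves is slightly right-skewed and can fail
a Shapiro–Wilk check even though each fit is unbiased to well under a
percent. `summarize_modulus()` warns in that case, by design; the mean
remains within the tested 5% of the planted modulus.

## Statistical procedure

`compare_groups()` reproduces the published decision rule: Shapiro–Wilk
at $\alpha = 0.05$ on each group, or — for paired data — on the paired
differences (the source is silent here; the t test's normality assumption
concerns the differences, so the gate is applied to them). Normal data
get a two-tailed paired/unpaired t test; otherwise the Wilcoxon
signed-rank (paired) or Mann–Whitney (unpaired) test. Rank tests use the
exact null distribution for $n \le 25$ without ties, else the
continuity-corrected normal approximation. A zero-variance sample is
treated as non-normal (the Shapiro–Wilk statistic is undefined for
constant data); identically zero paired differences are an explicit
error, since the signed-rank statistic is undefined. No multiple-testing
correction is applied, matching the source. Under a simulated null the
paired-t branch holds its 5% type-I error within ±1% over 10⁴ replicates
(tested).

Star labels use the ≤ convention: `ns` ($p > 0.05$), `*` ($p \le 0.05$),
`**` ($\le 0.01$), `***` ($\le 0.001$), `****` ($\le 0.0001$); boundary
values take the stronger label.

## The synthetic generator: what it emulates, what it does not

`generate_scene()` renders, deterministically per seed:

* **Region-dependent growth** — each pixel's stroke half-width is scaled
  by its region's growth factor. Day-3 defaults are a uniform 1.1; day-14
  defaults are 1.9 (stem tip), 1.7 (branch tips), 1.3 (trunk), chosen
  once so that tips visibly bulge, the stem tip leads, and expansion
  ratios land in a plausible 1.2–1.9× range; the published work reports
  orderings, not magnitudes, and these defaults are asserted only through
  orderings.
* **Invasive protrusions** — persistent random-walk tubes (width 20 µm,
  step 10 µm, persistence 0.8, mean length 60 µm) seeded on the culture
  outline. Region weights act per unit outline, so equal weights mean
  uniform seeding (the non-cancerous pattern) and the DCIS-like preset
  weights trunk outline 4:1. Tube width is below twice the default
  opening radius by construction, so extraction removes protrusions
  exactly.
* **Nuclei and channels** — nuclei scattered uniformly in the mask at
  0.004/µm² (day 14; ≈ 15 µm spacing, a confluent epithelial projection),
  marked Ki67⁺ with per-region probabilities (day-14 defaults 0.45 stem
  tip, 0.28 branch tips, 0.10 trunk) and dead at 3%. Channels are sums of
  unit-peak Gaussian spots ($\sigma = 3\,\mu m$) plus 2% additive Gaussian
  background.

It does **not** emulate: photorealistic microscopy (PSF tails, shading,
vignetting), 3D stacks (a single plane stands in for maximum
projections), cell mechanics, lumen or basement-membrane rendering, or
cell-scale texture in the transmitted-light mask. A green test therefore
establishes that the *measurement pipeline* recovers planted spatial
statistics from idealized images — not that it would segment difficult
real micrographs; segmentation thresholds and radii remain exposed for
that reason.

## Numerical conventions

* Images are row-major, top-left origin, pixel-center coordinates; world
  y decreases with rows. Areas are pixel counts × pixel size²; default
  analysis resolution 4 µm/px.
* Binary morphology uses the exact Euclidean distance transform
  (two-pass lower-envelope algorithm in C++); erosion keeps pixels
  farther than $r$ from background, with the image border counting as
  background. Results are identical to brute-force structuring-element
  sweeps (tested up to 128²).
* Registration is rigid (centroid + principal axis) with the 180°
  ambiguity resolved by symmetric-difference area; no scaling, because
  pixel size is metadata, not a fit parameter.
* File formats are deliberately plain text: PGM (P2) images, CSV tables,
  JSON sidecars/configs. TIFF input from real microscopes should be
  converted upstream; no binary codec is bundled.

## Known limitations

* The tip/trunk boundary is geometric, not intensity-based; a culture
  that detaches from the printed frame needs manual registration.
* Outline attribution of invasion pixels uses nearest-outline distance;
  a protrusion crossing a region boundary is split, not assigned to its
  biological origin.
* Viability by local maxima degrades in crowded scenes (see above).
* The Hertz fit assumes a homogeneous half-space; finite-thickness and
  adhesion corrections (JKR/DMT) are out of scope.
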