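---
title: "Detecting two-phase contraction waves in PIV vector fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting two-phase contraction waves in PIV vector fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(waveseg)
```

## The problem

Epithelial tissues such as the extra-embryonic membranes of insect embryos
can show recurring *contraction waves*: large patches of tissue move
coherently in one direction for a few frames (we call this the **V phase**,
for the ventral-ward motion that starts each wave in our motivating system)
and then swing back with a strong dorsal component (the **D phase**). Pixel
intensities alone do not reveal these events; velocity magnitude alone does
not either, because other processes (membrane rupture and retraction, embryo
twitching) also produce high speeds. What identifies a wave is the
*temporal pattern of directions* in the tissue velocity field.

`waveseg` therefore works on gridded displacement fields obtained by
particle image velocimetry (PIV) between consecutive frames of a 2D+t or
3D+t recording. The substrate of all downstream analysis is the **vector
time series** $v_{p,t}$: the displacement vector at one grid position $p$
across all time steps $t$.

## Masked PIV

`compute_piv_pair()` estimates, for each node of a regular grid of
interrogation windows, the displacement $d$ minimizing the normalized
squared-difference score

$$\mathrm{NSQ}(d) = \frac{\sum_x \left(a(x) - b(x+d)\right)^2}
  {\sqrt{\sum_x a(x)^2 \cdot \sum_x b(x+d)^2}},$$

over a bounded search range, with an optional three-point parabolic
sub-pixel fit per axis on the score surface. Squared-difference matching is
more robust than plain correlation for microscopy signals with strong local
intensity variation. Choices that matter:

* **Windows are clipped, never wrapped.** Displacements pushing a
  comparison window past the image border are scored on the overlap only;
  image content is never treated as periodic.
* **Sub-pixel refinement is skipped at a perfect match.** If the best score
  is exactly 0 (identical content) the parabolic fit could only add noise;
  the integer displacement is exact. It is likewise disabled when the score
  peak touches the search border.
* **Masking.** A node is *invalid* when the supplied binary mask covers
  less than `min_mask_fraction` (default 0.5) of its interrogation window,
  or when its window is entirely zero. Invalid nodes carry zero vectors
  everywhere downstream — a deliberate contract: quiescence and invalidity
  are both "no evidence of motion".
* **Defaults** (`piv_config()`): 32 px interrogation windows in 2D, 24 vx
  in 3D, search margin 10 px, 50% window overlap. These are standard values
  for nuclei-labelled light-sheet recordings at roughly 0.6 µm/px and
  minutes-scale frame intervals; all are exposed.

One static mask is used for a whole sequence so that every time step shares
the same node coordinates.

## Temporal wave segmentation

All angles below are in degrees and enter only through their cosines: "A is
within $\theta$ of B" always means $\hat{A} \cdot \hat{B} > \cos\theta$.
Magnitude thresholds are inclusive ($\ge$), angle comparisons strict; both
conventions are fixed and tested.

### Step 1 — candidate detection

For each position, the **direction similarity score**

$$\rho(t) = \frac{1}{|W_t|} \sum_{t' \in W_t} \hat{v}_{t'} \cdot r,
  \qquad W_t = [t-N,\, t+N] \cap [1, T]$$

is the windowed mean alignment between the normalized vectors and the unit
reference direction $r$ (the a-priori V-phase direction). Zero vectors
contribute a zero summand, so quiescent stretches pull $\rho$ toward zero
rather than becoming undefined. Local maxima of $\rho$ mark candidate
V-phase centres $t_{\max}$, local minima candidate D-phase centres
$t_{\min}$; each maximum is paired with the nearest subsequent minimum.

Numerical choices: plateaus resolve to their first frame; series endpoints
are never extrema; and $\rho$ is quantized to 12 decimals so that windows
whose contributions cancel exactly in real arithmetic yield exactly equal
score values — without this, $10^{-17}$-scale floating-point residues can
split a plateau nondeterministically. The half-width default is $N = 2$
(a 5-frame window): at minutes-scale sampling the phases span several
frames, and this is the smallest window that still suppresses single-frame
direction noise. It is a tunable parameter.

### Step 2 — screening a candidate pair

A pair $(t_{\max}, t_{\min})$ survives when

1. $\hat{v}_{t_{\max}} \cdot r > \cos\theta_r$ — the V representative
   points within $\theta_r$ of the reference;
2. $\hat{v}_{t_{\max}} \cdot \hat{v}_{t_{\min}} < \cos\theta_{VD}$ — the V
   and D representatives are separated by more than $\theta_{VD}$;
3. optionally, $\hat{v}_{t_{\min}} \cdot d > 0$ for the unit dorsal axis
   $d$ — the D phase points into the dorsal half-plane. This check is on in
   the lateral-projection preset, where a single dorsal axis exists, and
   off elsewhere.

The raw vector at $t_{\max}$ (not the window average) is used as the
representative: at a $\rho$ maximum the surrounding vectors are coherent,
so the central vector is representative, and the raw vector keeps the rule
local and cheap.

### Step 3 — phase expansion

Each phase grows outward from its seed ($t_{\max}$ for V, $t_{\min}$ for
D), testing frames from nearest to farthest and alternating sides (the
earlier frame first at each distance). A frame joins when its vector points
within $\theta_V$ (or $\theta_D$) of the normalized running average of the
vectors already in the phase, and its magnitude is at least $M_{\min}$. A
side closes at its first failure, so phases are contiguous. V expansion is
bounded above by $t_{\min} - 1$ and below by previously accepted waves; D
expansion starts only after the final V frame (this prevents one phase from
swallowing the other, and guarantees the two phases are disjoint).

If the phases end up separated by a small gap (up to `max_gap`, default 2
frames — typically low-magnitude interface vectors), each gap frame is
assigned to the phase whose average direction it matches best, with ties
going to V; to keep both intervals contiguous, the boundary is placed at
the first gap frame that prefers D. A larger gap rejects the candidate.

### Step 4 — speed filtering

A segmented wave is kept only if the mean V-phase speed is at least
$M_{\mathrm{avg}}$ and the total displacement (the sum of vector
magnitudes over V and D) is at least $M_{\mathrm{total}}$. This is what
separates genuine tissue waves from directionally plausible noise.

### Parameter presets

`wave_params(preset = ...)` bundles the parameter sets for the three
standard data representations:

| parameter | lateral | volume | cylinder | units |
|---|---|---|---|---|
| $\theta_r$ | 40 | 50 | 50 | deg |
| $\theta_V = \theta_D$ | 60 | 60 | 40 | deg |
| $\theta_{VD}$ | 30 | 30 | 30 | deg |
| $M_{\min}$ | 0.5 | 0.5 | 1.0 | px(vx)/frame |
| $M_{\mathrm{avg}}$ | 1.0 | 1.0 | 3.0 | px(vx)/frame |
| $M_{\mathrm{total}}$ | 10 | 10 | 10 | px(vx) |

The looseness is intentional: with one parameter set the algorithm accepts
both waves whose phases are nearly opposite (typical before membrane
rupture) and waves with a much smaller V–D angle (typical after), because
$\theta_{VD}$ only sets a *minimum* separation.

Reference directions follow the same presets: a single posteroventral
diagonal for lateral projections (with dorsal axis $+y$), a tilted 3D
ventral direction for fused volumes, and a two-sided field
(`cylinder_reference_field()`) for cylinder maps, where the ventral
direction flips sign across the map midline.

### Rasterization and spatial post-processing

`segment_field()` applies the temporal algorithm independently at every
node and rasterizes accepted waves into a label volume (0 none, 1 V, 2 D).
Because no spatial coupling exists in the temporal step, isolated spurious
detections are removed afterwards, per frame and per phase:
`morphological_open_labels()` (radius 1 by default; box structuring
element, so solid blocks survive unchanged while 1-cell lines vanish),
`size_filter()` (face-adjacent connected components below `min_size` cells
are dropped; default 50 in 2D), and `region_filter()` (components whose
centroid falls in a user-supplied exclusion region — e.g. around the
embryo's head, which twitches after rupture — are dropped). All three only
ever delete labels and are idempotent. Defaults for radius and minimum
size are pragmatic choices exposed in the configuration, not measured
constants.

## Cylinder-map distortion correction

Projecting a closed surface onto a flat cylinder map distorts lengths,
increasingly so toward the poles. `correct_distortion()` multiplies each
node's pole-to-pole vector component by a per-tile *longitudinal* factor
and the equator-parallel component by a *latitudinal* factor (10 px tiles,
nearest-tile lookup, matching the sampling granularity of the factors).
Angles are not corrected — angle distortion only becomes significant very
close to the poles, which are cropped before analysis
(`polar_crop_rows`).

`make_cylinder_distortion()` provides an analytic phantom for testing: for
a capsule (cylinder with spherical caps) mapped with vertical coordinate
proportional to the cap's axial coordinate, the meridian arc per map length
is $1/\cos\alpha$ ($\alpha$ the polar angle) and the circumference ratio is
$\cos\alpha$, so the longitudinal correction grows above 1 and the
latitudinal correction shrinks below 1 toward the poles, with the equator
exactly undistorted. Correction with a grid followed by its reciprocal
(`invert_distortion()`) restores a field to float tolerance.

`extract_surface_mask()` supports masked 3D PIV: it thresholds a volume,
bridges signal gaps at a chosen spatial scale `alpha` (gap-bridging is the
contract; it is implemented by morphological closing with an
`alpha`-radius ball), fills the interior so only the outer surface
remains, and thickens that surface into a shell (defaults: 6 voxels
inward, 3 outward — enough to capture a nuclear layer without reaching the
tissue below). The guaranteed property, and the one tested, is closure: a
flood fill of the background from the volume border cannot reach the
interior.

## Descriptors

**Divergence maps.** Rather than differentiating a smoothed field,
`divergence_map()` correlates the field with an *expanding template* — a
kernel of unit vectors pointing away from its centre — so the scale of the
divergence estimate is set explicitly by the kernel size (default 17
nodes). Positive values mark expansion, negative constriction. The
operation is linear in the field and odd under field negation; at the grid
border the kernel is clipped, so border estimates are attenuated, never
inflated. `divergence_extrema()` reports the strongest per-frame minima
and maxima after non-maximum suppression within one kernel radius
(strictly — constant regions yield no extrema).

**Kymographs.** `kymograph()` sums a label volume (per phase) or an image
sequence along one spatial axis, producing the (position × time) view in
which recurring waves appear as stripes. Sum is the default reduction;
mean is available for label-density views.

## The synthetic scene generator

`make_wave_field()` builds vector-field sequences with known ground truth:
inside each specified disk and time window the field equals the specified
phase vector (V speed · V direction, then D speed · D direction), plus
optional constant background flow and isotropic Gaussian component noise.
Truth labels mark exactly the specified cells. `make_particle_sequence()`
renders Gaussian spots advected by a prescribed displacement (analytically,
at sub-pixel positions, with wrap-around so spot density is conserved) for
testing the PIV layer itself.

`mini_embryo_scene()` fixes the package's default study conditions: 100
time steps on a 36 × 48 node grid; five pre-rupture waves in one lateral
disk (V phase 3 frames at 2 px/frame along the posteroventral diagonal, D
phase 5 frames at 1.5 px/frame in the opposite direction — V shorter than
D, the empirically typical asymmetry); a rupture frame at 80; and one
post-rupture wave in a shifted region whose D direction is rotated by 60°,
so its V–D angle is 120° instead of 180°. Component noise defaults to
σ = 0.2 px/frame, i.e. 20% of the V-phase `M_avg` threshold. The Gaussian
noise model is a stand-in — real PIV noise is spatially correlated and
signal-dependent — so passing recovery tests on this scene demonstrates
correctness of the algorithmic chain, not robustness to every microscopy
artifact. What the scene deliberately does not emulate: intensity
rendering of the tissue, curvature of the surface, the retraction flow
after rupture, and spatially varying noise.

These sizes keep a full end-to-end run (segmentation of 1728 vector time
series over 100 steps) in the tens of seconds on one CPU while leaving
every stage's behaviour measurable; they are the problem sizes used by the
test suite and the acceptance script.

## Worked example

```{r example, eval = FALSE}
scene <- mini_embryo_scene(seed = 1)
seg <- segment_field(scene$fields, reference_field("lateral"),
                     wave_params(preset = "lateral"))
clean <- postprocess_labels(seg, radius = 1, min_size = 20)
wave_report(clean, rupture_frame = scene$rupture_frame)
#> <wave_report> 6 wave events (5 pre-rupture, 1 post)
#>   median V duration 3 frames, median D duration 5 frames
```

## Known limitations

* Exactly two phases per wave; more complex phase patterns need a
  different rule set.
* The reference direction is an input (constant, preset, or per-node
  field); the package does not infer it from the data.
* The rupture frame is user-supplied bookkeeping, not detected.
* Spatial post-processing is per frame; no spatio-temporal morphology.
* Single-pass PIV without window deformation: strong shear within one
  interrogation window degrades the estimate.
* The divergence extrema are reported per frame; trajectories are not
  linked across frames.
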