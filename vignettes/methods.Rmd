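---
title: "Methods: 3D morphometry of dermal lymphatic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of dermal lymphatic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Light-sheet microscopy of cleared, reporter-labelled skin produces 3D
intensity volumes in which the dermal lymphatic vasculature appears as a
network of bright tubes: blind-ended initial capillaries ascending obliquely
toward the epidermis, a branched precollector plexus running parallel to the
skin surface, and deeper collecting vessels in the dermal adipose layer.
Intraluminal valves appear as compact, distinctly brighter blobs of roughly
10^3^–10^4^ µm³ inside the vessels.  `lymphnet3d` turns such a volume into a
quantitative description of this architecture:

1. **Preconditioning** — isotropic resampling (default 1.8 µm voxels,
   trilinear) and denoising derived from non-local means.
2. **Network segmentation** — dual-threshold 3D hysteresis (foreground =
   connected components of `{I >= t_low}` containing a voxel with
   `I >= t_high`) followed by discarding connected components smaller than
   5.832 × 10^6^ µm³ (10^6^ voxels at 1.8 µm) as artifacts.
3. **Skeleton and graph** — homotopic medial-axis thinning; conversion into
   a node/edge/adjacency graph, repeated until the (node, edge) counts
   converge with a 10 µm minimum edge length; classification of edges into
   *capillary branches* (an endpoint of degree 1, i.e. exiting/blind-ended)
   versus *precollector links*; ROI-border rules (border-touching elements
   < 25 µm are discarded as cropped capillaries, > 300 µm retained as
   cropped precollectors, the unaddressed 25–300 µm interval gets a
   dedicated `border_ambiguous` class so nothing joins either group
   silently).
4. **Valve detection** — inside the network mask: white top-hat with an
   18 µm spherical structuring element, Gaussian blur (σ = 2 voxels),
   local-mean adaptive binarization (sensitivity 0.5), 26-connected
   components, and a 10^3^–10^4^ µm³ volume gate.
5. **Morphometrics** — volume density (network volume / sample volume),
   length density (mm/mm³), capillary lengths, z-ranges and 3D orientation
   (roll/pitch/yaw of the principal axis of the path's second central
   moments), per-layer valve counts (depth bands at 150 and 210 µm
   separating the capillary, precollector and collector layers), and
   inter-valve distances measured along the skeleton path between valve
   projections.

All physical parameters live in micrometers in `pipeline_config()`; voxel
equivalents are derived at run time, so behaviour is independent of the
acquisition resolution.  Two parameters are in voxel units on purpose,
because the methods they feed are conventionally specified in pixels: the
pre-binarization blur σ and the adaptive window width.

## Why the structuring element is 18 µm, and what "attenuation" means

An opening with a ball of radius *r* removes every bright structure that
cannot contain the ball.  Valves are gated at ≤ 10^4^ µm³, i.e. an
equivalent-sphere radius ≤ 13.4 µm < 18 µm, so the opening *removes
valves* while reproducing the vessel tubes themselves (dermal lymphatics
are wide; all phantom radii are ≥ 20 µm) and any slowly varying
background.  The opening is therefore the background estimate, and
"attenuating residual background" is implemented as the white top-hat:
masked intensity minus its opening, clipped at zero.  This is the only
reading under which valves survive the stage, and it is flagged as an
interpretation.

## Numerical choices and deviations a reviewer should know about

* **NLM weighting.**  Plain `exp(-D/h²)` with `h ≈ 0.8·σ` gives near-zero
  weights even for identical patches, because the expected patch distance
  under noise is `2σ²`.  The standard noise-compensated weight
  `exp(-max(D − 2σ², 0)/h²)` is used, with σ estimated by robust MAD of
  z-differences.  Patch radius 1 and search radius 3 are common defaults
  (the source method's parameters are not published); all are configurable.
* **Post-NLM smoothing** (`post_smooth_sigma_vox`, default 1).  The source
  pipeline's denoiser is only described as "derived from" non-local means.
  NLM alone leaves spatially correlated residual noise; where the depth-
  ramped background approaches the low hysteresis threshold this residue
  forms a foam that survives the component filter and riddles the mask
  surface with hundreds of topological handles (which homotopic thinning
  faithfully preserves as spurious graph loops).  A 1-voxel Gaussian after
  NLM removes this failure mode; 0 disables it.
* **Hysteresis thresholds.**  Not published; defaults are data-driven:
  `t_high` = Otsu's threshold of the denoised volume, `t_low = 0.5·t_high`,
  both overridable.
* **Adaptive binarization.**  Foreground iff
  `I > max(µ_local · 2(1−s), k·MAD)` with the paper's `s = 0.5` (plain
  local mean) and window `2·⌊18 µm / voxel⌋ + 1`.  Two deviations, both
  documented: ties go to background (with `>=`, the exactly-zero masked
  background would be foreground and would merge every valve into one
  giant rejected component), and the `k·MAD` noise floor (`valve_floor_mads`,
  default 6, measured on the in-mask enhanced signal) exists because a
  purely relative threshold is scale-free: the top-hat of any noisy vessel
  retains a positive noise pedestal, and `pedestal ≥ 0.4·pedestal` holds at
  *any* SNR, which would mark whole vessel interiors as foreground.  The
  floor is exactly zero on noise-free input, so clean constructions are
  unaffected, and `valve_floor_mads = 0` restores the pure rule.
* **Skeletonization.**  Deterministic sequential homotopic thinning with six
  directional sub-cycles; a voxel is deleted only if it is *simple*
  (Bertrand–Malandain (26,6) characterization), checked at deletion time,
  so topology preservation is unconditional.  Endpoints (≤ 1 foreground
  neighbour) are preserved.  Like the reference parallel thinning
  algorithms, blunt cut surfaces (ROI faces) recede by roughly one vessel
  radius before a curve endpoint forms; a perfectly lattice-symmetric
  axis-aligned tube is a known degenerate input for this whole algorithm
  family (the standard reference implementation returns an empty skeleton
  for it).
* **Graph cleanup.**  Besides the specified spur removal and interior
  collapse below 10 µm, the convergence loop drops *self-loops* below the
  minimum edge length (tiny handles raised by surface noise), and a
  mask-guided significance pruning removes terminal edges shorter than
  twice the local vessel radius (the distance to background at their
  junction): such prongs lie entirely inside the tube and are artifacts of
  thinning blunt blind ends, not anatomical branches.  At a fork of such
  prongs the longest one is kept as the tube's continuation.  Edge lengths
  are measured on moving-average smoothed polylines (endpoints pinned,
  window 5) because raw 26-connected chains overestimate oblique lengths
  by up to ~8%.
* **Border detection.**  Because of the blunt-end recession, a cropped
  element's skeleton rarely touches the ROI face itself.  With the mask
  available, terminal edges are ray-marched through the foreground from
  their endpoint; if the tube exits through a face, the edge is
  border-touching.  Analytic (ground-truth) graphs use the direct
  path-touches-face test.
* **Orientation.**  Computed from the centerline path voxels, not the
  filled tube: the principal axis of the centerline captures direction
  without radius bias.  Angles are in degrees, range (−180°, 180°], with
  `v_z ≥ 0` sign fixing and zero-by-convention for degenerate components.
* **Inter-valve distances** use each valve's arc-length projection onto its
  assigned edge path; only edges carrying ≥ 2 valves contribute.
* **Channel-2 sampling window** (50 µm along the capillary and link sides
  of the junction) is a package choice — the source describes no window —
  and is configurable.

## The synthetic phantom: what it emulates and what it does not

`phantom_params()` describes the *stated world*: a 540 µm cube (300³ voxels
at 1.8 µm) containing

* a 3×3 grid precollector plexus (radius 20 µm) at 170 µm depth, lines
  placed off-lattice (91/271/451 µm) because real vessels never align with
  the voxel grid and exact lattice symmetry is the thinning degeneracy
  described above;
* 12 blind-ended capillaries (radius 22 µm, lengths 95–140 µm, mean
  115 µm), one per interior plexus span, ascending toward the epidermis
  with a common mean direction (35° from vertical, azimuth 45°) and
  von Mises–Fisher scatter of ≈ 15° — capillary bodies center near 140 µm
  depth, tips near 60–110 µm;
* two collector tubes (radius 24 µm) at 240 µm connected to the plexus by
  vertical links, so the whole network is one connected component (as the
  artifact filter assumes);
* valves as brighter ellipsoids (semi-axes 9×7×7 µm ≈ 1847 µm³, gain +80
  over the vessel level 100): one at each capillary base (15 µm from the
  junction), two along each capillary body, one per plexus span and
  collector valves every 180 µm — 52 valves, ~330/mm³, with ~69% of them
  within or at the base of capillaries;
* hair-follicle-like distractor spheres (radius 17 µm ≈ 2.1×10^4^ µm³ —
  deliberately above the valve volume gate) placed ≥ 60 µm away from any
  vessel;
* a linear depth background ramp (10 + 0.03·z) and additive Gaussian noise
  (σ = 12; vessel contrast-to-noise ≈ 6), optional Poisson noise.

Radii, intensity levels and the valve gain are assumptions, not published
facts; they are chosen so that dermal lymphatics are wider than the 18 µm
structuring element (which the detection stage requires) and the SNR
matches a reasonable cleared light-sheet acquisition.  The phantom does
**not** model the optical PSF, clearing artifacts, photobleaching,
membrane-only (hollow) reporter signal, vessel caliber variation along a
segment, or curved centerlines.  A green phantom test therefore
establishes that the pipeline recovers the geometry and statistics of
*ideal tubes under noise*, not that it handles every optical artifact of
real data.

The generator returns exhaustive ground truth — a noise-free label volume,
the true graph (classified with the same functions as the measured one),
the true valve table, and analytic metrics computed from the parametric
description (capsule volumes with documented first-order overlap
corrections; never from the raster) — so every downstream stage has an
independent oracle.

## What the tests establish

Module tests pin every operation to hand-computable cases and brute-force
oracles (flood-fill hysteresis, direct grayscale morphology, component
labeling, topology counts on tube/Y/H/torus phantoms).  The acceptance
suite additionally shows, on five seeded default phantoms, valve detection
F1 = 1.0 at a 10 µm matching radius, exact per-layer valve counts, and
valve density, median inter-valve distance and capillary length-density
share within 10% (typically 1–4%) of the analytic ground truth, plus
byte-identical artifacts across fixed-seed reruns.  The source study's
biological numbers (≈210 vs ≈100 valves/mm³ across skin sites, ≈30%
capillary density share, > 60% of valves within/at the base of
capillaries) derive from raw volumes that are not publicly deposited and
are therefore not reproduced; the phantom world mirrors their *structure*
(decreasing valve density with depth, capillary-dominated valve placement)
rather than their exact values.

## Known limitations

* Blind-end recession shortens measured capillaries by a few voxels; the
  significance pruning recovers the classification but not the missing
  tip length (≈ 3–5% per capillary).
* The valve detector's measured component volumes depend on the threshold
  geometry and can differ from the true blob volume by tens of percent in
  extreme-contrast, zero-background constructions (the gate is defined on
  measured volumes, as in the source pipeline); on the default noisy
  phantoms they land within ~10% of truth.
* Very coarse spacing (voxel > vessel radius) degrades everything; the
  renderer warns.
* `intensity_by_valve_position` samples the centerline, not the full lumen.
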