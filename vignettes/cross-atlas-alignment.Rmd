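---
title: "Cross-atlas alignment of rat brain reference spaces: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-atlas alignment of rat brain reference spaces}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratlas)
```

## The problem

Decades of rat neuroanatomy are mapped into incompatible reference spaces.
The two dominant atlas families — Paxinos–Watson (*PW*) and Swanson (*S*) —
section different brains at different intervals, number their plates
differently, and draw different regional boundaries. A dataset mapped onto a
*PW* plate in 1999 cannot be compared with one mapped onto an *S* plate
without an explicit correspondence between the two spaces.

`ratlas` implements a three-part toolkit for that correspondence:

1. **Craniometric alignment.** Every atlas plate carries an anteroposterior
   (AP) coordinate `z`: its distance in mm from Bregma, the skull landmark at
   the intersection of the coronal and sagittal sutures. Plates from
   different atlases can be aligned on `z` alone, without looking at the
   tissue.
2. **Feature-based plate matching.** A computer-vision check on the tissue
   itself: scale/rotation-invariant keypoints are extracted from Nissl-style
   plate images, matched by descriptor distance, filtered by a geometric
   consensus (RANSAC homography), and the surviving *inlier count* is used as
   a similarity metric to rank candidate plates against a query region of
   interest (ROI).
3. **Point-source data migration.** Experimental observations reduced to
   single coordinates (here, ventral tips of microinjection sites) are
   carried from one space into the other by anisotropic scaling, and the
   manual corrections applied afterwards by a subject-matter expert are
   quantified as vectors.

## The craniometric registry

The bundled registry (`ratlas_registry()`) transcribes the published
cross-atlas table: 387 entries covering four level groups — `PW1`
(1982/86/97 editions, one tissue set), `PW2` (1998; same tissue plus two
added plates, renumbered), `PW3` (2005/07/14; a different animal entirely),
and `S` (all four Swanson editions, one tissue set).

Coordinates are stored as **integer micrometers**. The register classes rest
on exact equality (`z` identical) and an inclusive 50 µm cutoff; both are
unsafe in floating point (0.48 mm is not representable in binary), and exact
integer arithmetic removes the issue at the source. CSV input in decimal mm
is converted by round-half-away-from-zero at the 1 µm place.

### Errata carried as printed

The transcription is deliberately verbatim. The printed table contains
anomalies, and the package surfaces rather than edits them:

* `PW3` level indices 117, 118, 119 and `S` indices 52, 53 each appear twice
  (once near z = −10.1 mm, again near −11.0/−11.4 mm). The second run is
  evidently a misprint for the absent indices `PW3` 125–127 / `S` 56–57.
* The row at z = −11.28 mm has no level index in any column (presumably the
  missing `PW3` 128), so a transcription cannot carry it.

`validate_monotonicity()` flags every repeated index and every place where
`z` fails to decrease with increasing level index; `load_registry()` refuses
duplicate keys by default and can either keep them (for auditing) or keep
the first printed occurrence (the occurrences corroborated by the published
distance tables — the default for the bundled registry). The source text
counts "312 unique atlas levels": `PW2` (78) + `PW3` (161) + `S` (73), with
`PW1` plates identified with their `PW2` counterparts (same tissue). On the
verbatim transcription `n_unique_levels()` returns 311 — the plate whose
index vanished from the −11.28 mm row is the difference.

## Register classification

Two plates with Bregma coordinates `z_a`, `z_b` are

* **fully in register** when `z_a == z_b`,
* **narrowly in register** when `0 < |z_a − z_b| <= 50` µm (boundary
  inclusive), and
* **not in register** otherwise.

The 50 µm default is on the order of the tip diameters of the probes and
cannulas whose placements these atlases are used to plan, so two plates this
close are operationally interchangeable targets; the threshold is a
configurable parameter (`alignment_config()`) because other use cases may
legitimately differ.

`cross_align()` gives every source level its minimal-|dz| destination level;
equidistant destinations are *both* reported (ascending level index), since
the craniometric rule alone cannot break such a tie and discarding one would
hide a valid pairing. `fully_in_register()` and `narrowly_table()` enumerate
the exhaustive pair sets behind the published tables.

Reproduction status of those tables, as asserted by the test suite:

* PW1↔S and PW2↔S: exactly 8 fully-in-register pairs each, matching the
  published rows.
* PW3↔S: 7 pairs. The published table prints an eighth row, "+0.00 11 11",
  inconsistent with the registry itself (`PW3` 11 sits at +3.00 mm, `S` 11
  at +1.70 mm); it is treated as an erratum and excluded.
* The PW3↔S narrow table (54 rows, minimum separation 10 µm) reproduces
  set-exactly. The PW1/PW2↔S narrow table reproduces all 26 printed rows
  with their printed separations, but exhaustive enumeration finds two
  further genuine pairs: (PW1 19 @ −0.30, S 19 @ −0.26, 40 µm) and
  (PW1 55 @ −9.30, S 49 @ −9.25, 50 µm). The first was plausibly suppressed
  because S 19 is already fully in register with PW1 18; the second appears
  simply omitted. Both are reported — the package enumerates what the data
  support.

The dot-plot export (`dotplot_data()`, `dotplot_svg()`) is the standard
Cleveland layout for one-dimensional data: one track per atlas group on a
dummy axis, every level a dot at its `z`, color-coded black/open/red for
fully/narrowly/not in register against the comparison space.

## The plate matcher

### Keypoints and descriptors

`detect_features()` implements the classic scale-invariant feature
transform: extrema of the difference of Gaussians across a scale-space
pyramid, subpixel refinement, rejection of low-contrast (< 0.04, measured at
the refined extremum) and edge-like responses (principal-curvature ratio
> 10), a dominant gradient orientation from a smoothed 36-bin histogram
(secondary peaks above 80% of the maximum yield additional keypoints), and a
4 × 4 × 8 gradient-orientation histogram descriptor — 128 nonnegative
numbers measured relative to the dominant orientation, giving rotation
invariance. Pyramid parameters follow Lowe's published defaults (base blur
σ = 1.6, three layers per octave, octaves down to a 32 px short side); the
original description leaves them unspecified, and the tests assert the
contract (determinism, 128-d, bounds, crop consistency, rotation
matchability) rather than internals. The detector is implemented in C++ for
speed and is fully deterministic.

### Matching

For each query descriptor `u`, the two nearest target descriptors `v`, `w`
by Euclidean distance are found by exhaustive search; `(u, v)` is accepted
when `|u−v| < abs_threshold` and `|u−v|/|u−w| < 0.8`. The absolute threshold
exists in the method description but is never given a value, so it defaults
to disabled (the ratio test is the operative filter — standard practice) and
can be enabled explicitly. Nearest-neighbor ties break to the smaller target
index so results are order-independent.

### Geometric consensus

`ransac_homography()` runs exactly 2000 random minimal samples of four
correspondences (degenerate samples — a repeated point or three points
collinear within 1e−9 — are redrawn without consuming an iteration), fits
each by the Hartley-normalized direct linear transform, counts
correspondences with reprojection error **strictly below 10 px**, and keeps
the earliest best hypothesis. No final least-squares refit is applied by
default, matching the plain "retain the largest consensus" rule; `refit =
TRUE` offers one that is kept only when it does not lose inliers. The
sampler is a private seeded generator (`std::mt19937`), so results are
bit-reproducible for a given seed and input order regardless of R's RNG
state. With 70% inliers, 2000 draws miss an all-inlier sample with
probability below 1e−300, which is why the planted-recovery tests can
demand 20/20 exact recoveries.

`rank_plates()` wires the three stages per candidate and sorts by inlier
count, then raw match count, then input order; each candidate's RANSAC run
derives its seed as `seed + position − 1` so the ranking is reproducible
while runs stay independent.

## Synthetic imagery

Atlas photomicrographs are copyrighted, so the matcher is exercised on
generated textures (`make_image()`, `make_stack()`, `perturb_roi()`) that
reproduce the *statistics the algorithms assume*, not the biology:

* **Blob texture.** A few hundred Gaussian blobs (σ between 2 and 15 px,
  signed amplitudes) stand in for somata, nuclei, and fiber bundles —
  contrast at the scales the DoG detector samples. The default 512 × 512
  spec yields several hundred keypoints (the suite asserts at least 100).
* **Band-limited noise** (white noise low-passed at σ = 2 px) supplies the
  fine granularity of a stained section.
* **Stack morphing.** Between adjacent levels a fraction `morph_step`
  (default 0.15) of blobs is re-sampled, survivors drift under a smooth
  affine-in-position field (8 px per unit step), and the noise evolves as an
  AR(1) process with correlation `1 − morph_step`. Structural similarity
  therefore decays monotonically with level distance, the property the
  ±1-level clustering experiment relies on; `morph_step = 0` degenerates to
  identical plates.
* **Query perturbation.** `perturb_roi()` crops a rectangle, rotates it (155°
  by default, the published test condition), and applies a scattered
  control-point warp: Gaussian radial-basis displacements, rescaled so the
  realized field never exceeds `max_displacement_px`. "Slight" is not
  quantified in the source; the 5 px default is our stand-in, chosen to stay
  within the descriptor's partial invariance to geometric distortion while
  being clearly visible to the consensus stage. The exact forward transform
  and a fixed-point numerical inverse are returned for oracle checks
  (round-trip accurate to 1e−9 on coordinates).

What passing these tests shows: the pipeline recovers a source plate from a
rotated, warped crop, and ranks near-neighbors of the true level highly,
under texture with realistic feature counts and smooth level-to-level decay.
What it does not show: performance on real Nissl material, whose laminar
structure, staining variability, and section artifacts are not modeled. The
published experiment on real plates produced match counts in the thousands;
the synthetic analogues assert the qualitative contract (correct plate
first, an order-of-magnitude inlier margin for the true source) rather than
those literal counts.

Test problem sizes, chosen once for the suite: a pinned 40-level 512 × 512
stack, 224 × 224 ROIs, ten seeds per experiment analogue.

## Point-source migration

`migrate_dataset()` carries positions between frames by anisotropic scaling
about the workspace origin: the *S* plate grid maps onto *PW* coordinates
under 139% horizontal and 161% vertical magnification (`scale_spec()`
defaults). The alternative normalize-both workflow (apply those factors,
then rescale both axes of *PW* by 139.5%) is provided as a mode; the two
differ by a documented fraction of a percent that depends on grid geometry
the package does not possess, so no numeric assertion ties them together.

Expert-guided relocation is an **input**, never a computation — the package
quantifies the expert, it does not imitate one. For each point the
uncorrected position `A` and corrected position `B` (mm, within a 2 × 2 mm
Cartesian workspace on the destination plate) produce

* per-axis error magnitudes `ABx = |Bx − Ax|`, `ABy = |Ay − By|`,
* magnitude `AB = sqrt(ABx² + ABy²)`, and
* direction `φ = atan2(ABy, ABx)` in degrees (0° = mediolateral,
  90° = dorsoventral; `A = B` gives 0 by convention).

Two notes on this convention, established by recomputing the published
24-site dataset:

* The published error columns are **per-axis magnitudes**, not signed
  differences — nine printed rows have `Bx − Ax < 0` with a positive printed
  `ABx`. The narrative's "subtracting the uncorrected from the relocated
  coordinate" matches the printed numbers only up to sign. The package
  reports the magnitude columns as printed and additionally keeps signed
  components `dx = Bx − Ax`, `dy = By − Ay`, which is what parameter-recovery
  analyses (planted-shift datasets) use.
* Three printed `A`-coordinate cells are typographic errors, identifiable
  because the printed per-row error columns *and* the printed column means
  are internally consistent against them: case 99/147 row *n* (`Ay` printed
  +0.48416, actual −0.48416), case 99/138 row *d* (`Ay` printed 0.09252,
  actual 0.09352), and case 99/135 row *q* (`Ay` printed −0.56996, actual
  −0.48648). The bundled fixture carries the consistent values; with them
  every one of the 24 rows reproduces to ±1e−6 mm and ±0.001°, and every
  printed column mean to the printed precision — including the headline
  values: mean correction magnitude 0.460175 mm, mean direction 78.351°,
  mean mediolateral error 76 µm, mean dorsoventral error 442 µm (the
  corrections are dominated by the dorsoventral axis).

`summarize_migration()` reports column means and standard errors with
SEM = sample SD (n−1 denominator) / √n. The published SEM row is its sample
SD divided by √26 although n = 24 — every column matches that mapping to
printed precision, a spreadsheet range artifact in the source. The package
computes the standard definition; the acceptance test reproduces the printed
row through the identified √(24/26) factor rather than adopting it.

Labels may repeat across migration pairs (the same animal contributes sites
on two plates), so the bundled fixtures carry a `pair` column and the join
key is (pair, case label, tag); files without the column join on
(case label, tag). The 2 × 2 mm workspace bound is validated warn-only,
since future datasets may use larger quadrants.

## Numerical and design choices, collected

* z parsing: round half away from zero to integer µm; equality tests exact.
* Register boundary: |dz| equal to the threshold is *narrowly* in register.
* RANSAC: strict `<` at 10 px; ties keep the earlier hypothesis; exactly
  2000 accepted samples; no default refit; mt19937 seeded per run.
* DLT degeneracy: collinearity tolerance 1e−9 on the triangle cross product;
  degenerate samples redrawn, not counted.
* Matching ties: smaller target index; a zero-distance nearest neighbor is
  always accepted.
* Resampling: bilinear, constant 0 outside; warp inversion by fixed-point
  iteration (40 steps, far beyond convergence for ≤5 px fields).
* Image quantization: generated images are rounded to 8-bit levels so
  PNG round-trips are exact.
* Generators: pure functions of their spec; the caller's RNG state is saved
  and restored.

## Known limitations

* The craniometric alignment is one-dimensional by design: it says nothing
  about mediolateral/dorsoventral correspondence or plane-of-section tilt.
* Affine (3-point) consensus, PROSAC-style variants, and non-rigid
  consensus models are out of scope; heavily distorted sections will
  depress inlier counts before they produce wrong rankings.
* The registry reconciles nothing: printed errata stay as printed, flagged.
* Synthetic fixtures bound what the matching tests can claim about real
  histology (see above).
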