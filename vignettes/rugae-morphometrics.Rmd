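---
title: "Landmark morphometrics of palatal rugae across imaging modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark morphometrics of palatal rugae across imaging modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rugometry)
```

## The scientific problem

Palatal rugae — the transverse mucosal ridges behind the upper incisors —
are individually distinctive and stable, and are used in forensic
odontology as an ancillary identifier. Clinically they can be recorded
three ways: a photograph of the palate, a plaster cast poured from an
alginate impression, or an intraoral optical scan. Whether the digital
record is as faithful as the analogue one is an agreement question:
for each subject, how strongly do geometric descriptors extracted from
one record correlate with the same descriptors from another, and do the
two impression routes differ?

`rugometry` implements that analysis: a reproducible landmark protocol, a
similarity superimposition step, six descriptor families, correlation and
determination matching with interpretive bands, cohort summary statistics
with a rank-based method comparison, and a synthetic data generator that
stands in for clinical images (which cannot be redistributed) while
preserving the statistical structure the analysis must handle.

## The landmark protocol

Five reference lines run parallel to the mid-sagittal direction: one
through the interincisal point and one through the collar centre of each
upper incisor (FDI 1.1, 1.2, 2.1, 2.2). Their crossings with the first two
rugae give six landmarks in a fixed order. Two protocol details are left
open by common practice and are fixed here deliberately:

* **Multiple crossings.** A wavy ruga can cross a reference line twice.
  The anterior-most crossing (smallest distance along the sagittal
  direction from the interincisal point) is chosen, because rugae are read
  from the incisive papilla backwards.
* **Line direction.** The lines are taken parallel to the mid-sagittal
  direction stored in the incisor frame, and they are infinite lines, not
  segments.

Superimposition of two records of the same palate is a closed-form
least-squares similarity fit (rotation, isotropic scale, translation;
reflections excluded as anatomically meaningless). This replaces the
manual image-overlay step of an operator-driven workflow with a
deterministic optimum: `align_similarity()` returns the transform and the
residual, and its result is confirmed in the tests against an independent
zooming grid-search oracle.

## Descriptor families and their numerics

From one six-point configuration the package computes:

1. **Absolute distances** — all 15 pairwise distances (unit-bearing).
2. **Relative distances** — the same divided by the maximum distance.
   The normaliser is a deliberate choice (the convention is not fixed in
   the rugoscopy literature): it makes the family scale-free, so
   photograph/cast/scan magnification differences cancel. A consequence
   worth knowing: because Pearson correlation is invariant to scaling a
   whole vector, the *within-pair* correlation of relative distances
   equals that of absolute distances exactly; the family differs only in
   its scaling behaviour and in cohort-level use.
3. **Perimeter, area, shape factor** of the canonical landmark polygon.
   Landmarks are ordered counter-clockwise by angle about their centroid
   before any polygon computation, guaranteeing a simple boundary whatever
   the digitising sequence; the area is computed by fan triangulation from
   the centroid (each triangle by the absolute homogeneous determinant)
   and agrees with the shoelace formula to 1e-12 relative in the tests.
   The shape factor `area / perimeter^2` is dimensionless, bounded by
   `1/(4*pi)`, and similarity-invariant. Any area below
   `1e-12 * (bounding-box diagonal)^2` is treated as exactly zero, so
   degenerate (collinear) configurations behave identically at any
   coordinate magnitude.
4. **Hu invariant moments** of the filled landmark polygon. Region
   moments are integrated exactly with Green's-theorem closed forms (no
   rasterisation), so translation/rotation/scale invariance holds to
   floating-point accuracy. The moment family choice is itself a design
   decision: commercial morphometric software reports "moments" without
   specifying the family, and Hu's seven invariants are the standard
   similarity-invariant choice consistent with the observed robustness of
   the moment family in cross-modality comparisons.

### Encoding the Hu moments

Raw Hu invariants span ten or more orders of magnitude, so they are
compressed with a signed decadic log. The naive encoding
`sign(h) * log10(|h|)` is discontinuous at `h = 0`: the fifth-to-seventh
invariants of near-symmetric landmark polygons are frequently of order
1e-8 to 1e-10, and sub-millimetre digitising noise can flip their sign,
swinging the naive encoding by ~15 decades and destroying the correlation
of an otherwise perfectly matching pair. `rugometry` therefore uses the
floor-referenced form

    v = sign(h) * max(0, log10(|h| / h_floor)),   h_floor = 1e-9,

a continuous odd function of `h`: an invariant within numerical noise of
zero maps to ~0, so its (meaningless) sign cannot dominate anything, while
large invariants keep both magnitude and sign. The floor is set at the
observed noise scale of the small third-order invariants for landmark
polygons a few tens of millimetres across digitised at ~0.05 mm precision.
Within-pair *matching* additionally correlates the moment family on the
magnitudes `|v|`: within one imaging protocol no record is a reflection of
another, so the signs are protocol-constant where stable and pure noise
where near zero. The signed values remain in the descriptor set, and a
true reflection still flips the sign of the seventh invariant — a property
the test suite checks explicitly.

## Matching and interpretive bands

Each family yields a Pearson `r` and `R2 = r^2` per image pair. The three
polygon scalars cannot produce a correlation alone; they are handled two
ways, reflecting the only two readings under which per-family scalar
coefficients are computable:

* within a pair, pooled into one 3-vector per image (standardised per
  component across the cohort when cohort statistics are available) —
  reported as the auxiliary "polygon scalars (pooled)" family;
* at cohort level, each scalar correlated across subjects between two
  modalities — this is what the per-family "Perimeters", "Areas" and
  "Shape factors" coefficients in the agreement table mean.

Band boundaries (0.3/0.7 for `r`; 0.2/0.4/0.6/0.8 for `R2`) are assigned
to the lower band: the conventional inequalities are strict on both sides
and leave the boundary values undefined, so a deterministic tie rule is
documented instead of an arbitrary one.

## Cohort statistics

`summarize_cohort()` uses the sample SD (n−1 denominator) and type-7
(linear-interpolation) quantiles — the table conventions are not otherwise
fixed. The method comparison is a two-sided Wilcoxon–Mann–Whitney test on
the pooled per-subject coefficients of photo-vs-plaster against
photo-vs-scan; small samples (both groups < 8) use exhaustive enumeration
of rank assignments (average ranks under ties), larger ones the
tie-corrected normal approximation with continuity correction. The two
branches agree within 0.02 absolute at n = 8 per group, and both are
cross-checked against `stats::wilcox.test` where it is applicable.

The paired-design sample-size calculator implements
`n = ceil((z_{alpha/2} + z_beta)^2 * sigma^2 / delta^2)` with exact normal
quantiles by default. With the standard inputs alpha = 0.05, power = 0.90,
sigma = 0.1 mm, delta = 0.05 mm it yields 43 subjects (42 with the
two-decimal z values 1.96/1.28 offered via `rounded_z = TRUE`). Published
rugoscopy studies sometimes quote substantially smaller numbers for these
same inputs; the formula does not support them, and the package follows
the formula.

## The synthetic palate generator

`generate_palate()` builds, per subject, an incisor frame and a set of
rugae modelled as damped sinusoidal perturbations of transverse lines:

* a palate-level wave (amplitude ~1.6 mm, frequency ~0.10 cycles/mm)
  shared by all rugae with small per-ruga modulation — rugae of one palate
  run roughly parallel, and this is also what keeps the *area* enclosed
  between the first two rugae from acquiring spurious between-subject
  variance;
* an asymmetric component scaled by `asymmetry` in [0, 1], combining an
  individual phase-shifted wave and a consistent-handedness transverse
  tilt; at `asymmetry = 0` every ruga is an even function of the
  transverse coordinate, so left/right landmark pairs mirror exactly (a
  generator property the tests exploit);
* a quadratic posterior bowing of the rugae field.

`generate_cohort()` draws per-subject anatomy from `cohort_population()`.
One structural choice matters for the statistics: an **arch-form
elongation factor** (SD 0.12) multiplies the antero-posterior dimensions
and divides the transverse ones — the classic broad-shallow versus
narrow-deep (brachy- vs dolicho-uranic) contrast. Elongation moves
perimeter and shape factor strongly while approximately conserving the
enclosed landmark area. That is what reproduces the characteristic family
ordering of cross-modality rugae agreement: moments and absolute distances
near-perfect, perimeters very strong, areas clearly the worst family.

`apply_modality()` distorts a palate per record type. All three records
carry iid Gaussian digitising noise (SD 0.05 mm) and a small random
projective warp; the warp models camera perspective for the photograph and
the dome-flattening of projecting a 3D palate into a 2D image for the cast
photograph and the rendered scan — without a low-order projection
distortion on every record, the area family could not come out as the
least reproducible one while perimeters stay near 0.99, because the three
scalars are algebraically linked (`area = shape_factor * perimeter^2`).
The plaster model additionally shrinks isotropically by 2% (alginate/
plaster setting), and both impression-derived records are lightly smoothed
(1.2 mm moving average along each ruga). Plaster and scan share identical
noise, warp and smoothing magnitudes: the generator's default study
condition *is* the hypothesis that the two impression methods are equally
faithful, so the method-comparison test operates under a true null and its
p-value is uniform — any single seed carries the nominal 5% risk of a
false positive, which is a property of the test, not of the
implementation. All magnitudes are synthetic configuration values chosen
at the millimetre scales above; they are not fitted to any measured
images.

### What the generator does and does not emulate

It reproduces: per-subject modality triplets sharing one underlying
pattern; realistic millimetre geometry; modality-specific distortion
classes (noise, shrinkage, smoothing, projection); and the qualitative
agreement structure across descriptor families. It does not emulate:
rugae branching or interruption patterns (wavy/curved/straight
taxonomies), operator variability in tracing the ruga crest, true 3D dome
geometry (the projection warp is a 2D surrogate), or texture. Passing
tests on synthetic cohorts therefore validate the pipeline's statistical
machinery and geometry, not the clinical acquisition process itself.

## Problem sizes and numerical choices

The shipped tests run the full study at 19 subjects (the clinical cohort
scale, a few seconds) and the scaled qualitative-reproduction study at 200
subjects with the default models, chosen as a size at which family
orderings and the rank test stabilise while the whole suite stays fast.
Degenerate inputs are handled by classed conditions
(`rugometry_invalid_input`, `rugometry_degenerate_geometry`,
`rugometry_no_intersection`, `rugometry_constant_vector`,
`rugometry_missing_data`, `rugometry_degenerate_test`), and every
stochastic operation is a pure function of its seed, with the caller's RNG
stream restored afterwards.

## Known limitations

* **Identity discrimination by moments is real but bounded.** Within-
  subject moment correlations exceed between-subject ones (the suite
  checks stochastic dominance and a positive standardised margin), but a
  7-component log-encoded family cannot separate genuine from impostor
  pairs by several pooled standard deviations: between-subject
  correlations are dominated by the decade profile that all palate
  polygons share, and the achievable standardised margin grows only like
  the square root of the number of effectively independent discriminative
  components (about 3 here). Rugoscopic identification in practice rests
  on the joint behaviour of all families, not on moments alone.
* The per-patient scalar coefficients printed by commercial comparison
  software are not reproducible from six landmarks alone (a single scalar
  has no within-pair correlation); the across-cohort reading implemented
  here is the one under which such coefficients are computable.
* Correlations near 1 compress all families into a narrow band; the
  agreement table's SD and IQR columns carry most of the discriminating
  information there.

```{r demo, eval = FALSE}
# the complete study, end to end
cohort <- generate_cohort(19, master_seed = 1)
report <- cohort_report(cohort)
report                      # agreement table + method comparison
family_mean_r(report$comparison)
```
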