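# rugometry

Quantitative rugoscopy for forensic odontology: landmark-based comparison
of palatal rugae patterns recorded by clinical photograph, alginate
impression/plaster cast, and intraoral scan.

Palatal rugae are the transverse mucosal ridges of the anterior hard
palate. Their pattern is individually distinctive, stable through life and
well protected inside the mouth, which makes them an ancillary identifier
in forensic dentistry — particularly for edentulous, burned or decomposed
remains where dental restorations are uninformative. A practical question
for both clinic and casework is whether a *digital* impression (intraoral
scanner) captures the rugae as faithfully as the classic alginate-and-
plaster workflow. `rugometry` implements the full analysis pipeline for
that comparison and, because clinical images cannot be redistributed, a
seeded synthetic palate generator so the whole study runs offline with
known ground truth.

## The method

**Landmark protocol.** For each palatal image, five parallel reference
lines are drawn along the mid-sagittal direction: one through the
interincisal point and one through the central point of the collar of each
upper incisor (FDI 1.1, 1.2, 2.1, 2.2). Six landmarks are taken where
these lines cross the first two palatal rugae, in a fixed sequence
(2.1×R1, 2.2×R1, 1.1×R1, 1.2×R1, 1.1×R2, 2.2×R2). Configurations from
different records of one subject are superimposed by closed-form
least-squares similarity alignment (scale *s*, rotation *R*, translation
*t*, no reflection), replacing the manual overlay of image-editing
software:

    min_{s,R,t}  Σᵢ ‖ s R xᵢ + t − yᵢ ‖²

**Descriptors.** Six families are computed from each six-point
configuration: the 15 absolute inter-landmark distances `d_ij`; the
relative distances `d_ij / max d_ij` (scale-free); the perimeter *P* and
area *A* of the canonical landmark polygon; its compactness shape factor
`A / P²` (dimensionless, ≤ 1/4π); and the seven Hu invariant moments of
the filled polygon, integrated exactly by Green's theorem and encoded as
floor-referenced signed decadic logs.

**Matching and cohort statistics.** Each pair of records is scored per
family by the Pearson correlation *r* and the determination coefficient
`R² = r²`, classified into the conventional interpretive bands
(*r*: weak < 0.3 ≤ moderate ≤ 0.7 < strong; *R²*: none/weak/moderate/
strong/very strong/perfect in 0.2-steps). Cohort-level reporting gives the
familiar agreement table (mean ± SD, range, median, IQR per family and
modality pair) and a two-sided Wilcoxon–Mann–Whitney test of whether the
photo-vs-plaster and photo-vs-scan coefficient distributions differ —
i.e., whether the two impression methods are equivalent. A paired-design
sample-size calculator (`ceil((z_{α/2}+z_β)² σ²/δ²)`) completes the study
design toolkit.

## Worked example

```r
library(rugometry)

# one synthetic palate: frame + rugae curves + ground-truth landmarks
pal <- generate_palate(palate_spec(seed = 42))
lm  <- extract_landmarks(pal$frame, pal$rugae[[1]], pal$rugae[[2]],
                         "photo", "demo")
lm
#> Rugae landmark set: subject demo, modality photo
#>        x       y
#> lm1 -4.3  7.9563
#> lm2 -7.9 10.4908
#> lm3  4.3  8.9426
#> lm4  7.9 10.6828
#> lm5  4.3 13.5331
#> lm6 -7.9 15.0160

d <- compute_descriptors(lm)
sprintf("perimeter %.2f mm, area %.2f mm^2, shape factor %.5f",
        d$perimeter, d$area, d$shape_factor)
#> "perimeter 38.46 mm, area 76.54 mm^2, shape factor 0.05174"

# a 19-subject cohort, three records each, full agreement study
cohort <- generate_cohort(19, master_seed = 1)
rep <- cohort_report(cohort)
subset(family_mean_r(rep$comparison), pair == "scan_plaster")
#>              family         pair    mean_r
#>  absolute_distances scan_plaster 0.9989942
#>                area scan_plaster 0.9678707
#>             moments scan_plaster 0.9992288
#>           perimeter scan_plaster 0.9950800
#>  relative_distances scan_plaster 0.9989942
#>        shape_factor scan_plaster 0.9725524

rep$wmw$pooled_r
#> Wilcoxon-Mann-Whitney (normal): U = 2955, n = 76/76, p = 0.8064
#> (not significant at 0.05)
```

Read the landmark coordinates in millimetres (x transverse, y running
posteriorly from the interincisal point). The per-family mean correlations
show the characteristic pattern of cross-modality rugae matching: moments
and absolute distances agree almost perfectly, perimeters very strongly,
while areas — the most distortion-sensitive scalar — agree worst. The
non-significant Mann–Whitney p-value is the study's central finding: the
plaster cast and the intraoral scan capture the rugae equally well.

A thin command-line wrapper for simulation, single-pair comparison and
cohort reporting is installed under `inst/scripts/rugometry-cli.R`:

```sh
Rscript inst/scripts/rugometry-cli.R simulate --n 19 --seed 1 --out-dir cohort/
Rscript inst/scripts/rugometry-cli.R cohort-report cohort/landmarks.tsv
```

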