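# vertrot

Measurement of vertebral axial rotation on true-axial CT endplate outlines,
and longitudinal analysis of inter- and intra-vertebral rotation changes
after instrumented scoliosis surgery.

`vertrot` is aimed at spine-imaging researchers who quantify axial vertebral
rotation from CT. After corrective fusion surgery for adolescent idiopathic
scoliosis, the question is whether the construct holds: do individual
vertebrae or discs keep rotating between follow-up scans, and does the fused
segment move *en bloc* against the neighbouring un-instrumented levels? The
package implements the full measurement chain on traced endplate outlines,
plus a synthetic phantom generator with exact ground truth so every stage can
be validated without patient data.

## The method

**Endplate rotation by maximum symmetry.** A vertebral endplate cross-section
on a true-axial slice is nearly mirror-symmetric about its anatomical
anteroposterior axis. For a binary endplate mask *S*, the package scans
candidate axes through the foreground centroid and computes the
mirror-overlap symmetry ratio

    R(theta) = area(S ∩ mirror(S, theta)) / area(S)  in [0, 1],

sampling theta over [0°, 180°) (default grid 0.1°, with sub-grid parabolic
peak refinement). The angle of maximum symmetry is the endplate's axial
rotation phi, measured clockwise (viewed from above) from the
anteroposterior reference line perpendicular to the scanner bed. Profiles
with two or more near-maximal, well-separated peaks (near-elliptical
endplates) are flagged *ambiguous* and are resolved against a prior angle
(e.g. the same endplate at the other timepoint) or declared unmeasurable.

**Rotation calculus.** With phi_u and phi_l the angles of an adjacent
endplate pair (cephalad over caudal), the inter-endplate rotation is
`phi_u − phi_l`, taken as the signed minimal difference on the
180°-periodic circle, clockwise positive viewed from above.
Intra-vertebral rotation uses a vertebra's own two endplates; inter-vertebral
(intra-discal) rotation uses the inferior endplate of the cephalad vertebra
and the superior endplate of the caudal one. Changes between timepoints are
`value_t2 − value_t1`; negative changes above the curve apex and positive
changes below it represent loss of surgical correction.

**Significance gating.** Repeatability is quantified Bland–Altman style from
repeated measurements by the same observer: with Δα = |α_n − α_m| the
absolute difference of repeated change measurements, the 95% limit of
agreement is `1.96 × SD(Δα)`, and only changes strictly exceeding it are
deemed real. An intra-observer SD of 4.2° gates at 8.2°.

**Cohort level.** Per-patient change records are assembled into a
level-by-patient matrix, junction summaries (first un-instrumented vertebra
and disc above and below the construct, and the apex), a count of patients
with at least one measurable change, and an en-bloc verdict: rigid rotation
of the whole construct must load the two junction discs with equal and
opposite changes.

## Worked example

```r
library(vertrot)

# a synthetic patient: fusion T5-T12, apex T8, one real 10-degree
# intra-vertebral change injected at T8 between the two scans
spec  <- spine_study_spec(injected_changes = c("T8" = 10), seed = 1)
study <- generate_spine_study(spec, outlines = FALSE)
study_changes(study, limit = 8.2) |>
  dplyr::filter(change != 0 | significant)
#> # A tibble: 1 × 10
#>   patient level_key kind            instrumented direction_vs_apex value_t1
#>   <chr>   <chr>     <chr>           <lgl>        <chr>                <dbl>
#> 1 P01     T8        intra_vertebral TRUE         at                  0.0737
#>   value_t2 change significant loss_of_correction
#>      <dbl>  <dbl> <lgl>       <lgl>
#> 1     10.1     10 TRUE        NA
```

The injected entity is recovered with `change = 10` and flagged significant;
every other level's change is exactly zero.

Measuring a single traced outline through the imaging path:

```r
o <- generate_endplate_outline(shape_params(), true_angle = 123)
measure_endplate_rotation(o, pixel_spacing = 0.4, angle_step = 0.1)
#> # A tibble: 1 × 6
#>   patient level side  timepoint   phi quality
#>   <chr>   <chr> <chr> <chr>     <dbl> <chr>
#> 1 NA      NA    NA    NA         123. ok
```

and the repeatability gate:

```r
res <- limits_of_agreement(c(0, 4.2 * sqrt(2)) + 1)  # sample SD 4.2
glance(res)
#> # A tibble: 1 × 4
#>   sd_intra loa95 n_pairs method
#>      <dbl> <dbl>   <int> <chr>
#> 1      4.2  8.23       2 absolute
```

`compute_symmetry_profile()` objects have `autoplot()` methods showing the
symmetry-ratio curve with its detected peaks, and cohort matrices plot as
heat grids.

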