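# implantfem

Voxel-based finite-element simulation of peri-implant bone stress for
virtual dental implant therapy.

## The problem

When a dental implant replaces a lost molar, the occlusal force is
transmitted directly into the mandibular bone — there is no periodontal
ligament to cushion it. Whether the surrounding bone stays healthy depends
on how that stress distributes, and the clinician's main design levers are
the implant's diameter and length. `implantfem` is for biomechanics
researchers and implantologists who want a fully scripted, reproducible
version of the classic virtual-implantation experiment: build a
heterogeneous bone FE model from a CT-like volume, virtually extract the
first molar, place a grid of implant designs into the socket, load each
one, and compare the equivalent stress in the peri-implant bone.

## The model

* **Bone properties from CT.** Each element's apparent density comes from
  its voxel's CT number, ρ = ct × 0.945 × 10⁻⁴ (gf/cc), and its Young's
  modulus from the three-branch bone law
  E = 0.001 MPa (ρ = 0); 33 900 ρ^2.20 (0 < ρ ≤ 0.27);
  5507 ρ + 469 (0.27 < ρ < 0.6); 10 200 ρ^2.01 (ρ ≥ 0.6), with ν = 0.4.
  Teeth: E = 4.80 × 10⁴ MPa, ν = 0.23. Titanium implant:
  E = 11.0 × 10⁴ MPa, ν = 0.29.
* **Geometry.** A synthetic mandibular-segment phantom (0.39 mm voxels,
  cortical shell + correlated-noise trabecular interior + molar) or an
  imported DICOM/NIfTI volume, threshold-segmented into bone and teeth.
* **Mechanics.** 4-node constant-strain tetrahedra (5 per voxel, conforming
  checkerboard decomposition), linear static elasticity, inferior border
  fully fixed, a 50 N point load on the buccal cusp at 45° to the tooth
  axis directed buccal→lingual, sparse Cholesky solve, element-wise von
  Mises stress, and the per-design maximum over the bone elements touching
  the implant.

## Worked example

```r
library(implantfem)

# the full default experiment: 12 designs, ~10 min on one CPU
manifest <- run_all(run_config(seed = 1L), quiet = TRUE)
tidy(manifest$summary)
#> # A tibble: 12 × 6
#>    diameter length peak_vm level side    peak_principal
#>       <dbl>  <dbl>   <dbl> <chr> <chr>            <dbl>
#>  1      3.8      9    6.60 neck  lingual         -0.832
#>  2      3.8     11    6.39 neck  lingual         -0.802
#>  3      3.8     13    6.28 neck  lingual         -0.787
#>  4      3.8     16    6.20 neck  lingual         -0.776
#>  5      4.3      9    5.71 neck  lingual         -5.37
#>  6      4.3     11    5.47 neck  lingual         -5.14
#>  7      4.3     13    5.33 neck  lingual         -5.01
#>  8      4.3     16    5.23 neck  lingual         -4.91
#>  9      6        9    3.68 neck  lingual         -2.99
#> 10      6       11    3.35 neck  lingual         -2.72
#> 11      6       13    3.14 neck  lingual         -2.56
#> 12      6       16    2.97 neck  lingual         -2.42

glance(manifest$summary)
#> # A tibble: 1 × 6
#>   n_designs peak_vm_min peak_vm_max monotone_diameter monotone_length all_neck
#>       <int>       <dbl>       <dbl> <lgl>             <lgl>           <lgl>
#> 1        12        2.97        6.60 TRUE              TRUE            TRUE

autoplot(manifest$summary)   # peak stress vs length, one line per diameter
```

Reading the numbers: `peak_vm` is the largest element-wise equivalent
stress (MPa) in the bone ring around the implant under the 50 N oblique
load. It always sits at the implant **neck** on the **lingual** (loaded)
side; it drops steeply with diameter (6.6 → 5.7 → 3.7 MPa at 9 mm length)
and gently with length — increasing diameter stiffens the part of the
"cantilever" that actually carries the bending moment, while extra length
is added inside the bone where little changes. `monotone_*` in `glance()`
confirm both trends across the whole grid.

The stages are also available individually — for example:

```r
vol  <- generate_mandible_volume()                    # synthetic CT
vol  <- segment_roi(vol, 1200, 17500)                 # thresholds
vol  <- fill_enclosed_pores(vol)
vol  <- virtual_extraction(vol, tooth_id = 1)         # molar out
one  <- solve_configuration(vol, implant_spec(4.3, 11))
one$row                                               # summary row
write_volume(vol, "segment.nii.gz")                   # NIfTI export
```

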