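# nmseg

Semi-automatic, atlas-free segmentation and quantification of the
substantia nigra (SN) on neuromelanin-sensitive T1-weighted MRI.

Neuromelanin is a paramagnetic pigment of the dopaminergic neurons that
degenerate in Parkinson's disease (PD); on suitable T1-weighted sequences
the SN appears as two hyperintense blobs in the midbrain, and their
surface and volume are reduced in patients. Quantifying them by hand is
slow and subjective. `nmseg` implements a signature-correlation
delineation that needs no atlas, template registration or spatial priors
— only one or a few operator-placed seed voxels — together with the
standard measurements and group statistics built on top of it. A
synthetic midbrain phantom generator with ground-truth masks makes every
stage testable without patient data.

The package is aimed at neuroimaging methods researchers: it is both a
working tool (R API plus a command-line interface) and a reproducible
test bed for this family of seeded, texture-based segmentation methods.

## Method

1. **Signatures.** For every voxel inside a domain mask (typically the
   midbrain), local statistics of the intensities captured by spherical
   neighborhoods of radius 1–5 mm are computed and stacked into a
   per-voxel feature vector — the voxel's *signature*, a 4th dimension on
   the 3D volume. Each feature is z-normalized over the domain. The
   default signature uses the local mean and median per radius (a
   multi-scale radial intensity profile); standard deviation, MAD,
   skewness and kurtosis are available.
2. **Seeded correlation.** The mean signature of the seed voxels is
   correlated (Pearson, across the feature axis) against every voxel's
   signature, giving a correlation map in [-1, 1].
3. **Threshold, connect, iterate.** The map is thresholded, only the
   connected component(s) containing the seeds are kept (26-connectivity
   by default), and the result is unioned over seed iterations until the
   nucleus is covered. The threshold is an explicit parameter, or is
   chosen automatically by a mask-stability + partial-volume-matching
   rule (see the methods vignette); Otsu's method on the Fisher-z
   correlation histogram is also available.
4. **Quantification.** For each subject: mask volume; maximal axial
   cross-sectional surface; mean signal intensity over the mask (SI_SN)
   and over a 4.9 mm reference sphere placed posterior to the SN
   (SI_background); and the normalizations

   ```
   SI_norm      = SI_SN / SI_background
   Surface_norm = surface / MV x 1000
   Volume_norm  = volume  / MV x 100
   ```

   where MV is the midbrain volume from a supplied mask.
5. **Group statistics.** Welch two-sample t-tests (from raw samples or
   summary statistics), relative group-mean reductions, and ROC analysis
   with pair-counting AUC and a Youden-optimal cutoff.

## Worked example

Generate a synthetic midbrain phantom with a 300 mm^3 nucleus, segment
it from the bundled seed points, and quantify:

```r
library(nmseg)

ph  <- generate_phantom(phantom_spec(sn_volume_mm3 = 300, rng_seed = 42))
seg <- segment(ph$volume, segmentation_config(),
               seed_spec = ph$meta$seeds, domain = ph$midbrain_truth)
seg
#> <nm_mask> 64x64x48 voxels @ 1x1x1 mm, 283 foreground (283.0 mm^3)
dice_coefficient(seg, ph$sn_truth)
#> [1] 0.8987993

quantify_subject(ph$volume, seg,
                 background = list(center_mm = ph$meta$background_center_mm),
                 midbrain_mask = ph$midbrain_truth,
                 subject_id = "phantom42", group = "PD")
#> <quantification: phantom42 (PD)>
#>   surface  42.0 mm^2 (slice 23)   volume  283.0 mm^3
#>   SI_SN 125.67  SI_background 98.68  SI_norm 1.273
#>   MV 6318.0 mm^3  surface/MV*1000 6.65  volume/MV*100 4.48
```

The recovered mask covers the 300 mm^3 ground truth with Dice 0.90 and a
−5.7 % volume error; the SI_norm of 1.273 reproduces the phantom's
nucleus-to-background contrast ratio of 1.27. Group-level analysis works
directly from published summary statistics as well:

```r
welch_t(group_summary(20, 235.1, 45.4), group_summary(12, 382.9, 100.5))
#> t = -4.81, df = 13.7, p = 0.00029
relative_reduction(382.9, 235.1)
#> [1] 38.6   # percent lower mean SN volume in the patient group
```

A command-line interface wrapping the same functions is installed at
`inst/cli/nmseg` with subcommands `phantom`, `cohort`, `segment`,
`quantify` and `stats`; every run writes a JSON provenance record next to
its outputs.

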