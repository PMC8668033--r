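# biokin

Segmental spine kinematics from calibrated sagittal landmark coordinates,
built around the **biokinemetric triangle**: a per-segment triangle whose
baseline is fixed on the lower vertebra's upper endplate (anterior edge →
ascending facet) and whose apex tracks the upper vertebra's posterior edge
at the roof of the neuroforamen.  Because the baseline is fixed, only the
triangle's height — and hence its area *S* — changes during segmental
movement.  The package is aimed at spine researchers and implant planners
who work with functional radiographs (three-pose exams or videofluoroscopic
sweeps) rather than force-based biomechanical models.

From the landmark tables it computes:

* **RoM curves** — *S* per segment against the percentage of the whole
  section's inclination→reclination movement, with shape-preserving
  monotone cubic interpolation for sparse three-pose exams, alongside the
  conventional angle-based ROM;
* **ΔS/S_max signatures** — each segment condensed to one dimensionless
  number, a spine section to a short ordered series; reproducibility of
  the series over repeated sessions is quantified as the **Bayes error**
  of a multi-class Gaussian identification problem (plus a leave-one-out
  1-NN check);
* **worst/best segment detection** against a reference surrogate of
  healthy per-level motion geometry;
* **implant planning** — virtual substitution of the best segment's
  motion into the worst, optimal device height with size-ratio scaling
  and an anti-overcorrection cap, mapping onto manufactured height grids,
  and prediction of adjacent-level motion redistribution after
  implantation (total section range conserved);
* **ΔRoM–outcome correlation** — Pearson correlation of adjacent-level
  range change |Δ(S_max−S_min)| with outcome relief, with a seeded
  permutation test;
* a seeded **synthetic-spine generator** (cervical C2–C7, lumbar L1–S1)
  producing calibrated landmark trajectories with configurable
  degeneration, device effects, session noise and paired outcome scores —
  the package's validation test bed.

## Worked example

```r
library(biokin)

# a synthetic cervical spine, noise-free: C5-C6 severely degenerated
# (2 mm disc-height loss, mobility halved), mild wear elsewhere, C6-C7 spared
cfg <- spine_config("cervical", noise_sd_fraction = 0,
                    degeneration = rbind(
                      data.frame(level = "C5-C6", height_loss_mm = 2,
                                 mobility_scale = 0.5),
                      data.frame(level = c("C2-C3", "C3-C4", "C4-C5"),
                                 height_loss_mm = 0.5, mobility_scale = 0.9)))
ref <- generate_reference_surrogate(spine_config("cervical"))
an  <- analyze_exam(generate_exam(cfg, "S01", "a"), ref)
an
#> Analysis S01/a (cervical): arc 70.0 deg over 101 frames
#>   dS/Smax series: 0.318 0.346 0.374 0.318 0.370
#>   worst segment C5-C6, best segment C6-C7

round(an$heights, 2)
#> C2-C3 C3-C4 C4-C5 C5-C6 C6-C7
#>   5.0   5.5   6.0   5.0   7.0

plan <- recommend_implant(an$curves, an$heights, ref,
                          device_spec("C", "cage", 0, seq(4, 8, by = 0.5)))
plan
#> Implant plan: target C5-C6 (best donor C6-C7)
#>   recommended height 7.00 mm -> device C height 7.00 mm (exact)
#>   predicted dRoM per level [mm^2]:
#>     C2-C3      0.000
#>     C3-C4      0.000
#>     C4-C5      8.678
#>     C5-C6     19.250
#>     C6-C7     10.572
```

The degenerated segment's ΔS/S_max drops from its healthy 0.40 to 0.318
and it is flagged worst; the spared C6-C7 — greatest preserved
intersegmental height (7.0 mm) and healthy curve shape — is the donor.
The recommended height restores the pre-degeneration 7 mm, never
exceeding the reference neutral height (the anti-overcorrection rule),
and maps exactly onto the cage's height grid.  The predicted ΔRoM rows
quantify the cost of fusing C5-C6: its 19.25 mm² of area range is pushed
onto the neighbouring C4-C5 and C6-C7 (total section range conserved),
while non-adjacent levels are untouched; a prosthesis with residual
mobility would push proportionally less.

The same workflows are available from the shell via the `biokin` script
(`inst/exec/biokin`): `simulate`, `analyze`, `compare`, `recommend`,
`reproducibility`; see `biokin` with no arguments for usage.

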