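# regionbehavior

Regional behavioral analysis of human brain regions from coordinate
tables of functional-imaging activation foci.

Large pools of imaging experiments report their activation peaks as
stereotaxic coordinates, each classifiable into one of 51 behavioral
sub-domains across five domains (Action, Cognition, Emotion,
Interoception, Perception). `regionbehavior` converts such a table into
a 4-D voxelwise probability-density image — channel *b* holds
per-voxel focus counts divided by that sub-domain's total focus count
N<sub>b</sub> — and scores any region of interest (ROI) against every
behavior with a binomial effect-size z-statistic:

```
z = (p_o − p_e) / sqrt( (p_o(1 − p_o) + p_e(1 − p_e)) / N_b )
```

where `p_o` is the PDF sum over the ROI (the fraction of that
behavior's foci inside the region) and `p_e` is the ROI-to-brain volume
ratio (the expectation under spatially uniform foci). Sub-domains with
`z ≥ 3.0` and positive effect are flagged; the ranked 51-row table is
the ROI's *behavior profile*.

The package also provides:

- foci-table I/O (CSV/TSV, Talairach or MNI tags) and the 51-sub-domain
  taxonomy;
- a pooled linear MNI→Talairach adjustment (two published variants)
  plus arbitrary 4×4 affines;
- ROI construction: statistical-map thresholding, atlas label
  selection, spheres, 3×3×3 dilation, half-space clipping, and exact
  1-mm/2-mm precision conversion;
- hemispheric lateralization statistics
  `z = (f − 0.5)/sqrt(f(1 − f)/N)` for left/right foci tallies;
- Gaussian-smoothed (FWHM 10 mm) behavior-specific ROIs and a
  self-consistency rank matrix;
- a seeded synthetic-foci generator with ground truth, so the whole
  method is testable without any proprietary coordinate database;
- a CLI front-end (`inst/cli/regionbehavior`) wrapping `rba_main()`.

See the methods vignette (`vignettes/regionbehavior-methods.Rmd`) for
the statistical model, grid conventions, and generator design.

## Worked example

```r
library(regionbehavior)

grid  <- grid_spec(2)                      # 2-mm Talairach-box grid
brain <- generate_brain_mask(grid)         # synthetic ellipsoid brain
fix   <- known_answer_suite(seed = 42)     # canonical synthetic fixtures

# fixture a: sub-domain 14 clustered at (-44, 20, 8), 50 uniform others
pdf     <- assemble_pdf4d(fix$a$foci, grid)
profile <- analyze_roi(pdf, fix$a$roi, brain)
print(profile, n = 3)
#> <behavior_profile> z >= 3: 1 significant sub-domain(s)
#>   subdomain_id    domain               name n_foci foci_in_roi  p_obs    p_exp
#> 1           14 Cognition Language:Semantics   2000        1453 0.7265 0.004568
#> 2            1    Action    Execution:Other   1000          10 0.0100 0.004568
#> 3            4    Action         Inhibition   1000          10 0.0100 0.004568
#>     effect rel_prob      z significant
#> 1 0.721932    1.189 71.615        TRUE
#> 2 0.005432    1.189  1.429       FALSE
#> 3 0.005432    1.189  1.429       FALSE
#> ... 48 more rows

# fixture b: 2000 uniform foci reflected left with probability 0.6
st <- symmetry_table(fix$b$foci)
st[st$n_total > 0, ]
#>                        label n_left n_right n_total left_fraction    z
#> 15 Cognition:Language:Speech   1213     787    2000         0.607 9.75
#>    significant
#> 15        TRUE
```

The same pipeline is scriptable from the shell:

```sh
regionbehavior simulate  --spec sim.yaml --seed 11 --out foci.csv
regionbehavior build-pdf --foci foci.csv --out pdf.nii.gz
regionbehavior make-roi sphere --center -44,20,8 --radius 12 --out roi.nii.gz
regionbehavior analyze   --pdf pdf.nii.gz --roi roi.nii.gz \
                         --brain brain.nii.gz --out profile.csv
```

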