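Package: regionbehavior
Title: Regional Behavioral Decoding of Brain ROIs from Stereotaxic Activation Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds 4-D voxelwise probability-density images from tables of
    stereotaxic activation foci classified into 51 behavioral sub-domains
    (five domains: Action, Cognition, Emotion, Interoception, Perception),
    and scores any spatially normalized brain region of interest against
    each sub-domain with a binomial effect-size z-statistic. Includes ROI
    construction tools (statistical-map thresholding, atlas labels, spheres,
    dilation, half-space clips, 1-mm/2-mm precision conversion), an
    MNI-to-Talairach affine adjustment, left-right lateralization statistics
    for foci tallies, Gaussian-smoothed behavior-specific ROIs with
    self-consistency ranking, and a seeded synthetic-foci generator for
    fully reproducible validation without access to any coordinate database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
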