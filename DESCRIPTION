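Package: cortexscales
Title: Multiscale Cortical Surface Morphometry and Lifespan Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scale-indexed coarse-graining of cortical pial/white surface
    pairs by voxelization and isosurface re-rendering, with scale-specific
    surface area, exposed (hull or closed) area and thickness metrics at
    hemisphere and lobe level; location-scale-shape normative lifespan
    trajectory models with P-spline age smooths and site/sex adjustment;
    and additive-model brain-age prediction from surface area measured at
    multiple spatial scales. Includes generators for synthetic folded
    cortical geometries with analytic ground truth and for cohort tables
    with controlled age, sex and site structure.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    mgcv,
    splines,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
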