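Package: drillprofile
Title: Bone-Density Profiles Along Drilled Vertebral Canals from Paired CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts Hounsfield-unit bone-density profiles along a drilled
    trans-pedicular canal from paired pre- and post-interventional CT volumes
    and correlates them with axial drilling-force recordings. Provides rigid
    pre/post registration, canal-axis estimation by weighted principal
    component analysis of the difference image, sub-voxel endpoint refinement,
    cylindrical-mask density profiling with gray-value conversion and a
    sliding +/- 0.2 mm min/max/mean filter, insertion-point alignment of force
    and intensity series, and Spearman/Pearson correlation with strength
    classification and grouped tabulation. Includes a synthetic vertebra
    phantom and force-trace generator with recorded ground truth so the whole
    pipeline is verifiable without cadaver data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
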