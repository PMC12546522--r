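Package: aneuhemo
Title: Aneurysm Hemodynamic Metrics, Vortex-Core Analysis and Wall Radiomics
Version: 0.1.0
Authors@R:
    person("Aneuhemo", "Developers", email = "aneuhemo@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for computational-fluid-dynamics studies of
    thrombosed intracranial aneurysms. Computes wall-shear-stress derived wall
    metrics (TAWSS, OSI, ECAP, RRT) from time-resolved surface vector fields,
    identifies vortex-core regions on tetrahedral velocity fields (Q-criterion
    and lambda-2) with vortex volume, core counts and adjacent-phase overlap
    (DVO), derives sac morphometrics (volume, area, height, width, aspect ratio,
    size ratio), extracts first-order and texture radiomic features (GLCM,
    GLRLM, GLSZM, GLDM, NGTDM) from masked image volumes, and screens radiomic
    feature versus hemodynamic parameter pairs with Spearman rank correlation.
    Includes a synthetic-data generator with analytic ground truth so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
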