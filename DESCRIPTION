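Package: oatopo
Title: Microscale Surface Topology and Quantitative Histology for Early
    Osteoarthritis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies early osteoarthritic change in articular cartilage
    from confocal-profilometry height maps and stained histology slides.
    Surface topology metrics (inter-maxima wavelengths of the height
    gradient, OA/healthy deformation ratios, angular-sector spectral
    decomposition and cohesion indices), polarized-light birefringence area
    fractions, chondrocyte cellularity, Mankin-modified score aggregation,
    and nonparametric group comparison (Kruskal-Wallis omnibus, Dunn
    post-hoc with Bonferroni correction). Includes a seeded synthetic-data
    generator that emulates the measurement regime (height maps with
    dominant wavelengths in the 8-28 micrometre band, paired healthy/OA
    surfaces with controlled wavelength stretch and angular-sector
    imbalance, slide images with planted cell counts and colour fractions)
    so the full pipeline is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
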