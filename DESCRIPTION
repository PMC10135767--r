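Package: caflow
Title: Calcium Transient Quantification for Flow-Chamber Cell Adhesion Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify integrin-triggered calcium signaling of cells
    firmly adhering to a ligand-coated substrate in a parallel-plate flow
    chamber. Provides a seeded synthetic time-lapse generator with known
    ground truth, cell detection and nearest-neighbour track linking,
    classification of firm arrest from a displacement-over-time criterion,
    local background estimation from symmetric circular domains, normalized
    fluorescence traces F_IN = (F_IC - F_IB)/F_IB, extraction of per-cell
    transient characteristics (delay time, peak time, peak calcium
    intensity), and the group-comparison layer (Student's t-test, one-way
    ANOVA with Tukey's HSD, boxplot summaries) used to compare experimental
    conditions such as ligand density, wall shear stress and molecular
    perturbations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
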