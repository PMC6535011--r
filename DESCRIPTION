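Package: adaptscape
Title: Climate-Adaptive Genetic Variation in Range Forecasts and Evolutionary Rescue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for incorporating intraspecific climate-adaptive genetic
    variation into climate-change vulnerability assessments. Identifies
    climate-adaptive SNPs by dual genotype-environment association (redundancy
    analysis outliers and a latent-factor association model), classifies
    individuals and populations into hot-dry, cold-wet and intermediate
    adaptation groups in constrained ordination space, fits and projects
    ensemble ecological niche models separately per adaptive group to measure
    range change and niche overlap, and estimates evolutionary-rescue potential
    with circuit-theory landscape connectivity (effective resistance, current
    density, isolation-by-resistance regression). Includes a synthetic-data
    generator (structured genotypes, climate rasters, occurrences,
    isolation-by-resistance distances) so the whole pipeline is testable
    without external downloads, plus Genepop and ESRI ASCII grid input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    methods,
    utils,
    graphics,
    Matrix,
    glmnet,
    vegan,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
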