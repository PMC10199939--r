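Package: pocketlib
Title: Epistasis-Aware Combinatorial Design of Active-Site Protein Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs combinatorial mutation libraries for buried ligand-binding
    pockets by combining phylogenetic conservation filtering, spatial
    neighborhood decomposition of the pocket, energy-based labeling of
    neighborhood designs, and a single-hidden-layer neural-network ranking of
    single mutations whose top-ranked set defines an enriched sequence space of
    mutually compatible mutations. Includes a synthetic additive-plus-pairwise
    energy landscape with planted incompatible mutation pairs for end-to-end
    validation, deep-sequencing enrichment and hit calling for sorted variant
    libraries, genotype-phenotype classifier features, allele-preference
    logistic-regression logos, an origin-fixation evolutionary model with
    diffusion-coordinate visualization of fitness landscapes, and
    exponential-decline fits of function versus mutation number.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    seqinr,
    nnet,
    glmnet,
    xgboost,
    randomForest,
    minpack.lm,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
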