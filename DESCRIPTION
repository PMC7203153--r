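Package: psapep
Title: Peptide Ligand Discovery and Characterisation for Polysialic Acid
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for rational discovery of peptide ligands against
    polysialic acid (PSA) and related glycans: epitope-tiling peptide
    library design from a parent lectin, per-peptide physicochemistry
    (net charge, isoelectric point, residue-class composition),
    microarray screen aggregation with replicate coefficient-of-variation
    filtering, top-binder selection and percent-selectivity analysis
    under glycan competition, residue-enrichment testing with
    two-proportion z-tests, fluorescence-anisotropy titration processing
    with four-parameter logistic binding fits (K_D, B_max, standard
    errors, reliability flags), structure-derived residue contact maps
    from multi-model coordinate sets, and a synthetic-data generator
    emulating each assay for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    bio3d,
    seqinr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
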