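Package: volscale
Title: Whole-Cell Resource-Allocation Model of Gene-Expression Scaling with Cell Volume
Version: 1.0.0
Authors@R:
    person("Riley", "Carter", email = "riley.carter@volscale.dev", role = c("aut", "cre"))
Description: Simulates a coarse-grained whole-cell model of gene expression in
    which genes compete for a limiting pool of RNA polymerases through
    heterogeneous promoter recruitment abilities (Michaelis-Menten constants),
    and mRNAs compete for ribosomes. Provides a seeded synthetic-genome
    generator, the self-consistent free-polymerase allocation solver, a stiff
    ODE driver for the coupled mRNA/protein dynamics with volume bookkeeping,
    closed-form predictions of the nonlinear volume-scaling degrees (beta for
    mRNA, alpha for protein), and nonlinear least-squares estimators of those
    degrees from expression-versus-volume tables. Genes with below-average
    recruitment ability scale superlinearly with cell volume, above-average
    ones sublinearly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
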