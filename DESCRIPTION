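Package: aslcvr
Title: Multi-Delay pCASL Kinetic Modelling and Cerebrovascular Reactivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxelwise kinetic modelling of multi-delay pseudo-continuous
    arterial spin labelling (pCASL) perfusion MRI. Implements four nested
    forward models of the label-control difference signal (the standard
    single-compartment kinetic model, optionally extended with a
    gamma-shaped bolus dispersion kernel and a macrovascular arterial
    component), fitted per voxel by variational Bayes with conjugate
    updates, automatic relevancy determination on arterial blood volume,
    and free-energy output for model comparison. Includes M0 calibration
    to absolute cerebral blood flow, grey-matter and arterial masking,
    cerebrovascular reactivity (CVR) and transit-time change maps between
    normocapnia and hypercapnia, regional summaries, and a digital
    phantom generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
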