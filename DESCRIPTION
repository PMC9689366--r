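Package: nodugrowth
Title: Uncertainty-Aware Prediction of Lung Nodule Growth from Baseline CT Patches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts future lung-nodule growth from a single baseline CT patch with a
    hierarchical probabilistic segmentation network. Two U-ResNet subnets (prior and
    posterior) with four interleaved latent blocks and attention-gated skip connections
    generate stochastic future segmentations conditioned on the time to predict and the
    baseline diameter; Monte-Carlo samples are post-processed into growth size, growth
    probability and uncertainty estimates. Includes a soft intersection-over-union plus
    diameter reconstruction loss, evidence-lower-bound training with Adam, bespoke
    evaluation statistics (generalized energy distance, balanced accuracy at two standard
    deviations, closest-annotator selection), and a synthetic multi-annotator cohort
    generator emulating longitudinal nodule measurements for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
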