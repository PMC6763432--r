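Package: prismr
Title: Multiplexed Synaptic Imaging Analysis and DNA-PAINT Post-Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of probe-based sequential multiplexed
    (PRISM-style) fluorescence imaging of neuronal cultures. Provides a
    synthetic-data generator with known ground truth, flat-field illumination
    correction and round-to-round rigid registration, object-count-maximizing
    punctae segmentation with watershed splitting and nuclear exclusion,
    single-synapse feature tables with correlation networks, treatment
    comparisons, t-SNE embedding and hierarchical clustering, DNA-PAINT
    localization post-processing (fiducial tracking, LOESS drift correction,
    histogram rendering, radial cross-correlation, trans-synaptic profiles),
    and an exhaustive locked-nucleic-acid substitution optimizer for imaging
    probes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    Rtsne,
    Biostrings,
    jsonlite,
    KernSmooth,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
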