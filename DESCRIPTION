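Package: ventseg
Title: Thickness-Agnostic Brain Ventricle Segmentation and Volumetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multimodal (CT/MRI) brain-ventricle segmentation and exact
    voxel-spacing volumetry. Implements a slice-wise encoder-decoder
    segmenter with sub-pixel-convolution upsampling, trained in two
    stages: supervised cross-entropy on labeled thick-slice volumes,
    then joint training with an entropy-minimization loss on unlabeled
    thin-slice volumes to bridge the thick/thin domain gap. Includes
    ventricular volume (VV), intracranial volume (ICV) and VV/ICV
    computation from label maps, agreement statistics (Dice, ICC(2,1),
    Pearson, Bland-Altman) between manual and automatic measurements,
    a synthetic head-phantom generator with analytically known
    compartment volumes for end-to-end testing, NIfTI-1 input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
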