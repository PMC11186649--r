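Package: ucycle
Title: Uncertainty-Aware Unpaired Translation of 3D Medical Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unpaired volume-to-volume translation between two imaging
    modalities (e.g. MR-like and CT-like spine volumes) with voxel-wise
    uncertainty estimation. Implements a cycle-consistent adversarial model
    whose generators output both a translated volume and a voxel-wise
    log-standard-deviation map, trained with an aleatoric (heteroscedastic)
    cycle-consistency loss and a gradient-correlation prior, and queried at
    test time with Monte-Carlo dropout to obtain a predictive mean, an
    epistemic variance map and a mean aleatoric map. Includes a synthetic
    spine-phantom generator with known bone and soft-tissue masks so the
    whole pipeline can be exercised without patient data, NIfTI input and
    output, and a self-contained volumetric neural-network layer with
    backpropagation and Adam optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
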