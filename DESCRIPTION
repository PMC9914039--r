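Package: cbctiq
Title: Task-Based Image Quality Assessment for Cone-Beam CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Task-based image quality assessment for axial CT and cone-beam CT
    image stacks: two-dimensional noise power spectrum estimation with
    second-order polynomial detrending, circular-edge task-based transfer
    function (edge spread function, line spread function, TTF and its 50%
    frequency, insert contrast), and the non-prewhitening-with-eye-filter
    (NPWE) model-observer detectability index for circular lesion tasks.
    Includes a synthetic Catphan-like phantom generator with prescribed
    radially symmetric noise power spectra, Gaussian system blur, cylindrical
    contrast inserts and an optional cupping artefact, so complete
    FBP-versus-iterative-reconstruction comparisons can be run without
    acquisition data, plus reading and writing of DICOM series and a simple
    headered raw-stack format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
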