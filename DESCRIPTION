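Package: dtwb
Title: Dynamic-Threshold Automatic White Balance for Skin Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automatic white balance for skin-colour imaging under varying
    room-light colour temperature, aimed at preprocessing for neonatal
    jaundice screening where colour fidelity drives the downstream reading.
    Implements a dynamic-threshold illuminant estimator that selects
    near-white candidate pixels from YUV chroma statistics with an
    iteratively adjusted weights threshold (Wr) and percentage threshold
    (Wp), and corrects images with diagonal von Kries gains.  Ships three
    classical baselines (white-patch retinex, gray-world/gray-edge, and the
    fixed-threshold dynamic method they descend from), a synthetic
    colour-cast scene generator with ground-truth illuminant gains for six
    correlated colour temperatures, and a CIEDE2000-based evaluation of
    cross-colour-temperature consistency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
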