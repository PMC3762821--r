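Package: ctrestore
Title: CT Image Sequence Restoration via Sparse and Low-Rank Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restores blurred, noisy computed-tomography (CT) image
    sequences by decomposing the stacked sequence into a shared low-rank
    background and per-frame sparse structures, then applying Wiener
    deconvolution separately to each component: a turbulence-type optical
    transfer function for the sparse frames and a Gaussian point spread
    function for the averaged low-rank frame. Three decomposition solvers
    are provided (robust principal component analysis via inexact augmented
    Lagrange multipliers, its linearized alternating-direction variant with
    adaptive penalty, and GoDec with bilateral random projections), together
    with restoration-quality metrics (standard deviation, information
    entropy, image-quality measurement function value), a ground-truthed
    phantom-sequence simulator, and PNG/TIFF sequence input/output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
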