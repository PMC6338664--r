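Package: nbed4d
Title: Scanning Nanobeam Electron Diffraction (4D-STEM) Mosaicity Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for four-dimensional scanning transmission
    electron microscopy (4D-STEM) of beam-sensitive nanocrystals: hybrid
    electron counting of sparse direct-detector frames with partial
    coincidence recovery, strip-wise centre-of-mass correction of
    diffraction shifts, log-ratio crystal-thickness mapping, unsupervised
    classification of diffraction patterns into lattice-orientation domains
    (k-means++ with G-means model selection), and library-based orientation
    indexing of cluster averages by peak-intensity RMSD. Includes a
    kinematic diffraction simulator that generates synthetic scans with
    known ground truth, so every stage of the chain is testable end to end,
    and a real-space counterpart for high-resolution TEM images (tiling,
    elbow-method cluster selection, shift-search clustering, Fourier
    filtering).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
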