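Package: dimergate
Title: Symmetry Breaking and Gate Geometry of Homodimeric Transporter
    Conformational Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural-analysis toolkit for conformational transitions of
    homodimeric ABC transporters such as the vitamin B12 importer BtuCD.
    Provides the spin angle between transmembrane-domain and
    nucleotide-binding-domain dimers via reference least-squares overlap,
    homodimer symmetry-breaking statistics (the asymmetry coefficient
    C_asymm, per-pair A_ij scores and asymmetric residue pair
    classification), pore-radius profiling of the translocation pathway by
    maximal inscribed spheres, gate and d_pair distance metrics, and Kabsch
    rigid-body superposition. A coarse-grained elastic-network toy homodimer
    evolved under a targeted-MD steering potential generates labelled
    synthetic trajectories so every statistic can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
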