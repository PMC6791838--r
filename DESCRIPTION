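Package: nestweave
Title: Digitization of Interlocked-Branch Bird Nests from Tomographic Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end digitization of interlocked-branch bird nests (and similar
    tangles of tubular elements) from 3D grayscale image stacks. Provides the two-track
    preprocessing that yields a skeletonization input and a thickness-measurement input,
    topology-preserving 3D thinning, decomposition of the curve skeleton into simple
    edges by tail pruning and junction elimination, reconnection of fragments belonging
    to the same physical branch via an endpoint friendship score, distance-transform
    thickness estimation, contact-point extraction, per-branch morphometrics, and two
    construction-order simulators ('Greedy' and 'Gradual') over the branch contact
    network. A synthetic phantom generator produces voxelized nests with full ground
    truth so every stage is testable without a CT scan.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
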