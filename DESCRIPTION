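Package: meascreen
Title: Addiction-Liability Screening from Multiwell MEA Network-Burst Activity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for chronic-exposure compound screening on
    multiwell microelectrode-array (MEA) recordings of cultured neuronal
    networks. Reads multiwell spike lists (native CSV plus a tolerant reader
    for vendor exports), detects array-wide network bursts with a four-step
    binned method, computes thirteen burst-structure parameters per well with
    per-well vehicle normalization, searches all parameter subsets of size two
    or more for a set on which only addictive-profile compounds shift
    significantly between the pre- and post-chronic phases on the first two
    principal components, and classifies compounds as producing addiction-like
    responses when the before/after centroid distance in the PC1-PC2 plane
    exceeds twice the standard deviation of the vehicle's distances. A seeded
    synthetic plate simulator with dose-response and chronic-shift compound
    profiles makes every stage testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    mvtnorm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
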