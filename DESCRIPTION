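Package: lfpmatch
Title: Latent Fingerprint Preprocessing, Minutiae Extraction and Core-Anchored Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digital processing and identification of developed latent
    fingerprints. Implements the three-phase preprocessing chain (grayscale
    conversion, mean/variance normalization, Otsu binarization), ridge
    orientation-field estimation with Poincare-index core and delta
    detection, Zhang-Suen skeletonization, crossing-number extraction of
    Galton-Henry feature points (terminations, bifurcations, trifurcations,
    eyes, spurs, short ridges, crossovers and sweat pores), and a
    core-anchored Euclidean-distance similarity score between a developed
    latent print and an inked control. Ships a seeded synthetic fingerprint
    generator (inked-control and fluorescent-powder appearance over several
    substrate archetypes) with exact ground-truth minutiae so the entire
    pipeline is testable without real fingerprint photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
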