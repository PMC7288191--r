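Package: cartafm
Title: AFM Surface Roughness and Nanoindentation Analysis of Articular
    Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for atomic-force-microscopy (AFM) based assessment of
    articular cartilage wear. Computes profile and areal surface-roughness
    parameters (Ra, Rp, mean local-peak spacing S, Sa) from height maps,
    detects elliptical lacunae, assigns osteoarthritic wear stages from
    equal-width Ra subranges, extracts depth-resolved Young's modulus from
    force-indentation curves via the Hertz sphere model, and models
    specimen dehydration as a power-law mass decay. Includes seeded
    generators for correlated rough surfaces, Hertzian force curves and
    drying series with known ground truth, plus an end-to-end study
    pipeline producing summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
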