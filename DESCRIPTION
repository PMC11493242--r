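Package: lumivox
Title: Precomputed Low-Frequency Lighting for Cinematic Volume Rendering
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Physically motivated rendering of 3-D scalar volumes such as CT
    and MR images. A precomputation stage surrounds the volume with circular
    area light sources arranged on its circumscribed sphere, emulating a
    shadowless surgical lamp, and traces photons through the classified
    volume with transmit/reflect splitting (Schlick Fresnel reflectance),
    accumulating deposited energy into a voxel-aligned ambient light field.
    A ray-casting renderer then fuses inverse-distance-interpolated ambient
    light with per-ray transmitted light to produce images. Includes
    analytic synthetic phantoms, NIfTI and raw-volume input/output, and a
    command-line pipeline with provenance-stamped, cacheable artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
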