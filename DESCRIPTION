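Package: unravelr
Title: Tract-Specific Microstructure from Multi-Fixel Diffusion Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns per-fixel microstructural metrics (fractional
    anisotropy, fiber volume fraction) from multi-fixel diffusion MRI
    models to macroscopic tractography streamlines. Streamline segments
    are subdivided at voxel boundaries and distributed across the fixels
    of each traversed voxel by relative volume, closest-fixel-only, or
    angular weighting; contributions aggregate into fixel weight maps,
    total-segment-length maps, tract-specific microstructure maps,
    tract-wide means, and along-streamline profiles. Includes readers
    and writers for NIfTI fixel volumes and TRK/TCK tractograms, a
    command-line interface, and a synthetic crossing-tract phantom
    generator with exact ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
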