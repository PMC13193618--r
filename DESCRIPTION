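Package: reliefstl
Title: Tactile 3D-Printable Relief Models from Agar-Plate and Micrograph Images
Version: 0.1.0
Authors@R:
    person("reliefstl", "maintainers", email = "reliefstl@example.org",
           role = c("aut", "cre"))
Description: Converts photographs of agar plates and micrographs into
    watertight, 3D-printable tactile models. Pixel brightness becomes
    surface height over a solid base (a heightmap), producing a closed
    topographic solid exported as binary or ASCII STL. Includes end-to-end
    generators for circular Petri-dish models (with a raised rim) and
    rectangular microscope-slide models (with a raised frame), optional
    Grade-1 braille labels, a synthetic colony/streak image generator with
    known object counts for teaching cell-counting skills, and a command
    line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jpeg,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
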