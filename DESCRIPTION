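Package: ivdmicro
Title: Nutrient Microenvironment Modelling of the Intervertebral Disc
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Steady-state reaction-diffusion modelling of oxygen, glucose
    and lactate in an idealized caprine lumbar intervertebral disc, with
    cell-density-scaled metabolic sinks, lactate-to-pH mapping and
    iterative Dirichlet boundary calibration against target nucleus
    pulposus microenvironments. Includes a transient glycosaminoglycan
    accumulation model for the nucleus pulposus, a single-bead alginate
    culture well model (spherical diffusion coupled to a well-mixed media
    reservoir with media-change events), extraction of per-cell oxygen
    consumption and lactate production rates from extracellular-flux
    traces, and a synthetic-data generator emulating a 24-condition
    factorial culture experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
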