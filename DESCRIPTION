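Package: femshield
Title: Stress Shielding, Bone Resorption and Implant Safety Analysis for
    Hip Prostheses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-total-hip-arthroplasty biomechanical analysis over paired
    intact/implanted femoral element fields: volume-weighted stress shielding
    increase (SSI) per Gruen zone, strain-adaptive bone resorption with a
    dead-zone remodeling rule, static yield and Soderberg fatigue factors of
    safety for the femoral stem, strain-gauge rosette reduction to principal
    strains and surface von Mises stress, stiffness estimation from
    load-displacement records, and Bland-Altman agreement between measured and
    modeled stresses. A modulus-weighted composite-beam model of the implanted
    femur generates paired element fields and simulated rosette readings so the
    whole pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
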