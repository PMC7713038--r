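Package: stiflesim
Title: Patellofemoral Stability Simulation of the Canine Stifle Under
    Distal Femoral Varus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale biomechanical simulator of medial patellar luxation
    (MPL) in the dog. Generates a parametric canine stifle (femur with a
    ridged trochlear groove, patella, tibia), applies virtual distal femoral
    varus by bending the femur at the centre of rotation of angulation
    (CORA) to any target anatomic lateral distal femoral angle (aLDFA),
    drives the patella with a Hill-type rectus femoris model through
    quadriceps-tendon and patellar-ligament spring elements, advances the
    patella as an unconstrained six-degree-of-freedom rigid body against
    frictional penalty contact with the trochlear surface, and detects
    luxation from the mediolateral contact reaction force and patellar
    displacement. A thirteen-angle sweep locates the critical aLDFA at
    which the patella leaves the groove under a constant quadriceps
    activation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
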