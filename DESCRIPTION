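Package: shuntr
Title: Lumped-Parameter Hemodynamics of Central Systemic-to-Pulmonary Shunts
Version: 0.1.0
Authors@R:
    person("shuntr", "developers", email = "shuntr@example.org", role = c("aut", "cre"))
Description: Steady-state zero-dimensional (lumped-parameter) modelling of the
    central shunt circulation in pulmonary artery stenosis and atresia. Solves
    a two-node resistive flow network with a nonlinear shunt element, converts
    outlet resistances to porous-zone viscous coefficients, computes
    pulmonary-to-systemic flow ratio, left/right pulmonary flow split,
    hemodynamic power loss and relative power loss, and systemic oxygen
    delivery from an oxygen mass balance. Includes calibration of outlet
    resistance boundary conditions against clinical mean arterial pressure, a
    seeded virtual-patient generator, and a driver for the 35-case shunt
    diameter by stenosis-ratio design grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
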