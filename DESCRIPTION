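Package: cicusim
Title: Monte Carlo Simulation of Cardiac ICU Occupancy Under Elective
    Surgery Scheduling Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-day Monte Carlo simulation of bed occupancy in a
    cardiac intensive care unit (CICU) fed by elective cardiac surgery.
    Length of stay is modelled as a lognormal law fitted to historical
    admissions, weekly surgical demand is calibrated through Little's law,
    and patients are assigned to weekday operating-room slots either at
    random (a proxy for current practice) or anticipatorily, placing
    short-stay cases early in the week. Scenarios are compared by annual
    surgical cancellations and by the weekday profile of the daily census,
    and an exhaustive day-pair search finds the best placement of two extra
    daily operating-room slots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    withr
Config/testthat/edition: 3
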