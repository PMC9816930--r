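Package: fortiplan
Title: Linear-Programming Design and Evaluation of Food-Fortification Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plans micronutrient fortification of food groups from individual
    dietary-survey data. Per-stratum median intakes feed a linear program that
    assigns a fortification level to each food group, expressed per 10 MJ of
    the group's energy and bounded by a common safety cap, so that every
    sex/age stratum's modelled intake reaches its recommended intake. Levels
    are converted to amounts per 100 g through population-level group energy
    density, applied to the food-composition table, and the resulting scheme
    is verified by recomputing individual intakes and screening medians
    against recommended intakes and 95th percentiles against tolerable upper
    intake levels. A synthetic dietary-survey generator emulating a national
    7-day-record survey makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
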