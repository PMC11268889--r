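Package: owlstrike
Title: Hunting-Success Inference from Barn Owl Biologger Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from raw biologger signals to hunting-success
    inference in nocturnal raptors. Derives VeDBA, body pitch and raw
    acceleration vector sums from 50 Hz tri-axial accelerometry, applies
    Boolean threshold rules to label take-offs, travelling flight, landings,
    self-feeding and nest-box visits, estimates landing ground-reaction forces
    from peak acceleration and body mass, categorizes hunting strategies
    (sit-and-wait versus on-the-wing), infers strike outcomes from subsequent
    feeding or provisioning behaviour, assigns perch types from a habitat map,
    and estimates group force ratios, success odds ratios and force-versus-
    time-to-hunt trends. Includes a ground-truthed synthetic-night generator
    so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    mgcv,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
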