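Package: acdbench
Title: Bench Evaluation of Reflection-Based Volatile Anaesthetic Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses bench recordings of a target-controlled,
    reflection-based volatile anaesthetic delivery system. Provides a seeded
    breath-by-breath simulator of 10 Hz anaesthetic/CO2 gas traces under
    volume-controlled ventilation with a MAC-fraction target staircase,
    capnographic breath segmentation, end-tidal concentration extraction,
    injection-peak quantification, per-period liquid consumption and
    reflection-efficiency accounting, Bland-Altman agreement statistics, and
    polynomial consumption-concentration regression with report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
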