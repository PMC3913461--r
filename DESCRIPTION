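Package: rore
Title: State-Sequence Representation and Automated Review of Resuscitation Episodes
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents cardiac-arrest resuscitation episodes as contiguous
    labeled-interval state sequences in a therapy domain (compressions,
    hands-off intervals, defibrillations) and a response domain (annotated
    cardiac rhythms), combines the two domains into a single episode
    representation, and reasons over that representation to derive the review
    variables used by EMS cardiac-arrest registries (shock times, compression
    times, post-shock rhythm checkpoints, VF recurrence, ROSC, device
    operation). Includes readers and writers for an open defibrillator
    event-log and annotation dialect, a seeded synthetic-episode generator
    with analytically computed ground truth, and an audit engine that codes a
    derived database against a manually abstracted one as correct, wrong or
    missing with sentinel-aware time comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
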