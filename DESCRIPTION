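Package: pairbond
Title: Event-Aligned Photometry, Patch-Clamp, and Behavioral Analysis for
    Pair-Bonding Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the quantitative analysis of
    pair-bonding neuroscience experiments: fiber-photometry dF/F computation
    with bout-aligned response quantification and refractory exclusion,
    partner-preference behavioral scoring from annotated event logs,
    whole-cell patch-clamp summaries (spontaneous PSC detection, evoked
    excitation-inhibition ratios, F-I curves and rheobase, bath-drug paired
    comparisons), and the statistical procedures used in such studies
    (repeated-measures ANOVA with Greenhouse-Geisser correction, mixed and
    two-way ANOVA, Sidak post-hoc, Kruskal-Wallis with Dunn follow-up).
    Includes a synthetic-data generator with configurable ground truth so
    the whole pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
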