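Package: cogmark
Title: Cognitive Effort and Tension Indices from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes two per-segment markers from a single frontal EEG
    channel recorded during a cognitive test: the Cognitive Effort Index
    (CEI), the standard-deviation-to-mean ratio of delta-band (1-4 Hz)
    epoch powers within 10 s segments, and the Tension Index (TensI), the
    high-beta (23-30 Hz) segment power relative to a causal running
    baseline drawn from segments of effective attentional effort. Includes
    test-level summaries (%CEIm, %TensI-high), a Montreal Cognitive
    Assessment (MoCA) cohort data model with range stratification and
    change-threshold bookkeeping, the stratified group-comparison
    machinery (Mann-Whitney, Welch and paired t, 2x2 chi-square quadrant
    analysis), seeded synthetic EEG and cohort generators, and a
    command-line interface. Reads EDF/EDF+ and two-column CSV recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
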