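Package: midilearn
Title: Objective Measures of Melodic Replication and Improvisation from MIDI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes objective, fully automated scores of musical learning
    from monophonic MIDI performances. Replication fidelity against a
    reference melody is quantified with subsequence dynamic time warping
    (pitch-only and joint pitch/inter-onset-interval variants, with aligned
    proportion and length-adjusted products) and with smoothed
    Kullback-Leibler distributional similarities of pitch and timing.
    Improvisations are scored with eighteen feature measures (note counts,
    interval/pitch/timing diversity and range, repeated and passing notes,
    dynamics, rests, articulation, retrogrades and transposed sequences).
    Includes score rescaling, standardisation and variance-sharing
    combination, posterior-summary utilities (one-sided evidence ratios and
    credibility intervals), a Standard MIDI File reader/writer, and a
    synthetic-performance generator that emulates novice learners so the
    whole measurement pipeline can be exercised end to end without study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
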