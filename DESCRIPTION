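Package: qtcmatch
Title: Qualitative Trajectory Calculus Pattern Matching for Movement Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognises recurring spatial movement patterns in uniformly
    sampled 2-D trajectories of co-moving objects (e.g. tracked team-sport
    players). Fragments of a recording are encoded with the basic
    Qualitative Trajectory Calculus (QTC_B) as sequences of pairwise
    relation matrices, compared with a Levenshtein edit distance whose
    substitution costs derive from conceptual distances between the
    qualitative symbols, and ranked against a user-chosen reference
    fragment over sliding candidate windows. Includes static anchor
    points that break the otherwise translation-, rotation- and
    scale-invariant description, role permutations between objects,
    seeded synthetic scene generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
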