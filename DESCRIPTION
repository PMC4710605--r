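Package: admetriage
Title: Exposure and ADME Triage of High-Throughput Screening Actives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based prioritization of active chemicals from
    high-throughput in vitro screens built on adverse outcome pathways.
    Active chemicals are gated through exposure, oral-absorption
    (Rule-of-5) and blood-brain-barrier distribution rules to separate
    high- from low-priority hits, and inactive chemicals are screened
    for possible in vitro false negatives by MACCS-166 fingerprint
    Tanimoto similarity to the nearest active neighbor. Includes the
    acetylcholinesterase case-study fixtures (30 actives with printed
    exposure/ADME annotations and the worked parent-metabolite pairs),
    a synthetic screening-library generator with planted analogs and
    decoys, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
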