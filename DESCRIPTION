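Package: facscore
Title: Composite Quality-of-Care Scoring for Health Facility Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for scoring routine supportive-supervision assessments of
    primary health care facilities with a weighted checklist of yes/no and
    graded indicators grouped into quality dimensions, and for evaluating the
    appropriateness of such a composite scoring system.  Computes indicator,
    quality-dimension and overall facility scores, ranks facilities, and
    quantifies robustness of scores and ranks to the number of indicators and
    to indicator weighting.  Includes an exploratory factor-analysis
    concordance check of the designed indicator grouping, mixed linear models
    with council-level random intercepts for year, facility-level and owner
    effects, a fully parameterised synthetic-data generator with known ground
    truth for parameter-recovery testing, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    lme4,
    lmerTest,
    lmtest,
    methods,
    pracma,
    sandwich,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
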