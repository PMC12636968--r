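Package: hegap
Title: Gender Gaps in Health Expectancy: Sullivan Estimation and
    Mortality-Health Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating disability-free and chronic-disease-free
    life expectancy at older ages with the Sullivan method, from abridged
    period life tables and survey-weighted age-group prevalence, and for
    splitting the women-minus-men gap in health expectancy into additive
    mortality and health components with a continuous-change (path integral)
    decomposition.  Includes a synthetic survey and life-table generator with
    closed-form truths for validation, a stepwise-replacement decomposition
    oracle, and a small pipeline driver with CSV/YAML interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
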