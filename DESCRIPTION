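Package: pchecker
Title: Consistency Checking of Reported Statistical Results in Article Text
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts APA-formatted null-hypothesis significance test results
    (t, F, chi-squared, r, Z) from plain-text or HTML articles, recomputes the
    p-value implied by each reported test statistic and its degrees of freedom,
    and classifies every result as consistent, inconsistent ("error"), or
    inconsistent across the significance threshold ("gross error"), taking the
    rounding of printed numbers into account. Includes a synthetic-corpus
    generator with planted, unambiguous errors for end-to-end validation, and
    prevalence estimators: intercept-only logistic models at the article level
    and random-intercept (multilevel) logistic models at the p-value level,
    with Bonferroni-corrected group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
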