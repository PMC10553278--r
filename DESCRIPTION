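Package: choiceval
Title: Discrete Choice Experiment Design, Conditional Logit Estimation,
    and Welfare Valuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the full valuation pipeline of a two-alternative
    discrete choice experiment (DCE): enumeration of factorial attribute
    spaces, D-efficient fractional design search by Fedorov exchange with
    random pairing and blocking into questionnaire versions, long-format
    choice-data handling with dominant-responder screening, conditional
    (McFadden) logit estimation by Newton-Raphson maximum likelihood with
    cluster bootstrap confidence intervals, and post-estimation welfare
    economics: willingness-to-accept ratios with Krinsky-Robb confidence
    intervals, relative attribute importance, compensating variation, and
    net-benefit cost-benefit analysis. Includes a random-utility choice
    simulator (linear utilities with i.i.d. type-I extreme-value errors and
    injectable single-attribute dominant responders) so every stage is
    testable without access to individual-level survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Matrix,
    jsonlite,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
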