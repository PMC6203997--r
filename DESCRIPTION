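Package: dyadfit
Title: Dyadic Data Analysis by Covariance-Structure Maximum Likelihood
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the three classical models for distinguishable dyads --
    the Actor-Partner Interdependence Model (APIM), the Mutual Influence
    Model (MIM) and the Common Fate Model (CFM) -- by maximum-likelihood
    covariance-structure estimation on RAM-style path specifications.
    Models can be fitted either to raw wide-format dyad tables or directly
    to published summary moments (sample size, means, standard deviations
    and correlations), so reported analyses can be reproduced without raw
    data.  Includes equality-constraint chi-square difference tests, the
    usual fit indices (CFI, TLI, RMSEA, SRMR), delta-method indirect
    effects for nonrecursive feedback models, scale scoring with
    Cronbach's alpha, a seeded multivariate-normal dyad simulator with
    known APIM/MIM/CFM structure, and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
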