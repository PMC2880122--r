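Package: curecart
Title: Mixture Cure Survival Regression and Cure Survival CART
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of censored time-to-event data containing long-term
    survivors ("cured" subjects), as arises in randomized withdrawal trials
    where many patients never relapse. Fits the semiparametric Cox cure
    regression model -- a logistic model for the cured fraction combined with
    a proportional-hazards model with nonparametric Breslow baseline for the
    latency of uncured subjects -- by a multi-start EM algorithm, with
    AIC-based best-subset covariate search and adjusted population survival
    curves. Grows, prunes and cross-validates "cure survival CART" trees
    that recursively partition patients by the deviance of parametric
    (exponential or Weibull) mixture cure models, using cost-complexity
    pruning and replicated V-fold cross-validation with the 1-SE rule.
    Also provides the Maller-Zhou q_n test of sufficient follow-up with
    simulation-based critical values, and a synthetic randomized-withdrawal
    trial data generator with known cure status for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
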