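Package: maxdiffseg
Title: Best-Worst Scaling (MaxDiff) Estimation and Latent-Class Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for best-worst scaling (MaxDiff) choice experiments:
    balanced incomplete block design generation and auditing, exploded-logit
    utility estimation (aggregate, latent-class multinomial logit by EM, and
    hierarchical Bayes by Gibbs sampling), sum-to-100 rescaled preference
    scores, model-selection metrics (percentage certainty, AIC, CAIC, BIC,
    ABIC, relative chi-square), segment profiling (chi-square tests, one-way
    MANOVA with pairwise comparisons), segment-membership prediction by
    multinomial logistic regression, and a synthetic respondent generator
    with latent-class structure and class-correlated covariates for
    end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
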