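Package: yawnscope
Title: Quantitative Ethology of Yawning from Behavioral Event Tables
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative analyses of yawning behavior in
    group-living primates, from raw behavioral event tables (yawn events with
    FACS action-unit codings, aggression bouts, posture streams, visibility
    records) to results: discovery of yawn morphs by multiple correspondence
    analysis and k-means clustering of action-unit configurations, Average
    Dominance Index computation from decided-conflict matrices, social-context
    and daytime annotation, behavioral state-change time-slot construction,
    yawn-contagion response attribution within a fixed perception window,
    mixed-effects model inference with likelihood-ratio tests and
    Tukey-adjusted pairwise contrasts, and inter-observer reliability metrics
    (Cohen's kappa and the FACS set-agreement index). A synthetic-ethogram
    generator with exported ground truth supports end-to-end validation and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mvtnorm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
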