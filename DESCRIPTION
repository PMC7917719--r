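Package: itvpart
Title: Partitioning Inter- and Intraspecific Trait Variability in Plant
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based analysis of plant communities sampled
    along an environmental gradient divided into ordered belts. Computes
    community-weighted means (CWM) and nonweighted community means (CM)
    from either gradient-pooled ("fixed") or belt-level ("specific")
    species trait values, partitions the between-belt variation of the
    specific community mean into species-turnover, intraspecific and
    covariation components via a one-way sum-of-squares decomposition,
    and tests belt differences with one-way ANOVA followed by
    Tukey-Kramer HSD pairwise comparisons with compact-letter displays.
    Includes a synthetic community generator that emulates a stratified
    elevational sampling design with controllable turnover strength,
    intraspecific trends, covariation sign and measurement noise, so the
    full pipeline can be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
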