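Package: pathseg
Title: Path Segmentation and Habitat-Use Analysis for Sympatric Foragers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-scale movement-path analysis of focal animal
    observations sampled at regular one-minute intervals: per-observation
    path segmentation metrics (step length, path length, net displacement,
    straightness index, turn angles, proportion of intervals with movement,
    and a line-of-sight visibility index), circular statistics on turn
    angles (mean resultant length, Rayleigh uniformity test, von Mises
    fitting with a Watson U-squared goodness-of-fit check), non-parametric
    group comparisons (Mann-Whitney U, two-sample Kolmogorov-Smirnov,
    R x C chi-square, two-proportion z, Pearson correlation), mixed-effects
    and trend regressions for step length, and a seeded correlated-random-walk
    simulator over a vegetation-patch mosaic with geometric line-of-sight,
    so the full analysis pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    optparse
Config/testthat/edition: 3
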