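Package: pollinet
Title: Temporal Plant-Pollinator Networks and Pollination-Service Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building weekly, annual, and multi-year (metaweb)
    bipartite plant-pollinator networks from dated flower-visitation and
    pollen-load records, computing their structural properties (size,
    binary and weighted connectance, NODF nestedness, Barber bipartite
    modularity), testing observed structure against metaweb-resampling
    null models with empirical-quantile verdicts, and converting visit
    counts plus single-visit pollen-deposition trials into estimates of
    the pollination service delivered to a focal plant. Includes a seeded
    generator of phenology-structured synthetic communities so that every
    stage of the analysis can be exercised and calibrated without field
    data, and a pipeline driver that runs the full analysis reproducibly
    from a single configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
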