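Package: forestdiv
Title: Community Assembly and Diversity Analysis for Forest Stand Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stem-level tree inventories from replicated
    forest plots: species importance values and family/genus overall relative
    importance, Hill-number diversity (q = 0, 1, 2) with size- and
    coverage-based rarefaction and extrapolation curves and bootstrap
    confidence intervals, fitting and AIC/Kolmogorov-Smirnov comparison of six
    classical species-abundance-distribution models (broken-stick, niche
    preemption, log-normal, Zipf, Zipf-Mandelbrot, and the neutral-theory
    sampling formula), and assemblage structure via group-average clustering
    and correspondence analysis.  Includes a synthetic two-belt stand
    generator with known ground truth so every pipeline stage is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    vegan
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
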