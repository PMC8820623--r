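Package: agridiet
Title: Farm Production Diversity, Market Access and Women's Dietary Diversity
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how farm production diversity relates to
    women's dietary diversity in smallholder survey settings. Implements five
    production-diversity indices (product count, Simpson index on monetary
    shares, food-group count, group Simpson index, and a dendrogram-based
    nutritional functional diversity score), seasonal and annual women's
    dietary diversity scoring on the ten MDD-W food groups, Shannon-entropy
    market-diversity indicators with crow-flies market access, and
    limited-information maximum likelihood (LIML) instrumental-variable
    estimation with weak-instrument diagnostics (Cragg-Donald F, Anderson LM,
    Sargan/Hansen J, Stock-Yogo reference values). A calibrated synthetic
    survey generator with known ground truth and built-in endogeneity supports
    end-to-end testing and Monte Carlo study of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    digest,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
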