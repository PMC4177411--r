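Package: cutaneotyper
Title: Community Analysis of Triplet-Matched Cutaneous Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical analysis of triplet-matched (lesion,
    unaffected, control) 16S rRNA skin microbiome surveys: OTU-table input and
    depth filtering, rarefaction-based alpha diversity and taxa sharing,
    unweighted and weighted UniFrac and square-root Jensen-Shannon beta
    diversity, Cailliez-corrected principal coordinates analysis,
    distance-based permutational MANOVA with sequential sums of squares and
    stratified permutations, community typing ("cutaneotypes") by partitioning
    around medoids with Calinski-Harabasz and gap-statistic model selection,
    and a marker-discovery battery (Kruskal-Wallis with FDR control,
    prevalence chi-square tests, incidence-based double-positive predictors
    with exact odds ratios, ROC/AUC, severity correlations, chimera QC).
    Includes a Dirichlet-multinomial cohort simulator with a ground-truth
    ledger so every stage is testable without restricted-access study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    biomformat,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    cluster,
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
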