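Package: micropair
Title: Paired-Design Comparison of Host Microbiota Across Body Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing microbial communities sampled from two
    body sites of the same host individuals, as in paired oral/faecal 16S
    rRNA surveys of wild birds. Provides OTU-table handling (contaminant
    and prevalence filtering, rarefaction), alpha diversity with
    mixed-model likelihood-ratio contrasts, four community dissimilarities
    (Bray-Curtis, binary Jaccard, unweighted and weighted UniFrac),
    principal coordinate analysis, PERMANOVA with individual-identity
    permutation strata, multivariate dispersion and Mantel tests,
    within-individual paired correlations, a permutation-based
    differential-abundance scan using Box-Cox-transformed counts in
    random-intercept linear mixed models with a sequencing-depth offset
    and Storey q-value FDR control, and a Dirichlet-multinomial simulator
    of paired two-region datasets with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    vegan,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    picante,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
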