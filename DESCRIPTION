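Package: otunet
Title: Co-Occurrence Networks, Co-Abundance Groups and Diversity Analysis
    for Microbiome OTU Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compositional analysis of 16S rRNA OTU count tables:
    SparCC correlation inference with resampling pseudo-p-values, signed
    co-occurrence networks with stability/complexity statistics and MCODE
    module detection, co-abundance group (CAG) construction by Ward
    clustering on correlation distance with permutational validation,
    alpha/beta diversity (Chao1, Shannon, Faith's PD, unweighted UniFrac,
    Bray-Curtis), PCoA, multi-factor PERMANOVA effect sizes, LEfSe-style
    linear discriminant effect-size screening, an optional PCIT edge filter,
    and a Dirichlet-multinomial synthetic-data generator with planted
    correlation blocks, stage-periodic taxa and group effects for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    MASS,
    picante,
    stats,
    utils,
    vegan,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
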