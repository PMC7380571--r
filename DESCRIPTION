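Package: mucodiv
Title: Diversity Accounting for Fish Mucosal Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for diversity accounting in marine fish
    mucosal microbiome surveys. Provides titration-based limit-of-detection
    quality gating and seeded rarefaction of sOTU feature tables; alpha
    diversity (richness, Shannon entropy, Faith's phylogenetic diversity)
    and phylogenetic beta diversity (unweighted and weighted UniFrac);
    gamma-richness accumulation and saturation sample sizes;
    host-versus-seawater richness ratios and uniqueness partitions;
    prevalence-based core-microbiome calling; assumption-gated linear
    models and permutational multivariate analysis (PERMANOVA) of
    environmental and biometric drivers; von Bertalanffy age inference and
    Fulton's condition factor; and a synthetic-study generator with
    recorded ground truth so every statistic is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lmtest,
    picante,
    phyloseq,
    car,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
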