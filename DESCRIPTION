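Package: aridgen
Title: Landscape Genomics Along an Aridity Gradient
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genomic analysis of organisms sampled
    along a climatic aridity gradient. Computes the annual Aridity Index
    from monthly climate series (Romanenko potential evapotranspiration
    and Magnus-form relative humidity), collapses mitochondrial alignments
    into haplotypes with minimum spanning networks, nucleotide diversity
    and Tajima's D, performs hierarchical (nested) analysis of molecular
    variance with permutation tests, a per-population SNP diversity panel
    (heterozygosities, rarefied allelic richness, private alleles,
    Hardy-Weinberg and multilocus linkage-disequilibrium tests, Fis),
    Nei Fst with permutation significance, isolation-by-distance versus
    isolation-by-environment regression including the residual procedure,
    and multi-method clustering (PCA, k-means/discriminant clustering with
    BIC, maximum-likelihood admixture with Evanno delta-K, spatial PCA with
    Moran's I Monte-Carlo tests). A synthetic-data generator with known
    ground truth (hierarchical Balding-Nichols genotypes, haplotype trees,
    sinusoidal climate series) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    geosphere,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
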