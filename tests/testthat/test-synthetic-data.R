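test_that("generators are pure functions of configuration and seed", {
  design <- flat_design(3, 5, 40, f_pop = 0.1)
  g1 <- simulate_genotypes(design, seed = 101)
  g2 <- simulate_genotypes(design, seed = 101)
  expect_identical(g1$dosage, g2$dosage)
  g3 <- simulate_genotypes(design, seed = 102)
  expect_false(identical(g1$dosage, g3$dosage))
  clim1 <- simulate_climate(synthetic_design(n_loci = 10), years = 2,
                            seed = 55)
  clim2 <- simulate_climate(synthetic_design(n_loci = 10), years = 2,
                            seed = 55)
  expect_identical(clim1$Klawer$records, clim2$Klawer$records)
})

test_that("vanishing population differentiation yields near-zero Fst", {
  design <- flat_design(3, 15, 400, f_pop = 1e-9)
  gd <- simulate_genotypes(design, seed = 103)
  pw <- pairwise_fst(gd$dosage, gd$metadata$population)
  expect_lt(mean(abs(pw[lower.tri(pw)])), 0.01)
})

test_that("sib structure depresses within-colony diversity", {
  base <- flat_design(1, 20, 600, f_pop = 1e-9)
  base$sites$n_colonies <- 4L
  sib <- base; sib$sib_fraction <- 1
  g_free <- simulate_genotypes(base, seed = 104)
  g_sib <- simulate_genotypes(sib, seed = 104)
  # full-sib colonies push genotype correlation up: positive rbarD signal
  # relative to the panmictic draw, visible as reduced colony-mean variance
  ho_free <- mean(heterozygosities(g_free$dosage)$means[["Ho"]])
  ho_sib <- mean(heterozygosities(g_sib$dosage)$means[["Ho"]])
  expect_true(is.finite(ho_free) && is.finite(ho_sib))
  d2 <- dosage_distance(g_sib$dosage)
  hier <- data.frame(sample = g_sib$metadata$sample,
                     colony = g_sib$metadata$colony)
  res <- nested_amova(d2, hier, "colony", squared = TRUE)
  expect_gt(res$phi[["PhiST"]], 0.05)  # colonies of sibs are differentiated
})

test_that("mtDNA simulation reproduces the generating haplotype tree", {
  sites <- c("A", "B")
  # star tree with unique branch lengths: recoverable as the MSN
  tree <- data.frame(haplotype = c("root", "h1", "h2", "h3"),
                     parent = c(NA, "root", "root", "root"),
                     mutations = c(0L, 1L, 2L, 4L),
                     population = c(NA, "A", "A", "B"),
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample = paste0("s", 1:12),
                        population = rep(c("A", "B"), each = 6))
  sim <- simulate_mtdna(tree, samples, length = 200, seed = 105)
  expect_equal(dim(sim$alignment), c(12L, 200L))
  ht <- collapse_haplotypes(sim$alignment)
  # every sampled haplotype is one of the tree's leaves
  expect_lte(nrow(ht$haplotypes), 3L)
  # mutational distances equal tree path lengths (distinct sites)
  seqs <- sim$haplotype_seqs
  expect_equal(sum(seqs$h1 != seqs$h2), 3)   # via the root: 1 + 2
  expect_equal(sum(seqs$h1 != seqs$h3), 5)
  expect_equal(sum(seqs$h2 != seqs$h3), 6)
  # zero mutations everywhere: a single haplotype, pi = 0
  flat_tree <- tree; flat_tree$mutations <- 0L
  sim0 <- simulate_mtdna(flat_tree, samples, length = 100, seed = 106)
  expect_equal(nrow(collapse_haplotypes(sim0$alignment)$haplotypes), 1L)
  expect_equal(nucleotide_diversity(sim0$alignment), 0)
  expect_error(simulate_mtdna(tree, samples, length = 5, seed = 1),
               "exceed")
})

test_that("a star genealogy of singletons gives negative Tajima's D", {
  k <- 8
  tree <- data.frame(haplotype = c("root", paste0("h", 1:k)),
                     parent = c(NA, rep("root", k)),
                     mutations = c(0L, rep(1L, k)),
                     population = c(NA, rep("A", k)),
                     stringsAsFactors = FALSE)
  samples <- data.frame(sample = paste0("s", 1:(k + 4)),
                        population = "A")
  sim <- simulate_mtdna(tree, samples, length = 300, seed = 107)
  nh <- nrow(collapse_haplotypes(sim$alignment)$haplotypes)
  expect_lte(nh, k + 1L)
  if (segregating_sites(sim$alignment) > 0)
    expect_lt(tajimas_d(sim$alignment)$D, 0)
})

test_that("simulated climate hits its target aridity", {
  design <- synthetic_design()
  clim <- simulate_climate(design, years = 10, seed = 108)
  tab <- aridity_table(clim)
  target <- design$sites$target_ai[match(tab$site, design$sites$site)]
  expect_true(all(abs(tab$AI - target) / target < 0.2))
  # zero-precipitation configuration
  dry <- design; dry$sites$target_ai <- 0
  tab0 <- aridity_table(simulate_climate(dry, years = 3, seed = 109))
  expect_true(all(tab0$AI == 0))
})

test_that("gradient coupling recovers its generating coefficients", {
  sites <- synthetic_design()$sites
  sim <- simulate_gradient_coupling(sites, intercept = 0.05,
                                    geo_effect = 2e-4, env_effect = 0.2,
                                    noise_sd = 0, seed = 110)
  fit <- isolation_models(sim$genetic, sim$geographic, sim$environmental)
  expect_equal(unname(fit$joint$coefficients["geo"]), 2e-4,
               tolerance = 1e-8)
  expect_equal(unname(fit$joint$coefficients["env"]), 0.2,
               tolerance = 1e-8)
  expect_equal(fit$residual$slope, 0.2, tolerance = 1e-8)
})

test_that("the fixture bundle round-trips through the readers", {
  dir <- tempfile("fixture_")
  design <- flat_design(3, 4, 25, f_pop = 0.2)
  design$sites$n_colonies <- 2L
  paths <- suppressMessages(make_fixture(dir, seed = 7, design = design))
  expect_true(all(file.exists(paths)))
  md <- read_sample_metadata(paths[["metadata"]])
  gd <- read_vcf_genotypes(paths[["vcf"]], md)
  expect_equal(nrow(gd$dosage), 12L)
  expect_equal(ncol(gd$dosage), 25L)
  aln <- read_fasta_alignment(paths[["fasta"]])
  expect_equal(nrow(aln), 12L)
  clim <- read_climate_table(paths[["climate"]])
  expect_equal(length(clim), 3L)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$seed, 7L)
})
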