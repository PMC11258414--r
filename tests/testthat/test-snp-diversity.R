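test_that("the unbiased-He correction is exact at every locus", {
  dose <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 1, 0), c(0, 1, 1))
  h <- heterozygosities(dose)
  N <- h$per_locus$N
  expect_equal(h$per_locus$uHe / h$per_locus$He, 2 * N / (2 * N - 1))
  # direct hand case: one locus, p = 0.5, 2 hets out of 4
  one <- matrix(c(0, 1, 1, 2), 4, 1)
  h1 <- heterozygosities(one)
  expect_equal(h1$per_locus$Ho, 0.5)
  expect_equal(h1$per_locus$He, 0.5)
  expect_equal(h1$per_locus$uHe, 0.5 * 8 / 7)
  # monomorphic locus contributes zeros
  h0 <- heterozygosities(matrix(0, 4, 1))
  expect_equal(unname(h0$means), c(0, 0, 0))
})

test_that("HWE chi-square matches hand-computed expectations", {
  perfect <- hwe_chisq(c(25, 50, 25))
  expect_equal(perfect$chisq, 0)
  expect_equal(perfect$p, 1)
  # total heterozygote deficit: statistic equals the sample size
  deficit <- hwe_chisq(c(50, 0, 50))
  expect_equal(deficit$chisq, 100)
  mono <- hwe_chisq(c(10, 0, 0))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$p))
})

test_that("the re-pairing distribution equals exhaustive enumeration", {
  # n = 5 genotypes, m = 4 alt alleles among 10 slots: enumerate all
  # C(10, 4) allele placements and tally heterozygote counts
  n <- 5; m <- 4
  placements <- combn(10, m)
  het_of <- apply(placements, 2, function(slots) {
    ind <- ceiling(slots / 2)
    sum(table(factor(ind, 1:n)) == 1)
  })
  emp <- table(factor(het_of, 0:4)) / ncol(placements)
  dist <- aridgen:::het_count_distribution(n, m)
  expect_equal(dist$h, c(0, 2, 4))
  expect_equal(dist$prob, as.numeric(emp[as.character(dist$h)]),
               tolerance = 1e-12)
})

test_that("the HWE Monte-Carlo test is seeded and directionally sound", {
  res <- hwe_mc(c(25, 50, 25), n_perm = 199, seed = 2)
  expect_gt(res$p, 0.5)                      # perfect HWE not rejected
  res2 <- hwe_mc(c(50, 0, 50), n_perm = 199, seed = 2)
  expect_equal(res2$p, 1 / 200)              # maximal deficit: minimum p
  expect_identical(hwe_mc(c(50, 0, 50), n_perm = 199, seed = 2)$p, res2$p)
  expect_true(hwe_mc(c(8, 0, 0), n_perm = 99, seed = 1)$monomorphic)
})

test_that("index of association matches a direct variance computation", {
  # 4 individuals x 3 loci toy; oracle from explicit pair loops
  m <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1), c(0, 2, 2))
  res <- index_of_association(m, n_perm = 0, seed = 1)
  pairs <- combn(4, 2)
  dl <- apply(pairs, 2, function(ij) abs(m[ij[1], ] - m[ij[2], ]))
  D <- colSums(dl)
  v0 <- function(x) mean(x^2) - mean(x)^2
  VO <- v0(D); VE <- sum(apply(dl, 1, v0))
  expect_equal(res$Ia, VO / VE - 1, tolerance = 1e-12)
  # duplicated locus: perfect association
  dup <- cbind(m[, 1], m[, 1])
  expect_equal(index_of_association(dup, n_perm = 0, seed = 1)$rbarD, 1)
  expect_error(index_of_association(m[, 1, drop = FALSE], n_perm = 0,
                                    seed = 1), "2 polymorphic")
})

test_that("independently shuffled loci show no association", {
  set.seed(9)
  m <- matrix(rbinom(30 * 40, 2, 0.4), 30, 40)
  res <- index_of_association(m, n_perm = 99, seed = 3)
  expect_lt(abs(res$rbarD), 0.05)
  expect_gt(res$p, 0.05)
})

test_that("rarefied allelic richness equals exhaustive subsampling", {
  # counts (9, 1) at g = 2: enumerate all C(10, 2) subsamples
  pool <- c(rep(0, 9), 1)
  subs <- combn(10, 2)
  distinct <- apply(subs, 2, function(ii) length(unique(pool[ii])))
  # build one population carrying 9 ref / 1 alt copies: 5 diploids
  dose <- matrix(c(0, 0, 0, 0, 1), 5, 1)
  ar <- rarefied_allelic_richness(dose, rep("a", 5), g = 2)
  expect_equal(unname(ar$mean), mean(distinct), tolerance = 1e-12)
  expect_equal(unname(ar$mean), 1.2, tolerance = 1e-12)
  # fixed locus: Ar = 1 at any g
  fixed <- matrix(2, 4, 1)
  expect_equal(unname(rarefied_allelic_richness(fixed, rep("a", 4),
                                                g = 3)$mean), 1)
  # g equal to the full copy count returns the observed allele count
  expect_equal(unname(rarefied_allelic_richness(dose, rep("a", 5),
                                                g = 10)$mean), 2)
  # Ar non-decreasing in g
  ar_g <- vapply(1:10, function(g)
    unname(rarefied_allelic_richness(dose, rep("a", 5), g = g)$mean), 1)
  expect_true(all(diff(ar_g) >= -1e-12))
  expect_equal(ar_g[1], 1)
  expect_error(rarefied_allelic_richness(dose, rep("a", 5), g = 11),
               "exceeds")
  # larger random case vs enumeration (N = 12 copies, g = 5)
  set.seed(10)
  dose2 <- matrix(rbinom(6 * 4, 2, 0.35), 6, 4)
  ar2 <- rarefied_allelic_richness(dose2, rep("a", 6), g = 5)
  oracle <- vapply(seq_len(4), function(l) {
    pool <- rep(c(0, 1), c(12 - sum(dose2[, l]), sum(dose2[, l])))
    subs <- combn(12, 5)
    mean(apply(subs, 2, function(ii) length(unique(pool[ii]))))
  }, 1)
  expect_equal(unname(ar2$mean), mean(oracle), tolerance = 1e-10)
})

test_that("private alleles match a brute-force scan", {
  set.seed(11)
  pops <- rep(c("a", "b", "c", "d"), each = 4)
  dose <- matrix(rbinom(16 * 10, 2, runif(10, 0.05, 0.6)), 16, 10,
                 byrow = TRUE)
  got <- private_alleles(dose, pops)
  oracle <- setNames(integer(4), c("a", "b", "c", "d"))
  for (l in 1:10) for (allele in 0:1) {
    present <- vapply(c("a", "b", "c", "d"), function(pp) {
      g <- dose[pops == pp, l]
      if (allele == 1) any(g > 0, na.rm = TRUE) else any(g < 2, na.rm = TRUE)
    }, logical(1))
    if (sum(present) == 1) oracle[present] <- oracle[present] + 1L
  }
  expect_equal(got, oracle)
  # an allele present everywhere contributes nowhere
  everywhere <- matrix(1, 8, 1)
  expect_equal(unname(private_alleles(everywhere, rep(c("a", "b"), 4))),
               c(0L, 0L))
})

test_that("Fis follows 1 - mean(Ho)/mean(uHe)", {
  # all heterozygotes: Ho > uHe, strongly negative
  allhet <- matrix(1, 6, 5)
  expect_lt(inbreeding_coefficient(allhet), 0)
  # no heterozygotes anywhere with variation: Fis = 1
  nohet <- rbind(matrix(0, 3, 4), matrix(2, 3, 4))
  expect_equal(inbreeding_coefficient(nohet), 1)
  # direct evaluation on a toy table
  set.seed(12)
  m <- matrix(rbinom(8 * 6, 2, 0.4), 8, 6)
  h <- heterozygosities(m)$means
  expect_equal(inbreeding_coefficient(m), 1 - h[["Ho"]] / h[["uHe"]])
  expect_error(inbreeding_coefficient(matrix(0, 4, 3)), "undefined")
})

test_that("the diversity panel is deterministic and honours subsetting", {
  design <- flat_design(3, 8, 80, f_pop = 0.15)
  gd <- simulate_genotypes(design, seed = 13)
  gd$metadata$colony <- paste0(gd$metadata$population,
                               rep(c("_c1", "_c2"), length.out = 24))
  p1 <- suppressMessages(diversity_panel(gd, n_perm = 49, seed = 5))
  p2 <- suppressMessages(diversity_panel(gd, n_perm = 49, seed = 5))
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_setequal(p1$population, c("P1", "P2", "P3"))
  expect_true(all(c("Ho", "He", "uHe", "Ar", "private_alleles", "Fis",
                    "rbarD") %in% names(p1)))
  expect_true(all(p1$uHe >= p1$He))
  sub <- suppressMessages(diversity_panel(gd, n_perm = 49, seed = 5,
                                          one_per_colony = TRUE))
  expect_equal(unique(sub$n), 2L)   # one sample per colony, two colonies
})
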