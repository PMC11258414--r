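test_that("Nei Fst matches hand-computed gene diversities", {
  # two populations fixed for alternative alleles
  fixed <- rbind(matrix(0, 5, 3), matrix(2, 5, 3))
  pop <- rep(c("a", "b"), each = 5)
  expect_equal(nei_fst(fixed, pop), 1)
  # identical frequencies, decent n: near zero
  set.seed(14)
  same <- matrix(rbinom(40 * 200, 2, 0.5), 40, 200)
  expect_lt(abs(nei_fst(same, rep(c("a", "b"), each = 20))), 0.02)
  # 3-population toy vs direct evaluation of the corrected components
  set.seed(15)
  m <- matrix(rbinom(18 * 5, 2, runif(5, 0.2, 0.8)), 18, 5, byrow = TRUE)
  pop3 <- rep(c("a", "b", "c"), each = 6)
  oracle_locus <- function(l) {
    nk <- tapply(!is.na(m[, l]), pop3, sum)
    pk <- tapply(m[, l], pop3, mean) / 2
    hok <- tapply(m[, l] == 1, pop3, mean)
    r <- 3; ntil <- r / sum(1 / nk)
    hs <- ntil / (ntil - 1) *
      (1 - mean(pk^2 + (1 - pk)^2) - mean(hok) / (2 * ntil))
    pb <- mean(pk)
    ht <- 1 - (pb^2 + (1 - pb)^2) + hs / (r * ntil) - mean(hok) / (2 * r * ntil)
    c(hs = hs, dstp = r / (r - 1) * (ht - hs))
  }
  comp <- vapply(1:5, oracle_locus, c(1, 1))
  oracle <- mean(comp["dstp", ]) / mean(comp["hs", ] + comp["dstp", ])
  expect_equal(nei_fst(m, pop3), oracle, tolerance = 1e-12)
  expect_error(nei_fst(m, rep("a", 18)), "2 populations")
  expect_error(nei_fst(matrix(0, 8, 3), rep(c("a", "b"), each = 4)),
               "undefined")
})

test_that("pairwise Fst is symmetric with a zero diagonal", {
  design <- flat_design(3, 10, 100, f_pop = 0.1)
  gd <- simulate_genotypes(design, seed = 16)
  pw <- pairwise_fst(gd$dosage, gd$metadata$population)
  expect_equal(pw, t(pw))
  expect_equal(unname(diag(pw)), rep(0, 3))
  # a population duplicated under two labels: near-zero differentiation
  # (the small-sample corrections leave a residual of order 1/(4(n-1)))
  big <- simulate_genotypes(flat_design(1, 30, 300, f_pop = 1e-9),
                            seed = 26)
  dup <- rbind(big$dosage, big$dosage)
  rownames(dup) <- paste0("r", seq_len(60))
  lab <- rep(c("x", "y"), each = 30)
  expect_lt(abs(pairwise_fst(dup, lab)["x", "y"]), 0.02)
})

test_that("the Fst permutation test is seeded with the +1 floor", {
  design <- flat_design(2, 8, 60, f_pop = 0.3)
  gd <- simulate_genotypes(design, seed = 17)
  res <- fst_permutation(gd$dosage, gd$metadata$population, n_perm = 99,
                         seed = 6)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 0.05)
  res2 <- fst_permutation(gd$dosage, gd$metadata$population, n_perm = 99,
                          seed = 6)
  expect_identical(res$p, res2$p)
  # label order does not change the observed statistic
  ord <- rev(seq_len(nrow(gd$dosage)))
  expect_equal(nei_fst(gd$dosage[ord, ], gd$metadata$population[ord]),
               res$fst, tolerance = 1e-12)
})

test_that("great-circle distances agree with an independent geodesic", {
  pts <- data.frame(site = c("north", "south"),
                    latitude = c(-29.345, -34.036),
                    longitude = c(17.787, 18.799))
  d <- geographic_distance_matrix(pts)
  expect_equal(unname(diag(d)), c(0, 0))
  # independent oracle: WGS84 ellipsoid geodesic, tolerance 0.5%
  ell <- geosphere::distGeo(c(17.787, -29.345), c(18.799, -34.036)) / 1000
  expect_lt(abs(d[1, 2] - ell) / ell, 0.005)
  # antipodal points: half the sphere circumference
  anti <- data.frame(site = c("a", "b"), latitude = c(0, 0),
                     longitude = c(0, 180))
  expect_equal(geographic_distance_matrix(anti)[1, 2], pi * 6371,
               tolerance = 1e-6)
  bad <- data.frame(site = "x", latitude = 95, longitude = 0)
  expect_error(geographic_distance_matrix(bad), "out of range")
})

test_that("environmental distances are absolute AI differences", {
  ai <- c(a = 0.04, b = 0.86, c = 0.11)
  env <- environmental_distance_matrix(ai)
  expect_equal(env["a", "b"], 0.82)
  expect_equal(env, t(env))
  # triangle inequality
  expect_lte(env["a", "b"], env["a", "c"] + env["c", "b"] + 1e-12)
})

test_that("isolation models recover constructed linear systems", {
  set.seed(18)
  sites <- data.frame(site = paste0("P", 1:5),
                      latitude = -30 - runif(5, 0, 4),
                      longitude = 18 + runif(5, 0, 2),
                      ai = c(0.04, 0.07, 0.11, 0.42, 0.86))
  geo <- geographic_distance_matrix(sites)
  env <- environmental_distance_matrix(setNames(sites$ai, sites$site))
  # genetic distance an exact function of the environment
  gen <- 0.02 + 0.3 * env
  fit <- isolation_models(gen, geo, env)
  expect_equal(unname(fit$joint$coefficients["env"]), 0.3,
               tolerance = 1e-10)
  expect_equal(unname(fit$joint$coefficients["geo"]), 0, tolerance = 1e-10)
  # residualized model-2 slope is algebraically the joint env coefficient
  expect_equal(fit$residual$slope, unname(fit$joint$coefficients["env"]),
               tolerance = 1e-10)
  # raw-predictor mode attenuates when geo and env correlate
  raw <- isolation_models(gen, geo, env, residual_predictor = "raw")
  expect_lte(raw$residual$slope, fit$residual$slope + 1e-12)
  # constant genetic distance: zero coefficients
  const <- matrix(0.5, 5, 5); diag(const) <- 0
  dimnames(const) <- dimnames(gen)
  fit0 <- isolation_models(const, geo, env)
  expect_equal(unname(fit0$joint$coefficients[-1]), c(0, 0),
               tolerance = 1e-10)
  # ordered pairs reproduce df = (2, 17) with 5 sites
  fit_ord <- isolation_models(gen + matrix(rnorm(25, 0, 1e-4), 5), geo,
                              env, ordered = TRUE)
  expect_equal(unname(fit_ord$joint$df), c(2, 17))
  # mantel permutation p is seeded
  m1 <- isolation_models(gen, geo, env, n_perm = 99, seed = 7)
  m2 <- isolation_models(gen, geo, env, n_perm = 99, seed = 7)
  expect_identical(m1$mantel, m2$mantel)
})

test_that("isolation models warn on collinear predictors", {
  sites <- data.frame(site = paste0("P", 1:4), latitude = -30 - (1:4),
                      longitude = rep(18, 4))
  geo <- geographic_distance_matrix(sites)
  env <- geo / 111                     # exact rescaling
  gen <- 0.1 * geo / max(geo); diag(gen) <- 0
  expect_warning(isolation_models(gen, geo, env), "collinear")
})

test_that("diversity-gradient fits recover lines and parabolas", {
  panel <- data.frame(population = paste0("P", 1:6),
                      Ar = 1.3 - 0.2 * seq(0.1, 0.9, length.out = 6),
                      private_alleles = NA)
  ai <- setNames(seq(0.1, 0.9, length.out = 6), panel$population)
  panel$private_alleles <- 50 + 200 * (ai - 0.5)^2   # U shape
  fits <- fit_diversity_gradient(panel, ai,
                                 responses = c("Ar", "private_alleles"))
  expect_equal(fits$Ar$linear$slope, -0.2, tolerance = 1e-10)
  expect_equal(fits$Ar$linear$r_squared, 1, tolerance = 1e-10)
  expect_gt(fits$private_alleles$quadratic$coefficients[["I(x^2)"]], 0)
  expect_equal(unname(fits$private_alleles$quadratic$coefficients[["I(x^2)"]]),
               200, tolerance = 1e-8)
})
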