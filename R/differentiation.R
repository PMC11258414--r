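# Nei Fst (global and pairwise) with permutation significance, geographic
# and environmental distance matrices, isolation-by-distance versus
# isolation-by-environment regression, and diversity-vs-aridity gradients.

# Per-locus gene-diversity components following Nei (1987) with the
# Nei & Chesser (1983) small-sample corrections. Populations with fewer
# than 2 called genotypes at a locus are dropped for that locus.
nei_components <- function(dosage, pop) {
  m <- as.matrix(dosage)
  pops <- unique(pop)
  nmat <- vapply(pops, function(pp)
    colSums(!is.na(m[pop == pp, , drop = FALSE])), numeric(ncol(m)))
  pmat <- vapply(pops, function(pp)
    colMeans(m[pop == pp, , drop = FALSE], na.rm = TRUE) / 2,
    numeric(ncol(m)))
  homat <- vapply(pops, function(pp)
    colMeans(m[pop == pp, , drop = FALSE] == 1, na.rm = TRUE),
    numeric(ncol(m)))
  if (!is.matrix(nmat)) {
    nmat <- matrix(nmat, nrow = ncol(m)); pmat <- matrix(pmat, nrow = ncol(m))
    homat <- matrix(homat, nrow = ncol(m))
  }
  hs <- ht <- dst <- rep(NA_real_, ncol(m))
  for (l in seq_len(ncol(m))) {
    ok <- nmat[l, ] >= 2
    r <- sum(ok)
    if (r < 2) next
    nk <- nmat[l, ok]; pk <- pmat[l, ok]; hok <- homat[l, ok]
    ntilde <- r / sum(1 / nk)
    ho_bar <- mean(hok)
    s1 <- mean(pk^2 + (1 - pk)^2)
    hs_l <- ntilde / (ntilde - 1) * (1 - s1 - ho_bar / (2 * ntilde))
    pbar <- mean(pk)
    ht_l <- 1 - (pbar^2 + (1 - pbar)^2) + hs_l / (r * ntilde) -
      ho_bar / (2 * r * ntilde)
    dst_l <- r / (r - 1) * (ht_l - hs_l)   # Nei 1987 Dst' correction
    hs[l] <- hs_l; ht[l] <- ht_l; dst[l] <- dst_l
  }
  list(hs = hs, ht = ht, dstp = dst)
}

#' Global Nei Fst
#'
#' Fst = Dst'/Ht' where Hs and Ht are the sample-size-corrected gene
#' diversities of Nei & Chesser (1983), Dst' = r/(r-1) (Ht - Hs) applies
#' Nei's (1987) correction for the number of populations r, and
#' Ht' = Hs + Dst'. Components are averaged across loci before the ratio.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param pop Population label per sample (at least two populations, each
#'   with at least two genotyped individuals per usable locus).
#' @return Global Fst.
#' @export
nei_fst <- function(dosage, pop) {
  if (length(unique(pop)) < 2L)
    stop("need at least 2 populations", call. = FALSE)
  cmp <- nei_components(dosage, pop)
  htp <- mean(cmp$hs + cmp$dstp, na.rm = TRUE)
  if (!is.finite(htp) || htp <= 0)
    stop("total gene diversity is zero: Fst undefined", call. = FALSE)
  mean(cmp$dstp, na.rm = TRUE) / htp
}

#' Permutation test for global Fst
#'
#' Individuals are permuted among populations (population sizes preserved)
#' and the global Nei Fst recomputed; the p-value uses the +1 correction so
#' 999 permutations can return exactly 0.001.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param pop Population label per sample.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with \code{fst}, \code{p}, \code{n_perm}, and \code{sims}
#'   (the permuted statistics).
#' @export
fst_permutation <- function(dosage, pop, n_perm = 999, seed) {
  obs <- nei_fst(dosage, pop)
  sims <- with_seed(seed, vapply(seq_len(n_perm), function(b)
    nei_fst(dosage, sample(pop)), 1))
  list(fst = obs, p = perm_pvalue(sum(sims >= obs - 1e-12), n_perm),
       n_perm = n_perm, sims = sims)
}

#' Pairwise Nei Fst matrix
#'
#' @param dosage Samples x loci dosage matrix.
#' @param pop Population label per sample.
#' @return Symmetric matrix of pairwise Fst (zero diagonal), populations in
#'   first-appearance order.
#' @export
pairwise_fst <- function(dosage, pop) {
  pops <- unique(pop)
  k <- length(pops)
  out <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- pop %in% c(pops[i], pops[j])
    out[i, j] <- out[j, i] <- nei_fst(dosage[sel, , drop = FALSE], pop[sel])
  }
  out
}

#' Great-circle distance matrix between sites
#'
#' Haversine distances on a sphere of radius 6371 km.
#'
#' @param coords Data frame with columns \code{site} (or row names),
#'   \code{latitude}, \code{longitude} in decimal degrees.
#' @return Symmetric distance matrix in kilometres.
#' @export
geographic_distance_matrix <- function(coords) {
  if (any(abs(coords$latitude) > 90) || any(abs(coords$longitude) > 180))
    stop("coordinates out of range", call. = FALSE)
  pts <- cbind(coords$longitude, coords$latitude)
  k <- nrow(pts)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- geosphere::distHaversine(pts[i, ], pts[j, ],
                                                   r = 6371000) / 1000
  nm <- if ("site" %in% names(coords)) coords$site else rownames(coords)
  dimnames(d) <- list(nm, nm)
  d
}

#' Environmental (Aridity Index) distance matrix
#'
#' @param ai Named numeric vector of per-site Aridity Index values.
#' @return Symmetric matrix of absolute AI differences.
#' @export
environmental_distance_matrix <- function(ai) {
  d <- abs(outer(ai, ai, `-`))
  dimnames(d) <- list(names(ai), names(ai))
  d
}

lower_pairs <- function(m, ordered = FALSE) {
  m <- as.matrix(m)
  if (ordered) m[row(m) != col(m)] else m[lower.tri(m)]
}

#' Isolation-by-distance and isolation-by-environment models
#'
#' Fits (1) a joint least-squares model of pairwise genetic distance on
#' geographic and environmental distance and (2) the residual procedure:
#' residuals of genetic ~ geographic regressed on environmental distance.
#' With \code{residual_predictor = "residualized"} (default) the
#' environmental predictor of model 2 is itself residualized on geographic
#' distance, which makes the model-2 slope algebraically identical to the
#' joint model's environmental coefficient; \code{"raw"} regresses on the
#' raw environmental distances instead.
#'
#' Because distance pairs are not independent observations, parametric
#' p-values carry a caveat; a Mantel-style permutation test (permuting
#' site identities and recomputing the coefficients) is available via
#' \code{n_perm}.
#'
#' @param genetic,geographic,environmental Conformable square distance
#'   matrices over the same sites.
#' @param ordered Use all ordered pairs (each pair twice) instead of the
#'   default unordered pairs.
#' @param residual_predictor \code{"residualized"} or \code{"raw"} (see
#'   above).
#' @param n_perm Mantel permutations for the environmental coefficient
#'   (0 = parametric only).
#' @param seed Seed when \code{n_perm > 0}.
#' @return List of class \code{isolation_models} with elements \code{joint}
#'   (coefficients, F, df, parametric p per coefficient) and
#'   \code{residual} (slope, F, df, p), plus Mantel p-values when requested.
#' @export
isolation_models <- function(genetic, geographic, environmental,
                             ordered = FALSE,
                             residual_predictor = c("residualized", "raw"),
                             n_perm = 0, seed = NULL) {
  residual_predictor <- match.arg(residual_predictor)
  k <- nrow(as.matrix(genetic))
  if (k < 4) stop("need at least 4 sites", call. = FALSE)
  fit_once <- function(perm = seq_len(k)) {
    gme <- as.matrix(genetic)[perm, perm]
    gen <- lower_pairs(gme, ordered)
    geo <- lower_pairs(geographic, ordered)
    env <- lower_pairs(environmental, ordered)
    m1 <- stats::lm(gen ~ geo + env)
    r <- stats::resid(stats::lm(gen ~ geo))
    x2 <- if (residual_predictor == "residualized")
      stats::resid(stats::lm(env ~ geo)) else env
    m2 <- stats::lm(r ~ x2)
    list(m1 = m1, m2 = m2)
  }
  if (abs(stats::cor(lower_pairs(geographic, ordered),
                     lower_pairs(environmental, ordered))) > 0.999)
    warning("geographic and environmental distances are collinear: joint",
            " coefficients are unstable", call. = FALSE)
  fits <- fit_once()
  sum1 <- summary(fits$m1); sum2 <- summary(fits$m2)
  fstat <- function(s) if (is.null(s$fstatistic)) c(NA, NA, NA) else
    s$fstatistic
  f1 <- fstat(sum1); f2 <- fstat(sum2)
  out <- list(
    joint = list(coefficients = stats::coef(fits$m1),
                 p = sum1$coefficients[, 4],
                 F = unname(f1[1]), df = unname(f1[2:3]),
                 F_p = if (is.na(f1[1])) NA else
                   stats::pf(f1[1], f1[2], f1[3], lower.tail = FALSE)),
    residual = list(slope = unname(stats::coef(fits$m2)[2]),
                    p = sum2$coefficients[2, 4],
                    se = sum2$coefficients[2, 2],
                    F = unname(f2[1]), df = unname(f2[2:3]),
                    F_p = if (is.na(f2[1])) NA else
                      stats::pf(f2[1], f2[2], f2[3], lower.tail = FALSE)),
    residual_predictor = residual_predictor, ordered = ordered)
  if (n_perm > 0) {
    if (is.null(seed)) stop("`seed` required when n_perm > 0", call. = FALSE)
    obs_env <- abs(stats::coef(fits$m1)[["env"]])
    obs_res <- abs(out$residual$slope)
    sims <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      f <- fit_once(sample.int(k))
      c(abs(stats::coef(f$m1)[["env"]]), abs(stats::coef(f$m2)[[2]]))
    }, c(1, 1)))
    out$mantel <- list(
      joint_env_p = perm_pvalue(sum(sims[1, ] >= obs_env - 1e-12), n_perm),
      residual_p = perm_pvalue(sum(sims[2, ] >= obs_res - 1e-12), n_perm),
      n_perm = n_perm)
  }
  class(out) <- "isolation_models"
  out
}

#' @export
print.isolation_models <- function(x, ...) {
  cat("Joint IBD + IBE model: F =", round(x$joint$F, 3), "on",
      paste(x$joint$df, collapse = ", "), "df\n")
  print(round(x$joint$coefficients, 5))
  cat("Residual IBE model (", x$residual_predictor, " predictor): slope = ",
      round(x$residual$slope, 5), ", p = ",
      signif(x$residual$p, 3), "\n", sep = "")
  if (!is.null(x$mantel))
    cat("Mantel permutation p (env):", x$mantel$joint_env_p, "\n")
  invisible(x)
}

#' Diversity-versus-aridity gradient fits
#'
#' Linear least-squares fits of per-population diversity statistics on the
#' Aridity Index; private-allele counts additionally get a quadratic term
#' (the curvature captures accumulation at both environmental extremes).
#'
#' @param panel A \code{\link{diversity_panel}} data frame (or any data
#'   frame with a \code{population} column and response columns).
#' @param ai Named numeric vector of AI per population.
#' @param responses Response columns to fit.
#' @param quadratic Responses that also get a quadratic fit.
#' @return Named list; per response, a list with \code{linear}
#'   (slope, intercept, p, r_squared) and, where requested,
#'   \code{quadratic} (coefficients, curvature p).
#' @export
fit_diversity_gradient <- function(panel, ai,
                                   responses = c("Ar", "Ho", "He", "uHe",
                                                 "Fis", "private_alleles"),
                                   quadratic = "private_alleles") {
  x <- ai[panel$population]
  out <- list()
  for (resp in intersect(responses, names(panel))) {
    y <- panel[[resp]]
    if (sum(is.finite(y)) < 3) next
    lin <- stats::lm(y ~ x)
    sl <- summary(lin)
    entry <- list(linear = list(
      slope = unname(stats::coef(lin)[2]),
      intercept = unname(stats::coef(lin)[1]),
      p = sl$coefficients[2, 4], r_squared = sl$r.squared))
    if (resp %in% quadratic && length(y) >= 4) {
      qu <- stats::lm(y ~ x + I(x^2))
      sq <- summary(qu)
      entry$quadratic <- list(coefficients = stats::coef(qu),
                              curvature_p = sq$coefficients[3, 4],
                              r_squared = sq$r.squared)
    }
    out[[resp]] <- entry
  }
  out
}
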