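# Per-population SNP diversity: Hardy-Weinberg tests, multilocus linkage
# disequilibrium (index of association), heterozygosities, rarefied allelic
# richness, private alleles and the inbreeding coefficient.

#' Unbiased expected heterozygosity from He and sample size
#'
#' Applies the small-sample correction \code{uHe = He * 2N / (2N - 1)},
#' where N is the number of diploid individuals genotyped.
#'
#' @param he Expected heterozygosity (2pq), in [0, 1].
#' @param n Number of diploid individuals.
#' @return Unbiased expected heterozygosity.
#' @examples
#' unbiased_he(0.197, 8)
#' @export
unbiased_he <- function(he, n) {
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  he * 2 * n / (2 * n - 1)
}

#' Per-locus and mean heterozygosities
#'
#' For each locus: Ho is the fraction of called genotypes that are
#' heterozygous, He = 2p(1-p) from the alternate-allele frequency, and
#' uHe applies the 2N/(2N-1) correction with N the locus's called sample
#' size. Population-level values are unweighted means across loci.
#'
#' @param dosage Samples x loci dosage matrix (0/1/2, NA = missing).
#' @param polymorphic_only Restrict the means to loci polymorphic within
#'   this sample set (default FALSE: all loci contribute).
#' @return List with \code{per_locus} (data frame: N, p_alt, Ho, He, uHe)
#'   and \code{means} (named vector Ho, He, uHe).
#' @export
heterozygosities <- function(dosage, polymorphic_only = FALSE) {
  m <- as.matrix(dosage)
  N <- colSums(!is.na(m))
  if (any(N == 0))
    message(sum(N == 0), " locus/loci with no called genotypes skipped")
  p <- colMeans(m, na.rm = TRUE) / 2
  ho <- colMeans(m == 1, na.rm = TRUE)
  he <- 2 * p * (1 - p)
  uhe <- ifelse(N >= 1, unbiased_he(he, pmax(N, 1)), NA_real_)
  keep <- N >= 1
  if (polymorphic_only) keep <- keep & p > 0 & p < 1
  per_locus <- data.frame(N = N, p_alt = p, Ho = ho, He = he, uHe = uhe)
  list(per_locus = per_locus,
       means = c(Ho = mean(ho[keep]), He = mean(he[keep]),
                 uHe = mean(uhe[keep])))
}

#' Chi-square test for Hardy-Weinberg equilibrium at one locus
#'
#' Expected genotype counts are p^2, 2pq, q^2 times the called sample size;
#' the statistic has 1 degree of freedom.
#'
#' @param counts Genotype counts \code{c(hom_ref, het, hom_alt)}.
#' @return List with \code{chisq}, \code{p}, \code{df}; both statistics NA
#'   with \code{monomorphic = TRUE} when the locus carries one allele.
#' @export
hwe_chisq <- function(counts) {
  if (length(counts) != 3L || any(counts < 0))
    stop("`counts` must be c(hom_ref, het, hom_alt)", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("no called genotypes", call. = FALSE)
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  if (p == 0 || p == 1)
    return(list(chisq = NA_real_, p = NA_real_, df = 1L,
                monomorphic = TRUE))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expd)^2 / expd)
  list(chisq = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, monomorphic = FALSE)
}

# Distribution of the heterozygote count when the 2n alleles (m alternate)
# are randomly re-paired into n genotypes: the permutation null for HWE.
het_count_distribution <- function(n, m) {
  h <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  a <- (m - h) / 2                     # hom-alt counts
  logw <- lchoose(n, a) + lchoose(n - a, h) + h * log(2)
  w <- exp(logw - max(logw))
  list(h = h, prob = w / sum(w))
}

#' Monte-Carlo permutation test for Hardy-Weinberg equilibrium
#'
#' Randomly re-pairs the observed alleles into genotypes (sampling the
#' heterozygote count from its exact re-pairing distribution, which is
#' equivalent to shuffling alleles among genotypes) and compares the
#' chi-square statistic of each replicate with the observed one, with the
#' +1 permutation correction.
#'
#' @param counts Genotype counts \code{c(hom_ref, het, hom_alt)}.
#' @param n_perm Number of Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with \code{p}, \code{chisq_obs}, \code{n_perm};
#'   \code{monomorphic = TRUE} (p NA) for single-allele loci.
#' @export
hwe_mc <- function(counts, n_perm = 1000, seed) {
  obs <- hwe_chisq(counts)
  if (isTRUE(obs$monomorphic))
    return(list(p = NA_real_, chisq_obs = NA_real_, n_perm = n_perm,
                monomorphic = TRUE))
  n <- sum(counts); m <- 2 * counts[3] + counts[2]
  dist <- het_count_distribution(n, m)
  chi_of_h <- vapply(dist$h, function(h)
    hwe_chisq(c(n - h - (m - h) / 2, h, (m - h) / 2))$chisq, 1)
  chi_of_h[is.na(chi_of_h)] <- 0       # monomorphic rearrangement: no signal
  sims <- with_seed(seed,
    sample(chi_of_h, n_perm, replace = TRUE, prob = dist$prob))
  list(p = perm_pvalue(sum(sims >= obs$chisq - 1e-12), n_perm),
       chisq_obs = obs$chisq, n_perm = n_perm, monomorphic = FALSE)
}

# Pair-by-locus distance matrix: absolute dosage difference per locus for
# every unordered sample pair. Missing genotypes are mean-imputed per locus.
pair_locus_distance <- function(m) {
  for (l in seq_len(ncol(m))) {
    nas <- is.na(m[, l])
    if (any(nas)) m[nas, l] <- mean(m[, l], na.rm = TRUE)
  }
  n <- nrow(m)
  ip <- rep(seq_len(n - 1), times = (n - 1):1)
  jp <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  abs(m[ip, , drop = FALSE] - m[jp, , drop = FALSE])
}

ia_stats <- function(dl) {
  # dl: pairs x loci distance matrix
  np <- nrow(dl)
  var0 <- function(x) mean(x^2) - mean(x)^2
  vl <- apply(dl, 2, var0)
  D <- rowSums(dl)
  VO <- var0(D)
  VE <- sum(vl)
  sv <- sum(sqrt(vl))
  denom <- sv^2 - sum(vl)              # 2 * sum_{l<m} sqrt(vl vm)
  c(Ia = if (VE > 0) VO / VE - 1 else NA_real_,
    rbarD = if (denom > 0) (VO - VE) / denom else NA_real_)
}

#' Index of association and standardized multilocus linkage disequilibrium
#'
#' Computes Ia = Var(D)/sum(var_l) - 1, where D is the total across loci of
#' per-locus pairwise dosage distances, and the standardized form rbarD
#' which divides the covariance excess by its maximum
#' 2*sum over locus pairs of sqrt(var_l var_m). Significance comes from
#' shuffling each locus's genotypes independently across individuals,
#' which destroys between-locus association while preserving per-locus
#' frequencies.
#'
#' @param dosage Samples x loci dosage matrix for one population.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with \code{Ia}, \code{rbarD}, \code{p} (for rbarD),
#'   \code{n_perm}.
#' @export
index_of_association <- function(dosage, n_perm = 999, seed) {
  m <- as.matrix(dosage)
  keep <- apply(m, 2, function(x) {
    x <- x[!is.na(x)]; length(unique(x)) > 1
  })
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2L)
    stop("need at least 2 polymorphic loci", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 individuals", call. = FALSE)
  dl <- pair_locus_distance(m)
  obs <- ia_stats(dl)
  p <- NA_real_
  if (n_perm > 0) {
    sims <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      shuffled <- apply(m, 2, sample)
      ia_stats(pair_locus_distance(shuffled))[["rbarD"]]
    }, 1))
    p <- perm_pvalue(sum(sims >= obs[["rbarD"]] - 1e-12), n_perm)
  }
  list(Ia = obs[["Ia"]], rbarD = obs[["rbarD"]], p = p, n_perm = n_perm)
}

#' Rarefied allelic richness
#'
#' Hypergeometric rarefaction of allele counts to a common number of gene
#' copies g: \code{Ar = sum_a (1 - choose(N - N_a, g)/choose(N, g))}, the
#' expected number of distinct alleles in a draw of g copies.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param pop Population label per sample.
#' @param g Number of gene copies to rarefy to. Default (NULL) uses, per
#'   locus, the minimum copy count across populations; loci unscored in some
#'   population are dropped.
#' @return List with \code{per_locus} (loci x populations matrix of Ar),
#'   \code{mean} (named per-population means) and \code{g} used per locus.
#' @export
rarefied_allelic_richness <- function(dosage, pop, g = NULL) {
  m <- as.matrix(dosage)
  pops <- unique(pop)
  L <- ncol(m)
  copies <- vapply(pops, function(pp)
    colSums(!is.na(m[pop == pp, , drop = FALSE])) * 2, numeric(L))
  alt <- vapply(pops, function(pp)
    colSums(m[pop == pp, , drop = FALSE], na.rm = TRUE), numeric(L))
  if (is.matrix(copies) == FALSE) { copies <- t(copies); alt <- t(alt) }
  if (is.null(g)) {
    g_l <- apply(copies, 1, min)
    usable <- g_l >= 1
  } else {
    if (any(copies < g))
      stop("rarefaction size g exceeds available gene copies at some locus",
           call. = FALSE)
    g_l <- rep(g, L); usable <- rep(TRUE, L)
  }
  ar <- matrix(NA_real_, L, length(pops), dimnames = list(NULL, pops))
  for (k in seq_along(pops)) {
    N <- copies[, k]; Na <- alt[, k]; Nr <- N - Na
    gl <- g_l
    miss_term <- function(cnt)           # P(allele absent from g draws)
      exp(lchoose(N - cnt, gl) - lchoose(N, gl))
    ar[, k] <- (1 - miss_term(Nr)) + (1 - miss_term(Na))
  }
  ar[!usable, ] <- NA_real_
  list(per_locus = ar, mean = colMeans(ar, na.rm = TRUE), g = g_l)
}

#' Private allele counts per population
#'
#' An allele at a locus is counted for a population when it is observed
#' there and in no other population; counts are summed over loci.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param pop Population label per sample.
#' @return Named integer vector of private-allele counts per population.
#' @export
private_alleles <- function(dosage, pop) {
  m <- as.matrix(dosage)
  pops <- unique(pop)
  has_alt <- vapply(pops, function(pp)
    colSums(m[pop == pp, , drop = FALSE] > 0, na.rm = TRUE) > 0,
    logical(ncol(m)))
  has_ref <- vapply(pops, function(pp)
    colSums(m[pop == pp, , drop = FALSE] < 2, na.rm = TRUE) > 0,
    logical(ncol(m)))
  if (!is.matrix(has_alt)) { has_alt <- t(has_alt); has_ref <- t(has_ref) }
  priv <- function(present) {            # loci x pops logical
    only <- rowSums(present) == 1L
    colSums(present & only)
  }
  out <- priv(has_alt) + priv(has_ref)
  setNames(as.integer(out), pops)
}

#' Inbreeding coefficient Fis
#'
#' \code{Fis = 1 - mean(Ho) / mean(uHe)}, means taken across loci; positive
#' values indicate a heterozygote deficit.
#'
#' @param dosage Samples x loci dosage matrix for one population.
#' @param polymorphic_only Passed to \code{\link{heterozygosities}}.
#' @return Fis value.
#' @export
inbreeding_coefficient <- function(dosage, polymorphic_only = FALSE) {
  h <- heterozygosities(dosage, polymorphic_only)$means
  if (!is.finite(h[["uHe"]]) || h[["uHe"]] <= 0)
    stop("mean uHe is zero: Fis undefined", call. = FALSE)
  1 - h[["Ho"]] / h[["uHe"]]
}

#' Per-population diversity panel
#'
#' Assembles observed/expected/unbiased heterozygosity, rarefied allelic
#' richness, private alleles, Fis, Hardy-Weinberg summaries (mean per-locus
#' p and fraction of polymorphic loci significant at 0.05, for both the
#' chi-square and Monte-Carlo tests) and the multilocus linkage statistics
#' Ia and rbarD for each population. Loci monomorphic across the full data
#' set are excluded by default.
#'
#' @param gd A \code{genotype_data} object with metadata, or a dosage matrix
#'   (then \code{metadata} is required).
#' @param metadata Metadata data frame when \code{gd} is a bare matrix.
#' @param g Rarefaction size (NULL = locus-wise minimum; see
#'   \code{\link{rarefied_allelic_richness}}).
#' @param n_perm Replicates for the HWE Monte-Carlo and linkage permutation
#'   tests.
#' @param seed Integer seed for all Monte-Carlo components.
#' @param drop_monomorphic Drop loci monomorphic across the full data set.
#' @param one_per_colony Restrict to the first sample (by id order) of each
#'   colony before computing the panel, the family-structure sensitivity
#'   analysis.
#' @return Data frame of class \code{diversity_panel}, one row per
#'   population, with attribute \code{provenance} (seed, locus count, g
#'   mode).
#' @export
diversity_panel <- function(gd, metadata = NULL, g = NULL, n_perm = 199,
                            seed = 1, drop_monomorphic = TRUE,
                            one_per_colony = FALSE) {
  if (inherits(gd, "genotype_data")) {
    m <- gd$dosage; metadata <- gd$metadata
  } else m <- as.matrix(gd)
  if (is.null(metadata)) stop("metadata required", call. = FALSE)
  metadata <- metadata[match(rownames(m), metadata$sample), , drop = FALSE]
  if (one_per_colony) {
    ord <- order(metadata$sample)
    first <- !duplicated(metadata$colony[ord])
    keep_samples <- metadata$sample[ord][first]
    sel <- rownames(m) %in% keep_samples
    m <- m[sel, , drop = FALSE]
    metadata <- metadata[sel, , drop = FALSE]
  }
  if (drop_monomorphic) {
    p_all <- colMeans(m, na.rm = TRUE) / 2
    m <- m[, p_all > 0 & p_all < 1, drop = FALSE]
  }
  pop <- metadata$population
  pops <- unique(pop)
  ar <- rarefied_allelic_richness(m, pop, g)
  pa <- private_alleles(m, pop)
  seeds <- child_seeds(seed, length(pops), salt = 7L)
  rows <- lapply(seq_along(pops), function(k) {
    pp <- pops[k]
    sub <- m[pop == pp, , drop = FALSE]
    h <- heterozygosities(sub)
    fis <- tryCatch(inbreeding_coefficient(sub), error = function(e) NA_real_)
    counts <- apply(sub, 2, function(x)
      c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
        sum(x == 2, na.rm = TRUE)))
    hw_chi <- apply(counts, 2, function(cc) hwe_chisq(cc)$p)
    mc_seeds <- child_seeds(seeds[k], ncol(counts), salt = 3L)
    hw_mc <- vapply(seq_len(ncol(counts)), function(l)
      hwe_mc(counts[, l], n_perm = n_perm, seed = mc_seeds[l])$p, 1)
    ia <- tryCatch(
      index_of_association(sub, n_perm = n_perm, seed = seeds[k]),
      error = function(e) list(Ia = NA_real_, rbarD = NA_real_, p = NA_real_))
    data.frame(population = pp, n = nrow(sub),
               hwe_chisq_mean_p = mean(hw_chi, na.rm = TRUE),
               hwe_chisq_frac_sig = mean(hw_chi < 0.05, na.rm = TRUE),
               hwe_mc_mean_p = mean(hw_mc, na.rm = TRUE),
               hwe_mc_frac_sig = mean(hw_mc < 0.05, na.rm = TRUE),
               Ia = ia$Ia, rbarD = ia$rbarD, rbarD_p = ia$p,
               Ho = h$means[["Ho"]], He = h$means[["He"]],
               uHe = h$means[["uHe"]],
               Ar = unname(ar$mean[pp]), private_alleles = unname(pa[pp]),
               Fis = fis, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(seed = seed, n_loci = ncol(m),
                                  g = if (is.null(g)) "locus-wise minimum"
                                      else g,
                                  n_perm = n_perm,
                                  drop_monomorphic = drop_monomorphic,
                                  one_per_colony = one_per_colony)
  class(out) <- c("diversity_panel", class(out))
  out
}

#' Write a diversity panel
#'
#' @param panel A \code{\link{diversity_panel}} result.
#' @param path Output path without extension; writes \code{.tsv} plus a
#'   \code{.json} provenance block.
#' @return Invisibly, the paths written.
#' @export
write_diversity_panel <- function(panel, path) {
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(panel, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(panel = as.data.frame(panel),
                            provenance = attr(panel, "provenance")),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
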