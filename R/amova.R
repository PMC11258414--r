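# Hierarchical (nested) analysis of molecular variance on a pairwise
# distance matrix, with 2- or 3-level hierarchies, Phi fixation indices and
# permutation significance.

# Sum, over each group in `g`, of (sum of squared distances within the
# group) / group size. `d2` is the squared distance matrix.
ssd_within <- function(d2, g) {
  g <- as.factor(g)
  block <- rowsum(t(rowsum(d2, g)), g)      # group x group block sums
  sum(diag(as.matrix(block)) / (2 * tabulate(g)))
}

amova_components <- function(d2, pop, grp = NULL) {
  n <- nrow(d2)
  ssd_t <- sum(d2) / (2 * n)
  ssd_wp <- ssd_within(d2, pop)
  P <- length(unique(pop))
  if (is.null(grp)) {                       # 2-level: among / within pops
    df_a <- P - 1; df_w <- n - P
    ms_a <- (ssd_t - ssd_wp) / df_a
    ms_w <- ssd_wp / df_w
    n_sizes <- tabulate(as.factor(pop))
    ncoef <- (n - sum(n_sizes^2) / n) / df_a
    sig_w <- ms_w
    sig_a <- (ms_a - ms_w) / ncoef
    list(sigma = c(among_populations = sig_a, within_populations = sig_w),
         ssd = c(among_populations = ssd_t - ssd_wp,
                 within_populations = ssd_wp),
         df = c(df_a, df_w),
         phi = c(PhiST = if (sig_a + sig_w > 0)
           sig_a / (sig_a + sig_w) else NA_real_))
  } else {                                  # 3-level nested
    G <- length(unique(grp))
    ssd_wg <- ssd_within(d2, grp)
    ssd_ap <- ssd_wg - ssd_wp
    ssd_ag <- ssd_t - ssd_wg
    df_ag <- G - 1; df_ap <- P - G; df_wp <- n - P
    if (df_ap <= 0 || df_ag <= 0)
      stop("degenerate hierarchy: a level has a single group", call. = FALSE)
    tab <- table(pop, grp)
    n_p <- rowSums(tab)                     # per-population sizes
    pop_grp <- apply(tab > 0, 1, which)     # parent group per population
    S_g <- tapply(n_p, pop_grp, sum)        # group sizes
    sum_np2_by_g <- tapply(n_p^2, pop_grp, sum)
    A <- sum(sum_np2_by_g / S_g)
    n1 <- (n - A) / df_ap
    n2 <- (A - sum(n_p^2) / n) / df_ag
    n3 <- (n - sum(S_g^2) / n) / df_ag
    ms_wp <- ssd_wp / df_wp
    ms_ap <- ssd_ap / df_ap
    ms_ag <- ssd_ag / df_ag
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    tot <- sig_a + sig_b + sig_c
    list(sigma = c(among_groups = sig_a, among_populations = sig_b,
                   within_populations = sig_c),
         ssd = c(among_groups = ssd_ag, among_populations = ssd_ap,
                 within_populations = ssd_wp),
         df = c(df_ag, df_ap, df_wp),
         phi = c(
           PhiCT = if (tot > 0) sig_a / tot else NA_real_,
           PhiSC = if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c)
                   else NA_real_,
           PhiST = if (tot > 0) (sig_a + sig_b) / tot else NA_real_))
  }
}

#' Nested analysis of molecular variance
#'
#' Partitions the variance implied by a matrix of pairwise molecular
#' distances across a 2-level (population > sample) or 3-level
#' (group > population > sample) hierarchy, using the sums-of-squared-
#' distances decomposition with unequal-group-size coefficients, and reports
#' Phi fixation indices with optional permutation p-values.
#'
#' Permutation schemes are level-appropriate: PhiST permutes samples across
#' the whole data set, PhiSC permutes samples among populations within their
#' group, and PhiCT permutes whole populations among groups.
#'
#' @param d Symmetric pairwise distance matrix with zero diagonal, samples
#'   in rows/columns (row names used when present).
#' @param hierarchy Data frame with a \code{sample} column plus one or two
#'   grouping columns named in \code{levels}.
#' @param levels Character vector of hierarchy column names ordered from the
#'   top level down (e.g. \code{c("biome", "population")}); a single name
#'   gives the 2-level analysis.
#' @param squared Set TRUE if \code{d} already contains squared distances;
#'   by default distances are squared internally.
#' @param n_perm Number of permutations for p-values (0 = none).
#' @param seed Seed for the permutation generator (required when
#'   \code{n_perm > 0}).
#' @param truncate Report negative variance components as zero when
#'   computing percentages (off by default; raw components are shown
#'   as computed).
#' @return An object of class \code{amova_result}: \code{table} (source of
#'   variation, df, sigma2, percent variance), \code{phi} (named fixation
#'   indices), \code{p_values}, \code{n_perm}, and \code{perm_sd} (standard
#'   deviation of each index's permutation distribution).
#' @export
nested_amova <- function(d, hierarchy, levels, squared = FALSE,
                         n_perm = 0, seed = NULL, truncate = FALSE) {
  d <- check_square_distance(d)
  if (!all(levels %in% names(hierarchy)))
    stop("hierarchy lacks level column(s): ",
         paste(setdiff(levels, names(hierarchy)), collapse = ", "),
         call. = FALSE)
  if (!is.null(rownames(d)) && all(rownames(d) %in% hierarchy$sample))
    hierarchy <- hierarchy[match(rownames(d), hierarchy$sample), ,
                           drop = FALSE]
  if (nrow(hierarchy) != nrow(d))
    stop("hierarchy must cover every sample in the distance matrix",
         call. = FALSE)
  three <- length(levels) == 2L
  pop <- as.character(hierarchy[[levels[length(levels)]]])
  grp <- if (three) as.character(hierarchy[[levels[1L]]]) else NULL
  if (three && length(unique(grp)) == 1L) {
    message("top level has a single group: reducing to the 2-level analysis")
    three <- FALSE; grp <- NULL
  }
  if (three && any(rowSums(table(pop, grp) > 0) != 1L))
    stop("hierarchy is not nested: a population maps to several groups",
         call. = FALSE)
  if (length(unique(pop)) < 2L)
    stop("degenerate hierarchy: fewer than 2 populations", call. = FALSE)
  d2 <- if (squared) d else d^2
  obs <- amova_components(d2, pop, grp)
  sig_pct <- obs$sigma
  if (truncate) sig_pct <- pmax(sig_pct, 0)
  pct <- 100 * sig_pct / sum(sig_pct)
  p_values <- NULL; perm_sd <- NULL
  if (n_perm > 0) {
    if (is.null(seed)) stop("`seed` required when n_perm > 0", call. = FALSE)
    perm <- with_seed(seed, amova_permute(d2, pop, grp, obs$phi, n_perm))
    p_values <- perm$p; perm_sd <- perm$sd
  }
  structure(list(
    table = data.frame(source = names(obs$sigma), df = obs$df,
                       SSD = as.numeric(obs$ssd),
                       sigma2 = as.numeric(obs$sigma),
                       percent = as.numeric(pct), stringsAsFactors = FALSE),
    phi = obs$phi, p_values = p_values, perm_sd = perm_sd,
    n_perm = n_perm), class = "amova_result")
}

amova_permute <- function(d2, pop, grp, phi_obs, n_perm) {
  n <- length(pop)
  counts <- setNames(numeric(length(phi_obs)), names(phi_obs))
  sims <- matrix(NA_real_, n_perm, length(phi_obs),
                 dimnames = list(NULL, names(phi_obs)))
  if (is.null(grp)) {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      ph <- amova_components(d2, pop[idx], NULL)$phi
      sims[b, ] <- ph
    }
  } else {
    upop <- unique(pop)
    pop_grp <- grp[match(upop, pop)]
    m_ct <- exp(lfactorial(length(upop)) -
                  sum(lfactorial(table(pop_grp))))
    if (m_ct < n_perm + 1)
      warning(sprintf(paste0("only %.0f distinct population-to-group ",
                             "assignments: minimum attainable PhiCT p is ",
                             "about %.3g"), m_ct, 1 / m_ct), call. = FALSE)
    for (b in seq_len(n_perm)) {
      # PhiST: samples permuted across the whole data set (the population
      # and group labels move together, keeping the hierarchy nested)
      ist <- sample.int(n)
      ph_st <- amova_components(d2, pop[ist], grp[ist])$phi[["PhiST"]]
      # PhiSC: samples among populations within their group
      idx <- seq_len(n)
      for (g in unique(grp)) {
        at <- which(grp == g)
        idx[at] <- at[sample.int(length(at))]
      }
      ph_sc <- amova_components(d2, pop[idx], grp)$phi[["PhiSC"]]
      # PhiCT: whole populations among groups
      new_grp_of_pop <- sample(pop_grp)
      ph_ct <- amova_components(
        d2, pop, new_grp_of_pop[match(pop, upop)])$phi[["PhiCT"]]
      sims[b, ] <- c(ph_ct, ph_sc, ph_st)
    }
  }
  for (k in names(phi_obs))
    counts[k] <- sum(sims[, k] >= phi_obs[[k]] - 1e-12, na.rm = TRUE)
  list(p = perm_pvalue(counts, n_perm),
       sd = apply(sims, 2, stats::sd, na.rm = TRUE))
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Analysis of molecular variance\n")
  print(x$table, row.names = FALSE)
  cat("Fixation indices:\n")
  print(round(x$phi, 5))
  if (!is.null(x$p_values)) {
    cat("Permutation p-values (", x$n_perm, " permutations):\n", sep = "")
    print(round(x$p_values, 4))
  }
  invisible(x)
}

#' Squared Euclidean distances between dosage rows
#'
#' Pairwise squared Euclidean distance on genotype dosage vectors using
#' pairwise-complete loci, rescaled to the full locus count so samples with
#' missing data remain comparable.
#'
#' @param dosage Samples x loci dosage matrix (NA allowed).
#' @return Squared-distance matrix with sample row names.
#' @export
dosage_distance <- function(dosage) {
  m <- as.matrix(dosage)
  n <- nrow(m); L <- ncol(m)
  miss <- is.na(m)
  m0 <- m; m0[miss] <- 0
  obs <- (!miss) * 1
  cross <- tcrossprod(m0)
  sq <- tcrossprod(m0^2, obs)            # sum of x_i^2 over shared loci
  shared <- tcrossprod(obs)
  d2 <- sq + t(sq) - 2 * cross
  d2 <- d2 / pmax(shared, 1) * L
  diag(d2) <- 0
  d2[d2 < 0] <- 0
  dimnames(d2) <- list(rownames(m), rownames(m))
  d2
}

#' Pairwise nucleotide difference matrix from an alignment
#'
#' @param aln Character alignment matrix.
#' @return Matrix of pairwise difference counts (comparable sites only).
#' @export
alignment_distance <- function(aln) {
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- pair_diff(aln[i, ], aln[j, ])[["diff"]]
  d
}

#' Write an AMOVA result as TSV and JSON
#'
#' @param res An \code{amova_result}.
#' @param path Output path without extension.
#' @return Invisibly, the paths written.
#' @export
write_amova <- function(res, path) {
  tab <- res$table
  tab$phi <- c(res$phi, rep(NA, nrow(tab) - length(res$phi)))
  if (!is.null(res$p_values))
    tab$p <- c(res$p_values, rep(NA, nrow(tab) - length(res$p_values)))
  tsv <- paste0(path, ".tsv"); js <- paste0(path, ".json")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(table = tab, phi = as.list(res$phi),
                            p_values = as.list(res$p_values),
                            n_perm = res$n_perm),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
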