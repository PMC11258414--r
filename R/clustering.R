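# Multi-method population structure: PCA, k-means/discriminant clustering
# with BIC model choice, maximum-likelihood admixture with Evanno delta-K,
# and spatial PCA with Moran's I Monte-Carlo tests.

impute_dosage <- function(dosage, drop_constant = TRUE) {
  m <- as.matrix(dosage)
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na)) {
    message("dropping ", sum(all_na), " all-missing locus/loci")
    m <- m[, !all_na, drop = FALSE]
  }
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(m, na.rm = TRUE)
    m[nas] <- mu[nas[, 2]]
    message(nrow(nas), " missing genotype(s) imputed by locus mean")
  }
  if (drop_constant) {
    v <- apply(m, 2, stats::var)
    m <- m[, v > 0, drop = FALSE]
  }
  m
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are imputed by the locus mean; the matrix is centred
#' (optionally scaled) and decomposed by singular value decomposition.
#' Scores are deterministic up to axis sign.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param n_axes Number of axes to retain.
#' @param scale Scale loci to unit variance.
#' @return List of class \code{genotype_pca}: \code{scores},
#'   \code{eigenvalues} (all), \code{prop_var}, \code{rotation}.
#' @export
genotype_pca <- function(dosage, n_axes = 10, scale = FALSE) {
  m <- impute_dosage(dosage, drop_constant = scale)
  if (nrow(m) < 2) stop("need at least 2 samples", call. = FALSE)
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  n_axes <- min(n_axes, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(n_axes), drop = FALSE],
                 eigenvalues = ev,
                 prop_var = ev / sum(ev),
                 rotation = pc$rotation[, seq_len(n_axes), drop = FALSE]),
            class = "genotype_pca")
}

admixture_loglik <- function(g, Q, P) {
  pi_mat <- Q %*% P
  pi_mat <- pmin(pmax(pi_mat, 1e-10), 1 - 1e-10)
  ll <- g * log(pi_mat) + (2 - g) * log(1 - pi_mat)
  het <- which(!is.na(g) & g == 1)
  ll[het] <- ll[het] + log(2)
  sum(ll, na.rm = TRUE)
}

#' Maximum-likelihood admixture by EM
#'
#' Fits the binomial admixture model g_il ~ Binomial(2, sum_k q_ik p_kl)
#' by expectation-maximization: individuals carry mixture proportions Q
#' over K ancestral clusters with allele frequencies P. The log-likelihood
#' is non-decreasing across iterations; missing genotypes are ignored in
#' both updates.
#'
#' @param dosage Samples x loci dosage matrix (0/1/2, NA allowed).
#' @param K Number of clusters (>= 1).
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap.
#' @param tol Relative log-likelihood change for convergence.
#' @return List of class \code{admixture_run}: \code{K}, \code{Q} (n x K,
#'   rows sum to 1), \code{P} (K x loci), \code{loglik} (final),
#'   \code{loglik_trace}, \code{iterations}, \code{converged}, \code{seed}.
#' @export
admixture_em <- function(dosage, K, seed, max_iter = 500, tol = 1e-6) {
  g <- as.matrix(dosage)
  n <- nrow(g); L <- ncol(g)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K cannot exceed the number of samples", call. = FALSE)
  obs <- !is.na(g)
  gz <- g; gz[!obs] <- 0
  A <- gz; B <- (2 - gz) * obs
  Li <- rowSums(obs)
  if (K == 1L) {
    P <- matrix(colSums(A) / pmax(colSums(obs) * 2, 1), 1, L)
    Q <- matrix(1, n, 1)
    ll <- admixture_loglik(g, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik = ll,
                          loglik_trace = ll, iterations = 0L,
                          converged = TRUE, seed = seed),
                     class = "admixture_run"))
  }
  init <- with_seed(seed, {
    Q0 <- matrix(stats::rexp(n * K), n, K)
    Q0 <- Q0 / rowSums(Q0)
    pool <- colSums(A) / pmax(colSums(obs) * 2, 1)
    P0 <- matrix(pmin(pmax(rep(pool, each = K) +
                             stats::rnorm(K * L, 0, 0.1), 0.01), 0.99), K, L)
    list(Q = Q0, P = P0)
  })
  Q <- init$Q; P <- init$P
  trace <- numeric(0)
  ll_old <- -Inf; converged <- FALSE; it <- 0L
  eps <- 1e-9
  while (it < max_iter) {
    it <- it + 1L
    Pi <- Q %*% P
    Pi <- pmin(pmax(Pi, eps), 1 - eps)
    RA <- A / Pi; RB <- B / (1 - Pi)
    # shared responsibilities
    TQ <- Q * (RA %*% t(P) + RB %*% t(1 - P))
    num_p <- P * (t(Q) %*% RA)
    den_p <- num_p + (1 - P) * (t(Q) %*% RB)
    Q <- TQ / (2 * Li)
    Q <- Q / rowSums(Q)
    P <- ifelse(den_p > 0, num_p / den_p, P)
    P <- pmin(pmax(P, eps), 1 - eps)
    ll <- admixture_loglik(g, Q, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(K = as.integer(K), Q = Q, P = P,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 iterations = it, converged = converged, seed = seed),
            class = "admixture_run")
}

#' @export
print.admixture_run <- function(x, ...) {
  cat("Admixture EM: K =", x$K, "log-likelihood =", round(x$loglik, 2),
      if (x$converged) "(converged)" else "(iteration cap reached)", "\n")
  invisible(x)
}

#' Run an admixture grid over K with replicate seeds
#'
#' @param dosage Samples x loci dosage matrix.
#' @param K_values Vector of K values.
#' @param n_rep Replicate runs per K (different seeds).
#' @param seed Master seed; replicate seeds are derived from it.
#' @param ... Passed to \code{\link{admixture_em}}.
#' @return List with \code{runs} (nested list runs[[K]][[rep]]) and
#'   \code{loglik} (replicates x K matrix, columns named by K).
#' @export
admixture_grid <- function(dosage, K_values, n_rep = 5, seed = 1, ...) {
  loglik <- matrix(NA_real_, n_rep, length(K_values),
                   dimnames = list(NULL, as.character(K_values)))
  runs <- list()
  for (ki in seq_along(K_values)) {
    seeds <- child_seeds(seed, n_rep, salt = ki)
    runs[[as.character(K_values[ki])]] <- lapply(seq_len(n_rep), function(r) {
      run <- admixture_em(dosage, K_values[ki], seed = seeds[r], ...)
      loglik[r, ki] <<- run$loglik
      run
    })
  }
  list(runs = runs, loglik = loglik)
}

#' Evanno delta-K cluster-number selection
#'
#' delta-K(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K)),
#' where the means and standard deviations are across replicate runs.
#' delta-K is defined only for interior K with non-zero replicate sd;
#' zero-sd entries are flagged and excluded from the argmax.
#'
#' @param loglik Replicates x K matrix of log-likelihoods, columns named by
#'   K (as from \code{\link{admixture_grid}}).
#' @return List of class \code{evanno_table}: \code{table} (K, mean_L, sd_L,
#'   delta_K, sd_zero flag), \code{selected_K}, \code{low_confidence}
#'   (TRUE when no interior delta-K is defined or the peak is weak).
#' @export
evanno_select <- function(loglik) {
  K <- as.integer(colnames(loglik))
  if (length(K) < 3) stop("need at least 3 consecutive K values",
                          call. = FALSE)
  if (nrow(loglik) < 2) stop("need at least 2 replicates per K",
                             call. = FALSE)
  mean_l <- colMeans(loglik); sd_l <- apply(loglik, 2, stats::sd)
  dk <- rep(NA_real_, length(K))
  for (i in 2:(length(K) - 1)) {
    if (sd_l[i] > 0)
      dk[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1]) / sd_l[i]
  }
  sel <- if (all(is.na(dk))) NA_integer_ else K[which.max(dk)]
  structure(list(
    table = data.frame(K = K, mean_L = mean_l, sd_L = sd_l, delta_K = dk,
                       sd_zero = sd_l == 0, row.names = NULL),
    selected_K = sel,
    low_confidence = all(is.na(dk)) ||
      (sum(!is.na(dk)) > 1 &&
         max(dk, na.rm = TRUE) < 2 * stats::median(dk, na.rm = TRUE))),
    class = "evanno_table")
}

#' @export
print.evanno_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("Selected K =", x$selected_K,
      if (x$low_confidence) "(low confidence)" else "", "\n")
  invisible(x)
}

#' Discriminant analysis of principal components with BIC model choice
#'
#' Reduces the genotypes by PCA, runs seeded k-means for each candidate K,
#' scores each solution with BIC(K) = n log(WSS/n) + K log(n), selects the
#' lowest-BIC K, and computes linear discriminant axes on the selected
#' clustering (when K > 1).
#'
#' @param dosage Samples x loci dosage matrix.
#' @param K_range Candidate cluster counts.
#' @param n_pcs Number of principal components retained (must be smaller
#'   than the sample count). The default keeps min(n - 1, 40) axes:
#'   retaining most of the variance matters here, because the BIC compares
#'   within-cluster variance across K and discarding axes understates it.
#' @param seed Integer seed for k-means initialization.
#' @return List of class \code{dapc_result}: \code{assignments} (best K),
#'   \code{bic} (data frame K, BIC), \code{best_K}, \code{discriminant}
#'   (sample scores on LD axes, NULL for K = 1), \code{pca}.
#' @export
dapc_clusters <- function(dosage, K_range = 1:8, n_pcs = NULL, seed = 1) {
  n <- nrow(as.matrix(dosage))
  if (any(K_range >= n)) stop("K must be smaller than the sample count",
                              call. = FALSE)
  if (is.null(n_pcs)) n_pcs <- min(n - 1, 40)
  n_pcs <- min(n_pcs, n - 1)
  pca <- genotype_pca(dosage, n_axes = n_pcs)
  X <- pca$scores
  fits <- with_seed(seed, lapply(K_range, function(k)
    stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)))
  bic <- vapply(seq_along(K_range), function(i) {
    wss <- fits[[i]]$tot.withinss
    n * log(max(wss, 1e-12) / n) + K_range[i] * log(n)
  }, 1)
  best <- which.min(bic)
  assignments <- fits[[best]]$cluster
  disc <- NULL
  if (K_range[best] > 1) {
    ld <- MASS::lda(X, grouping = factor(assignments))
    disc <- stats::predict(ld, X)$x
  }
  structure(list(assignments = assignments,
                 bic = data.frame(K = K_range, BIC = bic),
                 best_K = K_range[best], discriminant = disc, pca = pca),
            class = "dapc_result")
}

# Row-standardized k-nearest-neighbour connectivity matrix.
knn_weights <- function(coords, k = 5) {
  n <- nrow(coords)
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(coords))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, -i])[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    W[i, nb] <- 1
  }
  W <- pmax(W, t(W))                    # symmetrize neighbourhoods
  W / rowSums(W)
}

#' Spatial principal component analysis
#'
#' Decomposes the product of the centred genotype matrix with a spatial lag
#' operator built from a row-standardized k-nearest-neighbour graph: the
#' eigenvalues combine variance and Moran's I spatial autocorrelation, with
#' large positive values indicating global structure (clines, patches) and
#' large negative values local structure (sharp neighbour differences).
#' Duplicate coordinates are broken by a small deterministic jitter.
#' Significance of global and local structure comes from Monte-Carlo
#' permutation of the genotype rows against the coordinates.
#'
#' @param dosage Samples x loci dosage matrix.
#' @param coords Two-column matrix/data frame of per-sample x, y
#'   coordinates.
#' @param k Number of nearest neighbours for the connectivity graph.
#' @param n_perm Monte-Carlo replicates for the global/local tests.
#' @param seed Integer seed (jitter and permutations).
#' @param jitter_sd Standard deviation of the coordinate jitter applied to
#'   duplicated coordinates (degrees).
#' @return List of class \code{spca_result}: \code{eigenvalues} (signed),
#'   \code{scores} (samples x axes, ordered by decreasing eigenvalue),
#'   \code{moran} (Moran's I of each axis), \code{global_p},
#'   \code{local_p}, \code{W}.
#' @export
spca <- function(dosage, coords, k = 5, n_perm = 999, seed = 1,
                 jitter_sd = 1e-4) {
  X <- impute_dosage(dosage)
  X <- scale(X, center = TRUE, scale = FALSE)
  n <- nrow(as.matrix(dosage))
  coords <- as.matrix(coords)
  if (anyDuplicated(coords))
    coords <- with_seed(seed,
      coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                      nrow(coords)))
  W <- knn_weights(coords, k)
  g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1)
    warning("connectivity graph has ", ncomp, " components", call. = FALSE)
  M <- (W + t(W)) / 2
  # reduce to the sample space: eigenvalues of X' M X equal those of S' M S
  # where S are the full PCA scores of X
  sv <- if (ncol(X) > 0) svd(X) else list(d = numeric(0))
  r <- sum(sv$d > 1e-8)
  if (r == 0L)                       # constant genotypes: no eigenstructure
    return(structure(list(eigenvalues = numeric(0),
                          scores = matrix(0, n, 0), moran = numeric(0),
                          global_p = NA_real_, local_p = NA_real_, W = W,
                          n_perm = n_perm), class = "spca_result"))
  S <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
  stat_pair <- function(Smat) {
    H <- t(Smat) %*% M %*% Smat / n
    H <- (H + t(H)) / 2
    e <- eigen(H, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors,
         global = max(e$values), local = -min(e$values))
  }
  obs <- stat_pair(S)
  scores <- S %*% obs$vectors
  colnames(scores) <- paste0("sPC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(dosage)
  lag_i <- function(s) as.numeric(t(s) %*% M %*% s / sum(s^2))
  moran <- apply(scores, 2, lag_i)
  global_p <- local_p <- NA_real_
  if (n_perm > 0) {
    sims <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      Sp <- S[sample.int(n), , drop = FALSE]
      st <- stat_pair(Sp)
      c(st$global, st$local)
    }, c(1, 1)))
    global_p <- perm_pvalue(sum(sims[1, ] >= obs$global - 1e-12), n_perm)
    local_p <- perm_pvalue(sum(sims[2, ] >= obs$local - 1e-12), n_perm)
  }
  structure(list(eigenvalues = obs$values, scores = scores, moran = moran,
                 global_p = global_p, local_p = local_p, W = W,
                 n_perm = n_perm), class = "spca_result")
}

#' @export
print.spca_result <- function(x, ...) {
  cat("Spatial PCA:", length(x$eigenvalues), "axes; leading eigenvalue",
      round(x$eigenvalues[1], 4), "\n")
  if (!is.na(x$global_p))
    cat("Global test p =", x$global_p, "; local test p =", x$local_p, "\n")
  invisible(x)
}
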