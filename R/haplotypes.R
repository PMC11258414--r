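# Mitochondrial haplotype analysis: haplotype collapsing, diversity and
# neutrality statistics, minimum spanning networks, and protein-level
# annotation of haplotype changes.

# Number of differing sites and number of comparable (both non-missing)
# sites between two aligned sequences. N and '-' are treated as missing.
pair_diff <- function(a, b) {
  ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
  c(diff = sum(a[ok] != b[ok]), comparable = sum(ok))
}

#' Collapse aligned sequences into haplotypes
#'
#' Sequences identical over their mutually comparable sites (sites with N or
#' a gap in either sequence are skipped, pairwise deletion) are assigned to
#' one haplotype; with \code{deletion = "complete"} only sites that are
#' called in every sequence are compared. Haplotypes are numbered by order
#' of first appearance in the alignment, so ids are stable across runs.
#'
#' @param aln Character matrix from \code{\link{read_fasta_alignment}}.
#' @param metadata Optional metadata data frame with \code{sample} and
#'   \code{population} columns for per-population counts.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"} handling
#'   of missing sites when comparing sequences.
#' @return A list of class \code{haplotype_table}: \code{haplotypes} (data
#'   frame with id, representative sample, count, private flag),
#'   \code{members} (list of sample id vectors), \code{pop_counts}
#'   (haplotypes x populations matrix, NULL without metadata),
#'   \code{sequences} (representative sequences, character matrix), and
#'   \code{assignment} (haplotype id per input sequence).
#' @export
collapse_haplotypes <- function(aln, metadata = NULL,
                                deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (is.null(dim(aln)) || nrow(aln) == 0L)
    stop("empty alignment", call. = FALSE)
  if (deletion == "complete") {
    called <- matrix(!(aln %in% c("N", "-")), nrow(aln))
    cmp <- aln[, colSums(called) == nrow(aln), drop = FALSE]
  } else cmp <- aln
  n <- nrow(aln)
  assignment <- integer(n)
  reps <- integer(0)                      # row index of each representative
  for (i in seq_len(n)) {
    hit <- 0L
    for (h in seq_along(reps)) {
      pd <- pair_diff(cmp[i, ], cmp[reps[h], ])
      if (pd[["diff"]] == 0L) { hit <- h; break }
    }
    if (hit == 0L) { reps <- c(reps, i); hit <- length(reps) }
    assignment[i] <- hit
  }
  ids <- paste0("H", seq_along(reps))
  members <- split(rownames(aln), factor(assignment, seq_along(reps)))
  names(members) <- ids
  counts <- lengths(members)
  pop_counts <- NULL
  private <- rep(NA, length(reps))
  if (!is.null(metadata)) {
    pop <- metadata$population[match(rownames(aln), metadata$sample)]
    if (any(is.na(pop)))
      stop("alignment contains samples absent from metadata", call. = FALSE)
    pop_counts <- table(factor(assignment, seq_along(reps)), pop)
    dimnames(pop_counts)[[1]] <- ids
    pop_counts <- unclass(pop_counts)
    private <- rowSums(pop_counts > 0) == 1L
  }
  structure(list(
    haplotypes = data.frame(id = ids,
                            representative = rownames(aln)[reps],
                            count = as.integer(counts),
                            private = private, stringsAsFactors = FALSE),
    members = members, pop_counts = pop_counts,
    sequences = aln[reps, , drop = FALSE],
    assignment = ids[assignment]), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(nrow(x$haplotypes), "haplotype(s) from",
      sum(x$haplotypes$count), "sequences\n")
  invisible(x)
}

#' Number of segregating sites
#'
#' Counts alignment columns carrying two or more distinct non-missing
#' states (N and '-' excluded).
#'
#' @param aln Character alignment matrix.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  sum(apply(aln, 2, function(col) {
    obs <- col[!(col %in% c("N", "-"))]
    length(unique(obs)) >= 2L
  }))
}

# Mean pairwise differences: per.site divides each pair by its comparable
# length (nucleotide diversity); otherwise raw difference counts are used
# (the k-hat entering Tajima's D).
mean_pairwise <- function(aln, per_site = TRUE) {
  n <- nrow(aln)
  tot <- 0; npair <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pd <- pair_diff(aln[i, ], aln[j, ])
    if (pd[["comparable"]] == 0L && per_site) next
    tot <- tot + if (per_site) pd[["diff"]] / pd[["comparable"]] else
      pd[["diff"]]
    npair <- npair + 1L
  }
  tot / npair
}

#' Nucleotide diversity
#'
#' Mean over all unordered sequence pairs of the per-site difference
#' fraction; each pair is divided by its own number of comparable sites
#' (pairwise deletion), so partially ambiguous sequences do not deflate the
#' estimate.
#'
#' @param aln Character alignment matrix.
#' @return Nucleotide diversity per site, in [0, 1].
#' @export
nucleotide_diversity <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences", call. = FALSE)
  mean_pairwise(aln, per_site = TRUE)
}

#' Tajima's D
#'
#' Contrasts the mean pairwise difference count with the segregating-site
#' estimator of the scaled mutation rate through the standard coefficient
#' chain (a1, a2, b1, b2, c1, c2, e1, e2): negative values indicate an
#' excess of low-frequency polymorphism.
#'
#' @param aln Character alignment matrix with at least 4 sequences
#'   recommended.
#' @return List with \code{D}, \code{S}, \code{khat} (mean pairwise
#'   differences) and \code{n}.
#' @export
tajimas_d <- function(aln) {
  n <- nrow(aln)
  if (n < 3L) stop("need at least 3 sequences for Tajima's D", call. = FALSE)
  S <- segregating_sites(aln)
  if (S == 0L) stop("no segregating sites: Tajima's D undefined",
                    call. = FALSE)
  khat <- mean_pairwise(aln, per_site = FALSE)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- (khat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = S, khat = khat, n = n)
}

#' Pairwise mutation distances between haplotypes
#'
#' @param ht A \code{haplotype_table}.
#' @return Integer matrix of Hamming distances over comparable sites.
#' @export
haplotype_distances <- function(ht) {
  seqs <- ht$sequences
  k <- nrow(seqs)
  d <- matrix(0L, k, k, dimnames = list(ht$haplotypes$id, ht$haplotypes$id))
  if (k > 1) for (i in seq_len(k - 1)) for (j in (i + 1):k)
    d[i, j] <- d[j, i] <- as.integer(
      pair_diff(seqs[i, ], seqs[j, ])[["diff"]])
  d
}

#' Minimum spanning network of haplotypes
#'
#' Builds the union of all minimum spanning trees of the haplotype mutation
#' distance matrix (epsilon = 0). An edge of weight w is retained exactly
#' when its endpoints lie in different components of the graph restricted to
#' edges of weight strictly less than w (the cycle property), so tied
#' alternative connections are all kept rather than broken arbitrarily.
#'
#' @param ht A \code{haplotype_table}.
#' @return A list of class \code{msn} with \code{graph} (an \pkg{igraph}
#'   object whose edges carry \code{weight} = mutation count and whose nodes
#'   carry \code{freq}), \code{edges} (data frame from, to, mutations) and
#'   \code{distances}.
#' @export
build_msn <- function(ht) {
  d <- haplotype_distances(ht)
  k <- nrow(d)
  edges <- data.frame(from = character(0), to = character(0),
                      mutations = integer(0), stringsAsFactors = FALSE)
  if (k > 1) {
    comp <- seq_len(k)                 # union-find over haplotypes
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    w <- d[upper.tri(d)]
    ord <- order(w)
    for (wval in unique(w[ord])) {
      at <- which(w == wval)
      roots <- cbind(vapply(pairs[at, 1], find, 1L),
                     vapply(pairs[at, 2], find, 1L))
      keep <- roots[, 1] != roots[, 2]
      if (any(keep))
        edges <- rbind(edges, data.frame(
          from = rownames(d)[pairs[at[keep], 1]],
          to = rownames(d)[pairs[at[keep], 2]],
          mutations = as.integer(wval), stringsAsFactors = FALSE))
      for (e in at[keep]) {            # merge after the whole weight class
        r1 <- find(pairs[e, 1]); r2 <- find(pairs[e, 2])
        if (r1 != r2) comp[r2] <- r1
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ht$haplotypes$id,
                          freq = ht$haplotypes$count))
  igraph::E(g)$weight <- edges$mutations
  structure(list(graph = g, edges = edges, distances = d), class = "msn")
}

#' @export
print.msn <- function(x, ...) {
  cat("Minimum spanning network:", nrow(x$distances), "haplotypes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a minimum spanning network
#'
#' @param msn An object from \code{\link{build_msn}}.
#' @param path Output path without extension; writes \code{.tsv} (edge list)
#'   and \code{.graphml}.
#' @return Invisibly, the paths written.
#' @export
write_msn <- function(msn, path) {
  tsv <- paste0(path, ".tsv"); gml <- paste0(path, ".graphml")
  utils::write.table(msn$edges, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  igraph::write_graph(msn$graph, gml, format = "graphml")
  invisible(c(tsv, gml))
}

#' Private haplotype counts
#'
#' A haplotype is private when its population counts are non-zero in exactly
#' one population.
#'
#' @param ht A \code{haplotype_table} built with metadata.
#' @return List with \code{per_population} (named private counts),
#'   \code{n_private}, \code{n_haplotypes} and \code{fraction}.
#' @export
private_haplotypes <- function(ht) {
  if (is.null(ht$pop_counts))
    stop("haplotype table lacks population counts (metadata needed)",
         call. = FALSE)
  pc <- ht$pop_counts
  priv <- rowSums(pc > 0) == 1L
  per_pop <- colSums(pc[priv, , drop = FALSE] > 0)
  list(per_population = per_pop, n_private = sum(priv),
       n_haplotypes = nrow(pc), fraction = mean(priv))
}

#' Flag haplotypes with non-synonymous changes
#'
#' Translates each haplotype and a reference sequence under a chosen genetic
#' code (default: vertebrate mitochondrial) and flags haplotypes in which at
#' least one codon yields a different amino acid than the reference. Codons
#' containing N or a gap in either sequence are skipped.
#'
#' @param ht A \code{haplotype_table}.
#' @param reference Reference coding sequence (character vector of bases or
#'   a single string) aligned to the haplotypes.
#' @param frame_offset Number of bases to skip before the first codon.
#' @param code NCBI genetic code id; \code{"2"} is vertebrate mitochondrial.
#' @return Logical vector named by haplotype id; TRUE = non-synonymous
#'   change present.
#' @export
annotate_nonsynonymous <- function(ht, reference, frame_offset = 0,
                                   code = "2") {
  if (length(reference) == 1L) reference <- strsplit(reference, "")[[1]]
  reference <- toupper(reference)
  gc_table <- Biostrings::getGeneticCode(code)
  translate_codons <- function(bases) {
    bases <- bases[(frame_offset + 1):length(bases)]
    ncod <- length(bases) %/% 3
    codons <- vapply(seq_len(ncod), function(k)
      paste(bases[(3 * k - 2):(3 * k)], collapse = ""), "")
    aa <- rep(NA_character_, ncod)
    clean <- !grepl("[N-]", codons)
    aa[clean] <- unname(gc_table[codons[clean]])
    aa
  }
  ref_aa <- translate_codons(reference)
  if (any(ref_aa == "*" & seq_along(ref_aa) < length(ref_aa), na.rm = TRUE))
    warning("internal stop codon in reference translation", call. = FALSE)
  out <- vapply(seq_len(nrow(ht$sequences)), function(i) {
    aa <- translate_codons(ht$sequences[i, ])
    ok <- !is.na(aa) & !is.na(ref_aa)
    any(aa[ok] != ref_aa[ok])
  }, logical(1))
  names(out) <- ht$haplotypes$id
  out
}

#' Per-stratum mtDNA summary
#'
#' Computes segregating sites, nucleotide diversity, Tajima's D and
#' haplotype counts for the whole alignment and within each stratum (e.g.
#' population or biome).
#'
#' @param aln Character alignment matrix.
#' @param strata Named character vector (names = sample ids) or a vector
#'   aligned with the rows, giving the stratum of each sequence.
#' @return Data frame with one row per stratum plus an "overall" row:
#'   n, S, pi, tajimas_D (NA where undefined), n_haplotypes.
#' @export
mtdna_summary <- function(aln, strata = NULL) {
  one <- function(sub, label) {
    S <- if (nrow(sub) >= 2) segregating_sites(sub) else NA_integer_
    pi <- if (nrow(sub) >= 2) nucleotide_diversity(sub) else NA_real_
    D <- tryCatch(tajimas_d(sub)$D, error = function(e) NA_real_)
    nh <- nrow(collapse_haplotypes(sub)$haplotypes)
    data.frame(stratum = label, n = nrow(sub), S = S, pi = pi,
               tajimas_D = D, n_haplotypes = nh, stringsAsFactors = FALSE)
  }
  out <- one(aln, "overall")
  if (!is.null(strata)) {
    if (!is.null(names(strata))) strata <- strata[rownames(aln)]
    for (s in unique(strata))
      out <- rbind(out, one(aln[strata == s, , drop = FALSE], s))
  }
  rownames(out) <- NULL
  out
}
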