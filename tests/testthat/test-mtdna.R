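test_that("haplotype collapsing matches exact deduplication", {
  base <- random_alignment(1, 50, seed = 11)[1, ]
  pat2 <- base; pat2[c(5, 9)] <- c("T", "G")
  pat3 <- base; pat3[20] <- "C"
  aln <- rbind(base, pat2, base, pat3, pat2, base, pat3, base)
  rownames(aln) <- paste0("s", 1:8)
  md <- data.frame(sample = paste0("s", 1:8),
                   population = rep(c("north", "south"), each = 4),
                   colony = "c1", latitude = 0, longitude = 0)
  ht <- collapse_haplotypes(aln, md)
  # oracle: exact string dedup
  strings <- apply(aln, 1, paste, collapse = "")
  expect_equal(nrow(ht$haplotypes), length(unique(strings)))
  expect_equal(sum(ht$haplotypes$count), 8L)
  # first-occurrence numbering: H1 is the first row's haplotype
  expect_equal(ht$assignment[1], "H1")
  expect_equal(as.integer(table(strings)[apply(ht$sequences, 1, paste,
                                               collapse = "")]),
               ht$haplotypes$count)
  # collapse -> expand round trip recovers the input multiset
  expanded <- sort(unlist(ht$members, use.names = FALSE))
  expect_identical(expanded, sort(rownames(aln)))
  # 4 identical sequences collapse to one haplotype
  same <- aln[c(1, 3, 6, 8), ]
  expect_equal(nrow(collapse_haplotypes(same)$haplotypes), 1L)
  expect_error(collapse_haplotypes(aln[0, , drop = FALSE]), "empty")
})

test_that("missing sites are excluded pairwise when collapsing", {
  a <- c("A", "C", "G", "T")
  b <- c("A", "N", "G", "T")     # identical to a over comparable sites
  c2 <- c("A", "G", "G", "T")    # differs from a at site 2
  aln <- rbind(a, b, c2)
  rownames(aln) <- c("x", "y", "z")
  ht <- collapse_haplotypes(aln)
  expect_equal(unname(ht$assignment), c("H1", "H1", "H2"))
  # complete deletion drops the ambiguous column: all three merge
  ht2 <- collapse_haplotypes(aln, deletion = "complete")
  expect_equal(nrow(ht2$haplotypes), 1L)
})

test_that("segregating sites equal a per-column scan", {
  aln <- random_alignment(6, 40, seed = 3, bases = c("A", "C"))
  oracle <- sum(vapply(seq_len(ncol(aln)), function(j)
    length(unique(aln[, j])) > 1, logical(1)))
  expect_equal(segregating_sites(aln), oracle)
  expect_equal(segregating_sites(rbind(aln[1, ], aln[1, ])), 0L)
  one <- rbind(aln[1, ], aln[1, ]); one[2, 7] <- setdiff(c("A", "C"),
                                                         one[1, 7])
  expect_equal(segregating_sites(one), 1L)
})

test_that("nucleotide diversity equals the all-pairs brute force", {
  a <- random_alignment(2, 10, seed = 4, bases = c("A", "G"))
  a[2, ] <- a[1, ]; a[2, c(3, 8)] <- ifelse(a[1, c(3, 8)] == "A", "G", "A")
  expect_equal(nucleotide_diversity(a), 0.2)
  aln <- random_alignment(5, 30, seed = 5)
  pairs <- combn(5, 2)
  oracle <- mean(apply(pairs, 2, function(ij)
    sum(aln[ij[1], ] != aln[ij[2], ]) / ncol(aln)))
  expect_equal(nucleotide_diversity(aln), oracle, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(aln[c(1, 1), ]), 0)
  expect_error(nucleotide_diversity(aln[1, , drop = FALSE]), "at least 2")
  # pi is bounded by S over the alignment length
  expect_lte(nucleotide_diversity(aln), segregating_sites(aln) / ncol(aln))
  # invariant under sequence reordering
  expect_equal(nucleotide_diversity(aln[5:1, ]), nucleotide_diversity(aln))
})

test_that("Tajima's D matches an independent coefficient-chain evaluation", {
  # three singleton sites in distinct sequences of four: negative D
  aln <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  aln[1, 1] <- "C"; aln[2, 2] <- "C"; aln[3, 3] <- "C"
  res <- tajimas_d(aln)
  expect_lt(res$D, 0)
  khat <- mean(apply(combn(4, 2), 2, function(ij)
    sum(aln[ij[1], ] != aln[ij[2], ])))
  expect_equal(res$D, taj_oracle(4, 3, khat), tolerance = 1e-12)
  # balanced two-haplotype classes: intermediate frequencies, positive D
  bal <- matrix("A", 6, 12, dimnames = list(paste0("s", 1:6), NULL))
  bal[4:6, 1:4] <- "T"
  res2 <- tajimas_d(bal)
  expect_gt(res2$D, 0)
  khat2 <- mean(apply(combn(6, 2), 2, function(ij)
    sum(bal[ij[1], ] != bal[ij[2], ])))
  expect_equal(res2$D, taj_oracle(6, 4, khat2), tolerance = 1e-12)
  expect_error(tajimas_d(matrix("A", 4, 10)), "undefined")
})

test_that("the MSN is the union of all minimum spanning trees", {
  # deterministic toys
  mk_ht <- function(seqs) {
    aln <- do.call(rbind, seqs)
    rownames(aln) <- paste0("s", seq_along(seqs))
    collapse_haplotypes(aln)
  }
  # two haplotypes at distance k: one edge of weight k
  h <- mk_ht(list(c("A", "A", "A"), c("C", "C", "A")))
  net <- build_msn(h)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$mutations, 2L)
  # chain: d(A,B)=1, d(B,C)=1, d(A,C)=2 -> path, no shortcut
  h2 <- mk_ht(list(c("A", "A"), c("C", "A"), c("C", "C")))
  net2 <- build_msn(h2)
  expect_equal(nrow(net2$edges), 2L)
  expect_false(any(net2$edges$from == "H1" & net2$edges$to == "H3"))
  # mutual ties: three haplotypes pairwise at distance 1 -> triangle kept
  h3 <- mk_ht(list("A", "C", "G"))
  expect_equal(nrow(build_msn(h3)$edges), 3L)
  # random alignments vs exhaustive MST enumeration (<= 6 haplotypes)
  for (seed in 1:5) {
    aln <- random_alignment(6, 15, seed = seed, bases = c("A", "C", "G"))
    ht <- collapse_haplotypes(aln)
    net <- build_msn(ht)
    oracle <- msn_oracle(net$distances)
    got <- cbind(match(net$edges$from, ht$haplotypes$id),
                 match(net$edges$to, ht$haplotypes$id))
    expect_equal(sort_edges(got), sort_edges(oracle), ignore_attr = TRUE)
  }
})

test_that("private haplotype fractions match a direct scan", {
  pc <- rbind(H1 = c(3, 0, 0), H2 = c(0, 2, 0), H3 = c(1, 1, 0),
              H4 = c(0, 0, 2))
  colnames(pc) <- c("a", "b", "c")
  ht <- structure(list(pop_counts = pc), class = "haplotype_table")
  pr <- private_haplotypes(ht)
  expect_equal(pr$fraction, 0.75)
  expect_equal(pr$n_private, 3L)
  expect_equal(unname(pr$per_population), c(1, 1, 1))
  # all confined to one population each
  pc2 <- diag(3); rownames(pc2) <- paste0("H", 1:3)
  colnames(pc2) <- letters[1:3]
  ht2 <- structure(list(pop_counts = pc2), class = "haplotype_table")
  expect_equal(private_haplotypes(ht2)$fraction, 1)
})

test_that("non-synonymous annotation uses the vertebrate mitochondrial code", {
  ref <- c("G", "C", "T", "A", "G", "A", "A", "T", "G")  # Ala, Stop, Met
  mk <- function(...) {
    seqs <- list(...)
    aln <- do.call(rbind, seqs)
    rownames(aln) <- paste0("s", seq_along(seqs))
    collapse_haplotypes(aln)
  }
  same <- ref
  syn3 <- ref; syn3[3] <- "C"              # GCT -> GCC, still Ala
  stp <- ref; stp[6] <- "G"                # AGA -> AGG, both Stop (mt code)
  nonsyn <- ref; nonsyn[1] <- "C"          # GCT -> CCT, Ala -> Pro
  # N codon skipped; ATG -> ATA is Met -> Met under the mitochondrial code
  ambig <- ref; ambig[2] <- "N"; ambig[9] <- "A"
  ht <- mk(same, syn3, stp, nonsyn, ambig)
  flags <- suppressWarnings(annotate_nonsynonymous(ht, ref))
  expect_identical(unname(flags), c(FALSE, FALSE, FALSE, TRUE, FALSE))
})

test_that("per-stratum summaries cover overall and group rows", {
  aln <- random_alignment(8, 60, seed = 12, bases = c("A", "T"))
  strata <- setNames(rep(c("arid", "mesic"), each = 4), rownames(aln))
  tab <- mtdna_summary(aln, strata)
  expect_equal(tab$stratum, c("overall", "arid", "mesic"))
  expect_equal(tab$n, c(8, 4, 4))
  expect_equal(tab$S[1], segregating_sites(aln))
  expect_equal(tab$pi[2],
               nucleotide_diversity(aln[1:4, ]), tolerance = 1e-12)
})
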