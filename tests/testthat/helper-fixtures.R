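# Shared fixture builders; everything is generated in code at test time.

# Minimal genotype_data constructed directly (bypasses the VCF reader).
toy_genotype_data <- function(dosage, dp = NULL, gq = NULL, locus = NULL,
                              pos = NULL, metadata = NULL) {
  n <- nrow(dosage); L <- ncol(dosage)
  if (is.null(rownames(dosage))) rownames(dosage) <- paste0("s", seq_len(n))
  if (is.null(dp)) dp <- matrix(10, n, L)
  if (is.null(gq)) gq <- matrix(99, n, L)
  if (is.null(locus)) locus <- paste0("uce-", seq_len(L))
  if (is.null(pos)) pos <- rep(100L, L)
  structure(list(dosage = dosage, dp = dp, gq = gq,
                 variants = data.frame(locus = locus, pos = pos,
                                       ref = "A", alt = "G",
                                       stringsAsFactors = FALSE),
                 metadata = metadata),
            class = "genotype_data")
}

# Small flat design (no colony substructure, no sibs) for estimator tests.
flat_design <- function(n_pops, n_per_pop, n_loci, f_pop,
                        ai = seq(0.05, 0.8, length.out = n_pops)) {
  sites <- data.frame(site = paste0("P", seq_len(n_pops)),
                      latitude = -30 - seq_len(n_pops),
                      longitude = 18 + 0.5 * seq_len(n_pops),
                      target_ai = ai,
                      n_individuals = rep(as.integer(n_per_pop), n_pops),
                      n_colonies = rep(1L, n_pops),
                      stringsAsFactors = FALSE)
  list(sites = sites, n_loci = n_loci, f_pop = f_pop, f_col = 0,
       sib_fraction = 0, missing_rate = 0)
}

random_alignment <- function(n, len, seed, bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  aln <- matrix(sample(bases, n * len, replace = TRUE), n, len)
  rownames(aln) <- paste0("seq", seq_len(n))
  aln
}
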