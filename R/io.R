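#' Read an aligned FASTA file
#'
#' Reads a FASTA alignment into a character matrix (samples x sites),
#' uppercased, with sequence ids as row names. All sequences must share one
#' length; allowed symbols are A, C, G, T, N and the gap character '-'.
#'
#' @param path FASTA file path.
#' @return Character matrix with one row per sequence.
#' @export
read_fasta_alignment <- function(path) {
  seqs <- ape::read.FASTA(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  chr <- lapply(as.character(seqs), function(s) toupper(s))
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L)
    stop("FASTA sequences have unequal lengths (", paste(unique(lens),
         collapse = ", "), "): not an alignment", call. = FALSE)
  aln <- do.call(rbind, chr)
  rownames(aln) <- names(seqs)
  bad <- setdiff(unique(as.vector(aln)), c("A", "C", "G", "T", "N", "-", "?"))
  if (length(bad))
    stop("unexpected alignment symbols: ", paste(bad, collapse = " "),
         call. = FALSE)
  aln[aln == "?"] <- "N"
  aln
}

#' Write an alignment matrix as FASTA
#'
#' @param aln Character matrix as returned by
#'   \code{\link{read_fasta_alignment}}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta_alignment <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expected columns: sample, population, colony, latitude, longitude.
#' Sample ids must be unique and each sample belongs to exactly one
#' population and colony.
#'
#' @param path CSV/TSV path.
#' @param sep Field separator.
#' @return Data frame of metadata.
#' @export
read_sample_metadata <- function(path, sep = ",") {
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("sample", "population", "colony", "latitude", "longitude")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  if (anyDuplicated(md$sample))
    stop("duplicate sample ids in metadata", call. = FALSE)
  if (any(is.na(md$population)) || any(is.na(md$colony)))
    stop("every sample needs a population and a colony", call. = FALSE)
  md
}

#' Read a VCF into a dosage genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) carrying GT and, optionally, DP
#' and GQ per-sample fields. Genotypes are coded as alternate-allele dosage
#' 0/1/2 (phase ignored; heterozygotes are 1); missing genotypes are NA.
#' Multi-allelic sites are dropped with a message. Locus ids are taken from
#' the CHROM column (one locus may carry several SNPs until pruning).
#'
#' @param path VCF file path.
#' @param metadata Optional metadata data frame (see
#'   \code{\link{read_sample_metadata}}); every VCF sample must appear in it.
#' @return A list of class \code{genotype_data} with elements
#'   \code{dosage} (samples x variants integer matrix), \code{dp} and
#'   \code{gq} (same shape, NA when absent), \code{variants} (data frame
#'   with locus, pos, ref, alt) and \code{metadata}.
#' @export
read_vcf_genotypes <- function(path, metadata = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!"GT" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID &&
      !grepl("GT", v@gt[1, "FORMAT"]))
    stop("VCF lacks the GT FORMAT field", call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  gq <- tryCatch(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE),
                 error = function(e) NULL)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    message("dropping ", sum(multi), " multi-allelic site(s)")
    gt <- gt[!multi, , drop = FALSE]
    if (!is.null(dp)) dp <- dp[!multi, , drop = FALSE]
    if (!is.null(gq)) gq <- gq[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
  }
  dose <- gt_to_dosage(gt)
  samples <- colnames(dose)
  if (!is.null(metadata)) {
    missing_md <- setdiff(samples, metadata$sample)
    if (length(missing_md))
      stop("VCF samples absent from metadata: ",
           paste(missing_md, collapse = ", "), call. = FALSE)
    metadata <- metadata[match(samples, metadata$sample), , drop = FALSE]
  }
  variants <- data.frame(locus = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  na_mat <- function(m) if (is.null(m)) matrix(NA_real_, nrow(variants),
                                               length(samples)) else m
  structure(list(dosage = t(dose),
                 dp = t(na_mat(dp)), gq = t(na_mat(gq)),
                 variants = variants, metadata = metadata),
            class = "genotype_data")
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("Genotype data:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants across", length(unique(x$variants$locus)), "loci\n")
  invisible(x)
}

#' Filter genotypes and variants on depth, quality and completeness
#'
#' Individual genotype calls failing the depth bounds or the genotype-quality
#' minimum are masked to missing; variants are then retained only if the
#' fraction of non-missing genotypes is at least \code{completeness}. The
#' operation is total (never errors) and idempotent.
#'
#' @param gd A \code{genotype_data} object.
#' @param min_dp,max_dp Genotype depth bounds (inclusive). Calls with NA
#'   depth are kept (no depth information available).
#' @param min_gq Minimum genotype quality; NA quality is kept.
#' @param completeness Minimum fraction of called samples per variant.
#' @return A filtered \code{genotype_data}; attributes
#'   \code{masked_genotypes} and \code{dropped_variants} record counts.
#' @export
filter_variants <- function(gd, min_dp = 5, max_dp = 15, min_gq = 20,
                            completeness = 0.8) {
  stopifnot(inherits(gd, "genotype_data"))
  dose <- gd$dosage
  bad_dp <- !is.na(gd$dp) & (gd$dp < min_dp | gd$dp > max_dp)
  bad_gq <- !is.na(gd$gq) & gd$gq < min_gq
  mask <- (bad_dp | bad_gq) & !is.na(dose)
  dose[mask] <- NA_integer_
  called <- colMeans(!is.na(dose))
  keep <- called >= completeness
  message(sum(mask), " genotype call(s) masked; ", sum(!keep),
          " variant(s) dropped below ", completeness, " completeness")
  out <- gd
  out$dosage <- dose[, keep, drop = FALSE]
  out$dp <- gd$dp[, keep, drop = FALSE]
  out$gq <- gd$gq[, keep, drop = FALSE]
  out$variants <- gd$variants[keep, , drop = FALSE]
  attr(out, "masked_genotypes") <- sum(mask)
  attr(out, "dropped_variants") <- sum(!keep)
  out
}

#' Prune to one SNP per locus
#'
#' Retains a single variant per locus id (for UCE data, one SNP per locus)
#' to avoid strong linkage between SNPs from the same locus.
#'
#' @param gd A \code{genotype_data} object.
#' @param mode \code{"first"} keeps the lowest-position SNP (deterministic
#'   default); \code{"random"} draws one uniformly per locus.
#' @param seed Integer seed, required for \code{mode = "random"}.
#' @return A pruned \code{genotype_data} with one variant per locus.
#' @export
prune_one_snp_per_locus <- function(gd, mode = c("first", "random"),
                                    seed = NULL) {
  stopifnot(inherits(gd, "genotype_data"))
  mode <- match.arg(mode)
  locus <- gd$variants$locus
  if (any(is.na(locus) | locus == ""))
    stop("variants lack locus annotations", call. = FALSE)
  idx <- seq_along(locus)
  if (mode == "first") {
    ord <- order(locus, gd$variants$pos)
    keep <- tapply(idx[ord], locus[ord], `[`, 1L)
  } else {
    if (is.null(seed)) stop("`seed` is required for mode = \"random\"",
                            call. = FALSE)
    keep <- with_seed(seed, vapply(split(idx, locus), function(ii)
      if (length(ii) == 1L) ii else sample(ii, 1L), integer(1)))
  }
  keep <- sort(as.integer(keep))
  out <- gd
  out$dosage <- gd$dosage[, keep, drop = FALSE]
  out$dp <- gd$dp[, keep, drop = FALSE]
  out$gq <- gd$gq[, keep, drop = FALSE]
  out$variants <- gd$variants[keep, , drop = FALSE]
  out
}

#' Write a genotype dosage matrix as TSV
#'
#' @param gd A \code{genotype_data} object.
#' @param path Output TSV path (samples in rows, variants in columns).
#' @return Invisibly, \code{path}.
#' @export
write_genotype_tsv <- function(gd, path) {
  m <- gd$dosage
  colnames(m) <- paste(gd$variants$locus, gd$variants$pos, sep = ":")
  utils::write.table(data.frame(sample = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype dosage TSV written by \code{\link{write_genotype_tsv}}
#'
#' @param path TSV path.
#' @param metadata Optional metadata data frame.
#' @return A \code{genotype_data} object (DP/GQ fields are NA).
#' @export
read_genotype_tsv <- function(path, metadata = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab$sample
  ids <- strsplit(colnames(m), ":", fixed = TRUE)
  variants <- data.frame(locus = vapply(ids, `[`, "", 1L),
                         pos = as.integer(vapply(ids, `[`, "", 2L)),
                         ref = NA_character_, alt = NA_character_,
                         stringsAsFactors = FALSE)
  if (!is.null(metadata))
    metadata <- metadata[match(rownames(m), metadata$sample), , drop = FALSE]
  structure(list(dosage = m,
                 dp = matrix(NA_real_, nrow(m), ncol(m)),
                 gq = matrix(NA_real_, nrow(m), ncol(m)),
                 variants = variants, metadata = metadata),
            class = "genotype_data")
}
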