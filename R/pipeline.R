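# Configuration-driven orchestration of the full analysis, with stage
# isolation, seeded reproducibility and report tables written as TSV/JSON.

#' Default run configuration
#'
#' @param out_dir Output directory for report tables.
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param inputs Named list of input paths (\code{vcf}, \code{fasta},
#'   \code{metadata}, \code{climate}); NULL entries switch the stage to the
#'   built-in synthetic fixture.
#' @param n_perm Permutation count used by the AMOVA, Fst and diversity
#'   tests.
#' @param K_values Admixture K grid.
#' @param n_rep Admixture replicates per K.
#' @return Configuration list for \code{\link{run_full_analysis}}.
#' @export
default_config <- function(out_dir = tempfile("aridgen_run_"), seed = 1,
                           inputs = list(vcf = NULL, fasta = NULL,
                                         metadata = NULL, climate = NULL),
                           n_perm = 199, K_values = 1:5, n_rep = 3) {
  list(out_dir = out_dir, seed = seed, inputs = inputs, n_perm = n_perm,
       K_values = K_values, n_rep = n_rep,
       filter = list(min_dp = 5, max_dp = 15, min_gq = 20,
                     completeness = 0.8),
       thresholds = as.list(aridity_thresholds()),
       design = synthetic_design())
}

#' Validate a run configuration
#'
#' Schema check (unknown and missing fields), seed completeness, and
#' threshold sanity.
#'
#' @param config Configuration list, or path to a JSON file holding one.
#' @return Invisibly TRUE; stops with an informative message otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(c("out_dir", "seed"), names(config))
  if (length(missing))
    stop("missing config field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(config$seed) || !is.finite(config$seed))
    stop("config$seed must be a finite number (every stochastic stage",
         " is seeded)", call. = FALSE)
  if (!is.null(config$filter)) {
    f <- config$filter
    if (f$min_dp > f$max_dp) stop("filter: min_dp > max_dp", call. = FALSE)
    if (f$completeness < 0 || f$completeness > 1)
      stop("filter: completeness must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(config$thresholds))
    aridity_thresholds(config$thresholds$arid, config$thresholds$semi_arid)
  invisible(TRUE)
}

run_stage <- function(bundle, name, fun) {
  t0 <- Sys.time()
  res <- tryCatch(fun(), error = function(e) e)
  ok <- !inherits(res, "error")
  bundle$log[[name]] <- list(
    status = if (ok) "ok" else "failed",
    message = if (ok) NULL else conditionMessage(res),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(sprintf("[%s] %s (%.1fs)", name,
                  bundle$log[[name]]$status, bundle$log[[name]]$seconds))
  if (ok) bundle[[name]] <- res
  bundle
}

#' Run the full analysis
#'
#' Executes aridity -> data input/filtering -> mtDNA haplotypes (+ AMOVA)
#' -> SNP diversity -> differentiation and isolation models (+ AMOVA) ->
#' clustering, on either the configured input files or the built-in
#' synthetic fixture. A failing stage is recorded and downstream stages
#' that depend on it are skipped; independent stages still run. Report
#' tables are written under \code{config$out_dir}.
#'
#' @param config Configuration list (see \code{\link{default_config}}).
#' @return A report bundle (list) with one element per stage plus a
#'   \code{log} of stage status and timing; written to disk as TSV/JSON.
#' @export
run_full_analysis <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(config$seed, 8, salt = 1L)
  synthetic <- is.null(config$inputs$vcf)
  fixture_dir <- NULL
  if (synthetic) {
    fixture_dir <- file.path(config$out_dir, "fixture")
    paths <- make_fixture(fixture_dir, seed = seeds[1],
                          design = config$design)
    config$inputs <- as.list(paths[c("vcf", "fasta", "metadata", "climate")])
  }
  bundle <- list(log = list(), config = config)

  bundle <- run_stage(bundle, "aridity", function() {
    series <- read_climate_table(config$inputs$climate)
    tab <- aridity_table(series,
                         thresholds = aridity_thresholds(
                           config$thresholds$arid,
                           config$thresholds$semi_arid))
    write_aridity_table(tab, file.path(config$out_dir, "aridity"))
    tab
  })

  bundle <- run_stage(bundle, "genotypes", function() {
    md <- read_sample_metadata(config$inputs$metadata)
    gd <- read_vcf_genotypes(config$inputs$vcf, md)
    gd <- filter_variants(gd, config$filter$min_dp, config$filter$max_dp,
                          config$filter$min_gq, config$filter$completeness)
    prune_one_snp_per_locus(gd)
  })

  bundle <- run_stage(bundle, "mtdna", function() {
    if (is.null(config$inputs$fasta)) stop("no mtDNA input configured")
    aln <- read_fasta_alignment(config$inputs$fasta)
    md <- read_sample_metadata(config$inputs$metadata)
    ht <- collapse_haplotypes(aln, md)
    msn <- build_msn(ht)
    write_msn(msn, file.path(config$out_dir, "msn"))
    pops <- md$population[match(rownames(aln), md$sample)]
    summary_tab <- mtdna_summary(aln, setNames(pops, rownames(aln)))
    utils::write.table(summary_tab,
                       file.path(config$out_dir, "mtdna_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    amova <- NULL
    if (!is.null(bundle$aridity)) {
      biome <- bundle$aridity$class[match(pops, bundle$aridity$site)]
      hier <- data.frame(sample = rownames(aln), biome = biome,
                         population = pops, stringsAsFactors = FALSE)
      amova <- tryCatch(nested_amova(
        alignment_distance(aln), hier, c("biome", "population"),
        n_perm = config$n_perm, seed = seeds[2]),
        error = function(e) NULL)
      if (!is.null(amova))
        write_amova(amova, file.path(config$out_dir, "mtdna_amova"))
    }
    list(haplotypes = ht, msn = msn, summary = summary_tab,
         private = private_haplotypes(ht), amova = amova)
  })

  if (!is.null(bundle$genotypes)) {
    gd <- bundle$genotypes
    md <- gd$metadata
    pop <- md$population

    bundle <- run_stage(bundle, "diversity", function() {
      panel <- diversity_panel(gd, n_perm = config$n_perm, seed = seeds[3])
      write_diversity_panel(panel, file.path(config$out_dir, "diversity"))
      panel
    })

    bundle <- run_stage(bundle, "snp_amova", function() {
      hier <- data.frame(sample = md$sample, population = pop,
                         colony = md$colony, stringsAsFactors = FALSE)
      res <- nested_amova(dosage_distance(gd$dosage), hier,
                          c("population", "colony"), squared = TRUE,
                          n_perm = config$n_perm, seed = seeds[4])
      write_amova(res, file.path(config$out_dir, "snp_amova"))
      res
    })

    bundle <- run_stage(bundle, "differentiation", function() {
      fst <- fst_permutation(gd$dosage, pop, n_perm = config$n_perm,
                             seed = seeds[5])
      pw <- pairwise_fst(gd$dosage, pop)
      utils::write.table(pw, file.path(config$out_dir, "pairwise_fst.tsv"),
                         sep = "\t", quote = FALSE)
      iso <- NULL; gradient <- NULL
      if (!is.null(bundle$aridity)) {
        ai <- setNames(bundle$aridity$AI, bundle$aridity$site)[rownames(pw)]
        if (nrow(pw) >= 4) {
          sites <- stats::aggregate(cbind(latitude, longitude) ~ population,
                                    data = md, FUN = mean)
          names(sites)[1] <- "site"
          sites <- sites[match(rownames(pw), sites$site), ]
          iso <- isolation_models(pw, geographic_distance_matrix(sites),
                                  environmental_distance_matrix(ai),
                                  n_perm = config$n_perm, seed = seeds[6])
        }
        if (!is.null(bundle$diversity))
          gradient <- fit_diversity_gradient(bundle$diversity, ai)
      }
      list(global_fst = fst$fst, fst_p = fst$p, pairwise = pw,
           isolation = iso, gradient = gradient)
    })

    bundle <- run_stage(bundle, "clustering", function() {
      pca <- genotype_pca(gd$dosage, n_axes = 5)
      grid <- admixture_grid(gd$dosage, config$K_values,
                             n_rep = config$n_rep, seed = seeds[7])
      evanno <- evanno_select(grid$loglik)
      dapc <- dapc_clusters(gd$dosage,
                            K_range = seq_len(min(max(config$K_values),
                                                  nrow(gd$dosage) - 1)),
                            seed = seeds[8])
      sp <- spca(gd$dosage, md[, c("longitude", "latitude")],
                 n_perm = config$n_perm, seed = seeds[8])
      utils::write.table(
        data.frame(sample = rownames(pca$scores), pca$scores),
        file.path(config$out_dir, "pca_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(evanno$table,
                         file.path(config$out_dir, "evanno.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(pca = pca, evanno = evanno, admixture = grid, dapc = dapc,
           spca = sp)
    })
  }

  bundle$provenance <- list(seed = config$seed, seeds = seeds,
                            synthetic_fixture = synthetic,
                            timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(
    list(log = bundle$log, provenance = bundle$provenance),
    file.path(config$out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report bundle. Stages:\n")
  for (nm in names(x$log))
    cat(sprintf("  %-16s %s\n", nm, x$log[[nm]]$status))
  invisible(x)
}
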