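# Synthetic-data generators with known ground truth: hierarchically
# structured genotypes (Balding-Nichols), haplotype-tree mtDNA alignments,
# sinusoidal monthly climate series, and gradient-coupled genetic distances.
# All generators are pure functions of (configuration, seed).

#' Default synthetic study design
#'
#' Mirrors a five-site aridity transect: 39 diploid individuals across five
#' populations (8, 10, 7, 7, 7 individuals from 7, 6, 6, 6, 4 colonies),
#' 3,540 biallelic loci, site coordinates along a roughly 500-km
#' north-south coastal gradient and target Aridity Index values spanning
#' 0.04 to 0.86.
#'
#' @param n_loci Number of biallelic loci.
#' @param f_pop Balding-Nichols differentiation among populations.
#' @param f_col Additional differentiation among colonies within
#'   populations.
#' @param sib_fraction Fraction of each colony drawn as full sibs of a
#'   shared parent pair (depresses effective within-colony diversity).
#' @param missing_rate Uniform genotype missingness rate.
#' @return List describing the design (sites data frame with name, lat,
#'   lon, target AI, sample size, colony count; plus the scalar settings).
#' @export
synthetic_design <- function(n_loci = 3540, f_pop = 0.15, f_col = 0.05,
                             sib_fraction = 0.5, missing_rate = 0.02) {
  sites <- data.frame(
    site = c("Steinkopf", "NoHeep", "Klawer", "Darling", "SomersetWest"),
    latitude = c(-29.345, -30.043, -31.701, -33.407, -34.036),
    longitude = c(17.787, 17.959, 18.745, 18.418, 18.799),
    target_ai = c(0.04, 0.07, 0.11, 0.42, 0.86),
    n_individuals = c(8L, 10L, 7L, 7L, 7L),
    n_colonies = c(7L, 6L, 6L, 6L, 4L),
    stringsAsFactors = FALSE)
  list(sites = sites, n_loci = n_loci, f_pop = f_pop, f_col = f_col,
       sib_fraction = sib_fraction, missing_rate = missing_rate)
}

balding_nichols <- function(p, f) {
  if (f <= 0) return(rep(p, length.out = length(p)))
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate hierarchically structured genotypes
#'
#' Ancestral allele frequencies are uniform on (0.1, 0.9); population
#' frequencies follow a Balding-Nichols Beta around the ancestral value with
#' differentiation \code{f_pop}; colony frequencies are nested likewise with
#' \code{f_col}. Within each colony a configurable fraction of individuals
#' are full sibs whose genotypes are Mendelian draws from one shared parent
#' pair; the rest are binomial draws from the colony frequency. Missingness
#' is applied uniformly at random.
#'
#' @param design A list from \code{\link{synthetic_design}} (or the same
#'   shape with other settings).
#' @param seed Integer seed (mandatory).
#' @return A \code{genotype_data} object (DP/GQ fields NA) whose
#'   \code{truth} attribute records the ancestral, population and colony
#'   frequencies and the design.
#' @export
simulate_genotypes <- function(design = synthetic_design(), seed) {
  sites <- design$sites
  if (any(sites$n_individuals < 1))
    stop("each population needs at least one individual", call. = FALSE)
  L <- design$n_loci
  with_seed(seed, {
    p_anc <- stats::runif(L, 0.1, 0.9)
    rows <- list(); meta <- list(); truth_pop <- list()
    for (s in seq_len(nrow(sites))) {
      p_pop <- balding_nichols(p_anc, design$f_pop)
      truth_pop[[sites$site[s]]] <- p_pop
      n_ind <- sites$n_individuals[s]
      n_col <- sites$n_colonies[s]
      colony_of <- sort(rep_len(seq_len(n_col), n_ind))
      for (cc in seq_len(n_col)) {
        members <- which(colony_of == cc)
        if (!length(members)) next
        p_col <- balding_nichols(p_pop, design$f_col)
        n_sib <- round(design$sib_fraction * length(members))
        par1 <- stats::rbinom(L, 2, p_col)
        par2 <- stats::rbinom(L, 2, p_col)
        for (idx in seq_along(members)) {
          g <- if (idx <= n_sib)
            stats::rbinom(L, 1, par1 / 2) + stats::rbinom(L, 1, par2 / 2)
          else stats::rbinom(L, 2, p_col)
          id <- sprintf("%s_c%02d_i%02d", sites$site[s], cc, idx)
          rows[[id]] <- g
          meta[[id]] <- data.frame(
            sample = id, population = sites$site[s],
            colony = sprintf("%s_c%02d", sites$site[s], cc),
            latitude = sites$latitude[s] + cc * 0.002,
            longitude = sites$longitude[s] + cc * 0.002,
            stringsAsFactors = FALSE)
        }
      }
    }
    m <- do.call(rbind, rows)
    if (design$missing_rate > 0) {
      drop <- stats::runif(length(m)) < design$missing_rate
      m[drop] <- NA_integer_
    }
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    variants <- data.frame(locus = sprintf("uce-%04d", seq_len(L)),
                           pos = rep(100L, L),
                           ref = rep("A", L), alt = rep("G", L),
                           stringsAsFactors = FALSE)
    gd <- structure(list(dosage = m,
                         dp = matrix(NA_real_, nrow(m), ncol(m)),
                         gq = matrix(NA_real_, nrow(m), ncol(m)),
                         variants = variants, metadata = metadata),
                    class = "genotype_data")
    attr(gd, "truth") <- list(p_ancestral = p_anc, p_population = truth_pop,
                              design = design, seed = seed)
    gd
  })
}

#' Default haplotype tree specification
#'
#' One root haplotype, a population-ancestor haplotype per site several
#' mutations from the root, and a few private descendants one to two
#' mutations from each ancestor: a topology of population-private clusters.
#'
#' @param sites Character vector of population names.
#' @param n_private Descendant haplotypes per population ancestor.
#' @return Data frame with columns haplotype, parent (NA for the root),
#'   mutations (branch length), population.
#' @export
default_haplotype_tree <- function(sites, n_private = 3) {
  tree <- data.frame(haplotype = "root", parent = NA_character_,
                     mutations = 0L, population = NA_character_,
                     stringsAsFactors = FALSE)
  for (s in seq_along(sites)) {
    anc <- paste0(sites[s], "_anc")
    tree <- rbind(tree, data.frame(haplotype = anc, parent = "root",
                                   mutations = 3L + s, population = sites[s],
                                   stringsAsFactors = FALSE))
    for (h in seq_len(n_private))
      tree <- rbind(tree, data.frame(
        haplotype = paste0(sites[s], "_h", h), parent = anc,
        mutations = 1L + (h %% 2L), population = sites[s],
        stringsAsFactors = FALSE))
  }
  tree
}

#' Simulate an mtDNA alignment from a haplotype tree
#'
#' Mutations on each branch are placed at globally distinct random sites, so
#' the mutational distance between any two haplotypes equals their path
#' length in the tree and the generating tree is recoverable as the minimum
#' spanning network whenever path lengths are unique.
#'
#' @param tree Haplotype tree specification (see
#'   \code{\link{default_haplotype_tree}}).
#' @param samples Data frame with \code{sample} and \code{population};
#'   each sample is assigned a haplotype of its population.
#' @param length Alignment length in bases (must exceed total mutations).
#' @param seed Integer seed.
#' @return List with \code{alignment} (character matrix),
#'   \code{assignment} (haplotype per sample), \code{haplotype_seqs} and
#'   \code{tree}.
#' @export
simulate_mtdna <- function(tree, samples, length = 1140, seed) {
  total_mut <- sum(tree$mutations)
  if (total_mut > length)
    stop("total mutations exceed sequence length", call. = FALSE)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    root_seq <- sample(bases, length, replace = TRUE)
    free_sites <- sample.int(length)     # distinct sites for all branches
    site_cursor <- 0L
    seqs <- list()
    remaining <- tree
    seqs[["root"]] <- root_seq
    done <- "root"
    while (length(done) < nrow(tree)) {
      for (i in seq_len(nrow(tree))) {
        h <- tree$haplotype[i]
        if (h %in% done || !(tree$parent[i] %in% done)) next
        sq <- seqs[[tree$parent[i]]]
        nm <- tree$mutations[i]
        if (nm > 0) {
          at <- free_sites[site_cursor + seq_len(nm)]
          site_cursor <- site_cursor + nm
          for (pos in at)
            sq[pos] <- sample(setdiff(bases, sq[pos]), 1)
        }
        seqs[[h]] <- sq
        done <- c(done, h)
      }
    }
    leaves <- tree$haplotype[!is.na(tree$population)]
    assignment <- vapply(samples$population, function(pp) {
      cand <- leaves[tree$population[match(leaves, tree$haplotype)] == pp]
      sample(cand, 1)
    }, "")
    names(assignment) <- samples$sample
    aln <- do.call(rbind, lapply(assignment, function(h) seqs[[h]]))
    rownames(aln) <- samples$sample
    list(alignment = aln, assignment = assignment,
         haplotype_seqs = seqs, tree = tree)
  })
}

#' Simulate monthly climate series for the design sites
#'
#' Air temperature and dew point follow a sinusoidal seasonal cycle with
#' Gaussian noise; the dew-point depression grows with site aridity.
#' Monthly precipitation is generated as the site's target Aridity Index
#' times the month's realized potential evapotranspiration, with
#' multiplicative log-normal noise, so the realized AI fluctuates around
#' the target.
#'
#' @param design A list from \code{\link{synthetic_design}}.
#' @param years Number of simulated calendar years.
#' @param start_year First calendar year.
#' @param seed Integer seed.
#' @return Named list of \code{\link{climate_series}}, one per site.
#' @export
simulate_climate <- function(design = synthetic_design(), years = 10,
                             start_year = 2011, seed = 1) {
  sites <- design$sites
  with_seed(seed, {
    out <- list()
    for (s in seq_len(nrow(sites))) {
      ai <- sites$target_ai[s]
      # drier sites: hotter summers, larger dew-point depression
      t_mean <- 18 + 4 * (1 - ai)
      dep <- 4 + 10 * exp(-4 * ai)
      rec <- expand.grid(month = 1:12,
                         year = start_year + seq_len(years) - 1)
      phase <- 2 * pi * (rec$month - 1) / 12
      t_air <- t_mean + 6 * cos(phase) + stats::rnorm(nrow(rec), 0, 0.8)
      d2m <- t_air - dep + stats::rnorm(nrow(rec), 0, 0.5)
      rh <- suppressWarnings(relative_humidity(pmin(d2m, t_air), t_air))
      pet <- pet_romanenko(t_air, rh)
      t_p <- ai * pet * exp(stats::rnorm(nrow(rec), -0.02, 0.2))
      out[[sites$site[s]]] <- climate_series(
        sites$site[s],
        data.frame(year = rec$year, month = rec$month, t_air = t_air,
                   t_p = t_p, d2m = pmin(d2m, t_air)))
    }
    out
  })
}

#' Simulate gradient-coupled pairwise genetic distances
#'
#' Pairwise genetic distance between sites is a linear function of the
#' geographic distance (km) and the environmental distance (absolute AI
#' difference) plus Gaussian noise; negative values are clipped at zero.
#' The generating coefficients are stored for recovery tests.
#'
#' @param sites Data frame with site, latitude, longitude and an \code{ai}
#'   (or \code{target_ai}) column.
#' @param intercept,geo_effect,env_effect Generating coefficients
#'   (per km and per AI unit).
#' @param noise_sd Standard deviation of the pair noise.
#' @param seed Integer seed.
#' @return List with \code{genetic}, \code{geographic}, \code{environmental}
#'   distance matrices, \code{pairs} (long-format table) and \code{truth}.
#' @export
simulate_gradient_coupling <- function(sites, intercept = 0.05,
                                       geo_effect = 0, env_effect = 0.2,
                                       noise_sd = 0.01, seed = 1) {
  ai <- if ("ai" %in% names(sites)) sites$ai else sites$target_ai
  names(ai) <- sites$site
  geo <- geographic_distance_matrix(sites)
  env <- environmental_distance_matrix(ai)
  k <- nrow(geo)
  gen <- with_seed(seed, {
    g <- intercept + geo_effect * geo + env_effect * env
    noise <- matrix(0, k, k)
    noise[lower.tri(noise)] <- stats::rnorm(k * (k - 1) / 2, 0, noise_sd)
    g <- g + noise + t(noise)
    diag(g) <- 0
    if (any(g < 0)) {
      message(sum(g < 0), " negative distance(s) clipped at 0")
      g[g < 0] <- 0
    }
    g
  })
  dimnames(gen) <- dimnames(geo)
  ut <- upper.tri(gen)
  pairs <- data.frame(site1 = rownames(gen)[row(gen)[ut]],
                      site2 = colnames(gen)[col(gen)[ut]],
                      km = geo[ut], d_ai = env[ut], genetic = gen[ut])
  list(genetic = gen, geographic = geo, environmental = env, pairs = pairs,
       truth = list(intercept = intercept, geo_effect = geo_effect,
                    env_effect = env_effect, noise_sd = noise_sd,
                    seed = seed))
}

#' Write simulated genotypes as a VCF with synthetic DP and GQ fields
#'
#' Depth and genotype-quality values are drawn around typical filtering
#' thresholds (depth bounds 5-15, quality 20) so that a fraction of calls
#' fails each rule and the filtering path is exercised; the fractions are
#' controlled by \code{fail_dp} and \code{fail_gq}.
#'
#' @param gd A \code{genotype_data} object.
#' @param path Output VCF path.
#' @param seed Integer seed for the DP/GQ draws.
#' @param fail_dp,fail_gq Approximate per-call probabilities of failing the
#'   depth and quality rules.
#' @return Invisibly, \code{path}.
#' @export
write_synthetic_vcf <- function(gd, path, seed = 1, fail_dp = 0.03,
                                fail_gq = 0.02) {
  m <- gd$dosage
  n <- nrow(m); L <- ncol(m)
  with_seed(seed, {
    dp <- matrix(sample(5:15, n * L, replace = TRUE), n, L)
    low <- stats::runif(n * L) < fail_dp / 2
    high <- stats::runif(n * L) < fail_dp / 2
    dp[low] <- sample(1:4, sum(low), replace = TRUE)
    dp[high] <- sample(16:40, sum(high), replace = TRUE)
    gq <- matrix(sample(20:99, n * L, replace = TRUE), n, L)
    bad <- stats::runif(n * L) < fail_gq
    gq[bad] <- sample(2:19, sum(bad), replace = TRUE)
    gt <- matrix("./.", n, L)
    gt[!is.na(m) & m == 0] <- "0/0"
    gt[!is.na(m) & m == 1] <- "0/1"
    gt[!is.na(m) & m == 2] <- "1/1"
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
                 "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(m)),
                       collapse = "\t")), con)
    for (l in seq_len(L)) {
      cells <- paste(gt[, l], dp[, l], gq[, l], sep = ":")
      writeLines(paste(c(gd$variants$locus[l], gd$variants$pos[l], ".",
                         gd$variants$ref[l], gd$variants$alt[l], ".",
                         "PASS", ".", "GT:DP:GQ", cells),
                       collapse = "\t"), con)
    }
  })
  invisible(path)
}

#' Generate the default synthetic study bundle on disk
#'
#' Writes a FASTA mtDNA alignment, a VCF of SNP genotypes (with synthetic
#' DP/GQ), a sample metadata CSV, a monthly climate CSV and a ground-truth
#' JSON into a directory.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param design Study design (see \code{\link{synthetic_design}}).
#' @return Invisibly, a named vector of the files written.
#' @export
make_fixture <- function(dir, seed = 1, design = synthetic_design()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- child_seeds(seed, 4, salt = 9L)
  gd <- simulate_genotypes(design, seed = seeds[1])
  mt <- simulate_mtdna(default_haplotype_tree(design$sites$site),
                       gd$metadata, seed = seeds[2])
  clim <- simulate_climate(design, seed = seeds[3])
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             fasta = file.path(dir, "mtdna.fasta"),
             metadata = file.path(dir, "metadata.csv"),
             climate = file.path(dir, "climate.csv"),
             truth = file.path(dir, "truth.json"))
  write_synthetic_vcf(gd, paths[["vcf"]], seed = seeds[4])
  write_fasta_alignment(mt$alignment, paths[["fasta"]])
  utils::write.csv(gd$metadata, paths[["metadata"]], row.names = FALSE,
                   quote = FALSE)
  clim_tab <- do.call(rbind, lapply(clim, function(s)
    cbind(site = s$site, s$records)))
  utils::write.csv(clim_tab, paths[["climate"]], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(seed = seed,
                            design = design,
                            mtdna_assignment = as.list(mt$assignment)),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
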