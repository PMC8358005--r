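# Seeded simulator of reciprocal-cross F1 allele counts and correlated DE
# tables. Ground truth is returned alongside every fixture so that each
# inference stage can be scored against planted effects.
#
# Model: per SNP per sample, total depth ~ NegBinom(mu = depth_mean,
# size = depth_dispersion); ref depth ~ BetaBinom(total, theta_subgroup, rho)
# with the intra-class-correlation parameterisation
# alpha = theta (1 - rho) / rho, beta = (1 - theta)(1 - rho) / rho;
# rho = 0 degenerates to the plain binomial. Effect classes are assigned at
# the gene level so SNPs within a gene share a signal, as in real data.

#' Simulation configuration for reciprocal-cross allele counts
#'
#' Builds and validates the parameter set for [simulate_allele_counts()].
#' Defaults describe a modest reciprocal-cross RNA-seq experiment: 8 samples
#' per subgroup, mean depth 60 reads per SNP per sample (so subgroup sums are
#' comfortably above the 20-read filter while low-depth SNPs still occur),
#' mild overdispersion (rho = 0.02, typical of well-behaved ASE replicates),
#' and imprinting/cis effect sizes of 0.3/0.2 on the reference fraction.
#'
#' Subgroup A is the cross whose father carries the non-reference (alt)
#' strain genome. A paternally expressed gene therefore shows
#' theta_A = 0.5 - imprint_delta and theta_B = 0.5 + imprint_delta; a
#' maternally expressed gene flips the signs; a cis effect shifts both
#' subgroups identically by +/- cis_delta; mapping_bias is added to every
#' theta before clamping into (0, 1).
#'
#' @param n_genes Number of genes (default 200).
#' @param snps_per_gene_mean Poisson mean SNPs per gene (default 2).
#' @param n_samples_per_subgroup Samples per subgroup (default 8).
#' @param depth_mean Mean total reads per SNP per sample (default 60).
#' @param depth_dispersion Negative-binomial size parameter (default 5).
#' @param overdispersion_rho Beta-binomial intra-class correlation in
#'   [0, 1) (default 0.02).
#' @param frac_imprinted_paternal Proportion of genes paternally expressed
#'   (default 0.05).
#' @param frac_imprinted_maternal Proportion maternally expressed
#'   (default 0.05).
#' @param frac_cis_effect Proportion with a cis strain effect (default 0.1).
#' @param imprint_delta Shift of the true reference fraction per subgroup at
#'   imprinted genes, in (0, 0.5] (default 0.3).
#' @param cis_delta Shared shift at cis genes, in (0, 0.5] (default 0.2).
#' @param mapping_bias Additive shift toward the reference allele applied to
#'   every site, in [-0.2, 0.2] (default 0).
#' @param tissue Tissue label stamped on every record (default "NAcc").
#' @param seed Integer seed; required, no default.
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genes = 200L,
                              snps_per_gene_mean = 2,
                              n_samples_per_subgroup = 8L,
                              depth_mean = 60,
                              depth_dispersion = 5,
                              overdispersion_rho = 0.02,
                              frac_imprinted_paternal = 0.05,
                              frac_imprinted_maternal = 0.05,
                              frac_cis_effect = 0.1,
                              imprint_delta = 0.3,
                              cis_delta = 0.2,
                              mapping_bias = 0,
                              tissue = "NAcc",
                              seed) {
  if (missing(seed)) stop2("simulation_config: 'seed' is required")
  seed <- assert_count(seed, "seed")
  n_genes <- assert_count(n_genes, "n_genes", minimum = 1L)
  assert_scalar_number(snps_per_gene_mean, "snps_per_gene_mean",
                       lower = 0, allow_equal_lower = FALSE)
  n_samples_per_subgroup <- assert_count(n_samples_per_subgroup,
                                         "n_samples_per_subgroup",
                                         minimum = 1L)
  assert_scalar_number(depth_mean, "depth_mean", lower = 0,
                       allow_equal_lower = FALSE)
  assert_scalar_number(depth_dispersion, "depth_dispersion", lower = 0,
                       allow_equal_lower = FALSE)
  assert_scalar_number(overdispersion_rho, "overdispersion_rho",
                       lower = 0, upper = 1, allow_equal_upper = FALSE)
  assert_scalar_number(frac_imprinted_paternal, "frac_imprinted_paternal",
                       lower = 0, upper = 1)
  assert_scalar_number(frac_imprinted_maternal, "frac_imprinted_maternal",
                       lower = 0, upper = 1)
  assert_scalar_number(frac_cis_effect, "frac_cis_effect",
                       lower = 0, upper = 1)
  if (frac_imprinted_paternal + frac_imprinted_maternal + frac_cis_effect > 1)
    stop2("simulation_config: effect-class proportions sum above 1")
  assert_scalar_number(imprint_delta, "imprint_delta", lower = 0, upper = 0.5,
                       allow_equal_lower = FALSE)
  assert_scalar_number(cis_delta, "cis_delta", lower = 0, upper = 0.5,
                       allow_equal_lower = FALSE)
  assert_scalar_number(mapping_bias, "mapping_bias", lower = -0.2,
                       upper = 0.2)
  cfg <- list(n_genes = n_genes,
              snps_per_gene_mean = snps_per_gene_mean,
              n_samples_per_subgroup = n_samples_per_subgroup,
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              overdispersion_rho = overdispersion_rho,
              frac_imprinted_paternal = frac_imprinted_paternal,
              frac_imprinted_maternal = frac_imprinted_maternal,
              frac_cis_effect = frac_cis_effect,
              imprint_delta = imprint_delta,
              cis_delta = cis_delta,
              mapping_bias = mapping_bias,
              tissue = tissue,
              seed = seed)
  class(cfg) <- "simulation_config"
  cfg
}

clamp_unit <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

rbetabinom <- function(n_draws, size, theta, rho) {
  if (rho == 0) return(stats::rbinom(n_draws, size, theta))
  a <- theta * (1 - rho) / rho
  b <- (1 - theta) * (1 - rho) / rho
  p <- stats::rbeta(n_draws, a, b)
  stats::rbinom(n_draws, size, p)
}

#' Simulate reciprocal-cross allele counts with planted effects
#'
#' Generates per-sample allele depth records at heterozygous SNPs for the two
#' reciprocal subgroups, together with a truth table recording each SNP's
#' effect class and true subgroup reference fractions. Gene models (one
#' interval per gene containing its SNPs) are included for SNP-to-gene
#' assignment downstream. Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @return List with elements \code{records} (allele depth table:
#'   snp_id, chrom, pos, ref, alt, sample_id, subgroup, tissue, ref_depth,
#'   alt_depth), \code{truth} (snp_id, gene_id, effect_class,
#'   true_ref_frac_A, true_ref_frac_B), and \code{genes} (gene_id, chrom,
#'   start, end, strand).
#' @export
simulate_allele_counts <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop2("simulate_allele_counts: expected a simulation_config")
  cfg <- config
  set.seed(cfg$seed)

  n_snps_per_gene <- stats::rpois(cfg$n_genes, cfg$snps_per_gene_mean)
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))

  # effect classes at gene level; deterministic counts, shuffled assignment
  n_pat <- round(cfg$frac_imprinted_paternal * cfg$n_genes)
  n_mat <- round(cfg$frac_imprinted_maternal * cfg$n_genes)
  n_cis <- round(cfg$frac_cis_effect * cfg$n_genes)
  classes <- c(rep("imprinted_paternal", n_pat),
               rep("imprinted_maternal", n_mat),
               rep("cis", n_cis),
               rep("null", cfg$n_genes - n_pat - n_mat - n_cis))
  classes <- sample(classes)
  cis_sign <- sample(c(-1, 1), cfg$n_genes, replace = TRUE)

  # lay genes along one chromosome, 10 kb apart, 5 kb bodies
  gene_start <- 1L + (seq_len(cfg$n_genes) - 1L) * 10000L
  gene_end <- gene_start + 4999L
  genes <- data.frame(gene_id = gene_ids, chrom = "chr1",
                      start = gene_start, end = gene_end, strand = "+",
                      stringsAsFactors = FALSE)

  theta_for <- function(class, sgn) {
    # returns c(theta_A, theta_B) before bias/clamp
    switch(class,
           null = c(0.5, 0.5),
           cis = c(0.5 + sgn * cfg$cis_delta, 0.5 + sgn * cfg$cis_delta),
           imprinted_paternal = c(0.5 - cfg$imprint_delta,
                                  0.5 + cfg$imprint_delta),
           imprinted_maternal = c(0.5 + cfg$imprint_delta,
                                  0.5 - cfg$imprint_delta))
  }

  bases <- c("A", "C", "G", "T")
  n_total_snps <- sum(n_snps_per_gene)
  if (n_total_snps == 0L)
    stop2("simulate_allele_counts: no SNPs drawn; increase snps_per_gene_mean")

  snp_gene_idx <- rep(seq_len(cfg$n_genes), n_snps_per_gene)
  snp_within <- sequence(n_snps_per_gene)
  snp_id <- sprintf("%s_snp%d", gene_ids[snp_gene_idx], snp_within)
  pos <- gene_start[snp_gene_idx] + snp_within * 100L
  ref <- sample(bases, n_total_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  theta_mat <- t(vapply(seq_len(n_total_snps), function(i) {
    g <- snp_gene_idx[i]
    theta_for(classes[g], cis_sign[g])
  }, numeric(2)))
  theta_mat <- clamp_unit(theta_mat + cfg$mapping_bias)

  truth <- data.frame(snp_id = snp_id,
                      gene_id = gene_ids[snp_gene_idx],
                      effect_class = classes[snp_gene_idx],
                      true_ref_frac_A = theta_mat[, 1],
                      true_ref_frac_B = theta_mat[, 2],
                      stringsAsFactors = FALSE)

  ns <- cfg$n_samples_per_subgroup
  sample_ids <- c(sprintf("A%02d", seq_len(ns)), sprintf("B%02d", seq_len(ns)))
  subgroups <- rep(c("A", "B"), each = ns)

  rec_list <- vector("list", 2L * ns)
  for (j in seq_along(sample_ids)) {
    total <- stats::rnbinom(n_total_snps, mu = cfg$depth_mean,
                            size = cfg$depth_dispersion)
    theta <- theta_mat[, if (subgroups[j] == "A") 1L else 2L]
    refd <- integer(n_total_snps)
    pos_depth <- total > 0L
    if (any(pos_depth)) {
      if (cfg$overdispersion_rho == 0) {
        refd[pos_depth] <- stats::rbinom(sum(pos_depth), total[pos_depth],
                                         theta[pos_depth])
      } else {
        a <- theta * (1 - cfg$overdispersion_rho) / cfg$overdispersion_rho
        b <- (1 - theta) * (1 - cfg$overdispersion_rho) /
          cfg$overdispersion_rho
        p <- stats::rbeta(n_total_snps, a, b)
        refd[pos_depth] <- stats::rbinom(sum(pos_depth), total[pos_depth],
                                         p[pos_depth])
      }
    }
    rec_list[[j]] <- data.frame(snp_id = snp_id, chrom = "chr1", pos = pos,
                                ref = ref, alt = alt,
                                sample_id = sample_ids[j],
                                subgroup = subgroups[j],
                                tissue = cfg$tissue,
                                ref_depth = refd,
                                alt_depth = as.integer(total - refd),
                                stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec_list)
  records <- records[order(records$snp_id, records$sample_id), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, truth = truth, genes = genes)
}

#' Simulate a pair of correlated differential-expression tables
#'
#' Produces two DE tables whose log2 fold changes over a shared
#' significantly-DE gene subset are drawn from a bivariate normal with the
#' requested Pearson correlation; all other genes' fold changes are
#' independent. Shared genes receive p-values below 0.05 in both tables;
#' other genes' p-values are uniform.
#'
#' @param n_genes Total genes per table (>= 3).
#' @param frac_shared_de Proportion of genes significantly DE in both tables.
#' @param target_correlation Desired Pearson correlation of shared log2FC,
#'   in [-1, 1].
#' @param seed Integer seed.
#' @param labels Character(2) contrast labels (default "X", "Y").
#' @return List with \code{table_x}, \code{table_y} (gene_id, log2FC, pvalue)
#'   and \code{shared_genes}.
#' @export
simulate_de_tables <- function(n_genes, frac_shared_de, target_correlation,
                               seed, labels = c("X", "Y")) {
  n_genes <- assert_count(n_genes, "n_genes", minimum = 3L)
  assert_scalar_number(frac_shared_de, "frac_shared_de", lower = 0, upper = 1)
  assert_scalar_number(target_correlation, "target_correlation",
                       lower = -1, upper = 1)
  seed <- assert_count(seed, "seed")
  set.seed(seed)

  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  n_shared <- round(frac_shared_de * n_genes)
  shared <- if (n_shared > 0) sample(gene_ids, n_shared) else character(0)
  is_shared <- gene_ids %in% shared

  r <- target_correlation
  z1 <- stats::rnorm(n_genes)
  z2 <- stats::rnorm(n_genes)
  fc_x <- numeric(n_genes)
  fc_y <- numeric(n_genes)
  fc_x[is_shared] <- z1[is_shared]
  fc_y[is_shared] <- r * z1[is_shared] + sqrt(1 - r^2) * z2[is_shared]
  fc_x[!is_shared] <- stats::rnorm(sum(!is_shared), sd = 0.3)
  fc_y[!is_shared] <- stats::rnorm(sum(!is_shared), sd = 0.3)

  p_x <- ifelse(is_shared, stats::runif(n_genes, 1e-8, 0.049),
                stats::runif(n_genes, 0.05, 1))
  p_y <- ifelse(is_shared, stats::runif(n_genes, 1e-8, 0.049),
                stats::runif(n_genes, 0.05, 1))

  mk <- function(fc, p, label) {
    tab <- data.frame(gene_id = gene_ids, log2FC = fc, pvalue = p,
                      stringsAsFactors = FALSE)
    attr(tab, "contrast_label") <- label
    tab
  }
  list(table_x = mk(fc_x, p_x, labels[1]),
       table_y = mk(fc_y, p_y, labels[2]),
       shared_genes = sort(shared))
}

#' Write a simulated fixture bundle to disk
#'
#' Emits the allele-count TSV, an equivalent multi-sample VCF v4.2 with
#' per-sample AD fields, the truth table TSV, a BED file of gene models, and
#' (optionally) a pair of DE TSVs. Files round-trip losslessly through the
#' readers in this package.
#'
#' @param sim Output of [simulate_allele_counts()].
#' @param out_dir Output directory (created if needed).
#' @param de Optional output of [simulate_de_tables()].
#' @return Named character vector of file paths.
#' @export
write_fixture_bundle <- function(sim, out_dir, de = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(out_dir, "allele_counts.tsv"),
             vcf = file.path(out_dir, "allele_counts.vcf"),
             truth = file.path(out_dir, "truth.tsv"),
             genes = file.path(out_dir, "genes.bed"))
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_tsv(sim$records, paths[["counts"]])
  write_tsv(sim$truth, paths[["truth"]])
  bed <- data.frame(chrom = sim$genes$chrom,
                    start = sim$genes$start - 1L,
                    end = sim$genes$end,
                    name = sim$genes$gene_id,
                    score = 0L,
                    strand = sim$genes$strand)
  utils::write.table(bed, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_allele_vcf(sim$records, paths[["vcf"]])
  if (!is.null(de)) {
    paths <- c(paths, de_x = file.path(out_dir, "de_x.tsv"),
               de_y = file.path(out_dir, "de_y.tsv"))
    write_tsv(de$table_x, paths[["de_x"]])
    write_tsv(de$table_y, paths[["de_y"]])
  }
  paths
}

# Serialise allele depth records as a minimal multi-sample VCF v4.2 with
# GT:AD per sample. One line per SNP; samples are columns.
write_allele_vcf <- function(records, path) {
  assert_columns(records, c("snp_id", "chrom", "pos", "ref", "alt",
                            "sample_id", "ref_depth", "alt_depth"),
                 "allele depth record table")
  samples <- sort(unique(records$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (!nrow(records)) {
    writeLines(header, path)
    return(invisible(path))
  }
  dt <- data.table::as.data.table(records)
  data.table::setorderv(dt, c("chrom", "pos", "snp_id"))
  site_key <- c("snp_id", "chrom", "pos", "ref", "alt")
  sites <- unique(dt[, site_key, with = FALSE])
  wide <- data.table::dcast(
    dt, snp_id + chrom + pos + ref + alt ~ sample_id,
    value.var = c("ref_depth", "alt_depth"))
  data.table::setorderv(wide, c("chrom", "pos", "snp_id"))
  geno_cols <- lapply(samples, function(s) {
    rd <- wide[[paste0("ref_depth_", s)]]
    ad <- wide[[paste0("alt_depth_", s)]]
    ifelse(is.na(rd) | is.na(ad), "./.:.",
           sprintf("0/1:%d,%d", rd, ad))
  })
  lines <- do.call(paste, c(list(wide$chrom, wide$pos, wide$snp_id,
                                 wide$ref, wide$alt, ".", "PASS", ".",
                                 "GT:AD"),
                            geno_cols, sep = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}
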