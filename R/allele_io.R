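# Readers/writers for the standard formats the pipeline touches (VCF, FASTA,
# GFF3/BED, TSV), reference N-masking, and SNP-to-gene interval assignment.
#
# Coordinates are 1-based inclusive internally (VCF/GFF3 convention); BED is
# converted at the boundary.

#' Read per-sample allele depths from a multi-sample VCF
#'
#' Extracts reference/alternate read depths (the AD genotype field) for every
#' sample at every bi-allelic SNP. Multi-allelic sites and indels are skipped
#' and counted; the skip count is reported via \code{message()} and attached
#' as attribute \code{"n_skipped"}.
#'
#' @param vcf_path Path to a VCF (v4.x) with per-sample AD fields.
#' @param subgroup_map Named character vector mapping sample id to subgroup
#'   \code{"A"} or \code{"B"}. Every sample in the VCF must be present.
#' @param tissue Tissue label stamped on the records.
#' @return Allele depth record data frame (columns snp_id, chrom, pos, ref,
#'   alt, sample_id, subgroup, tissue, ref_depth, alt_depth).
#' @export
read_vcf_allele_depths <- function(vcf_path, subgroup_map, tissue) {
  if (!file.exists(vcf_path)) stop2("VCF not found: ", vcf_path)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  samples <- colnames(vcf)
  unknown <- setdiff(samples, names(subgroup_map))
  if (length(unknown))
    stop2("read_vcf_allele_depths: sample(s) absent from subgroup_map: ",
          paste(unknown, collapse = ", "))
  if (!all(subgroup_map[samples] %in% c("A", "B")))
    stop2("read_vcf_allele_depths: subgroup_map values must be 'A' or 'B'")
  if (!("AD" %in% names(VariantAnnotation::geno(vcf))))
    stop2("read_vcf_allele_depths: VCF has no AD genotype field: ", vcf_path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  alt_chr <- rep(NA_character_, length(ref))
  alt_chr[n_alt == 1L] <- as.character(unlist(alt_list[n_alt == 1L]))
  biallelic_snv <- n_alt == 1L & nchar(ref) == 1L &
    !is.na(alt_chr) & nchar(alt_chr) == 1L & alt_chr %in% c("A", "C", "G", "T")
  n_skipped <- sum(!biallelic_snv)
  if (n_skipped > 0)
    message("read_vcf_allele_depths: skipped ", n_skipped,
            " multi-allelic/indel record(s)")

  keep <- which(biallelic_snv)
  ad <- VariantAnnotation::geno(vcf)$AD  # matrix of integer pairs (list)
  out <- vector("list", length(samples))
  ids <- names(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  # AD comes back as a list-matrix (variable Number=R) or a 3-d array
  # (fixed Number); normalise to a list of per-record vectors
  extract_ad <- function(keep, j) {
    if (length(dim(ad)) == 3L) {
      lapply(keep, function(i) ad[i, j, ])
    } else {
      as.list(ad[keep, j, drop = FALSE])
    }
  }
  for (j in seq_along(samples)) {
    depths <- extract_ad(keep, j)
    rd <- vapply(depths, function(x) {
      if (length(x) < 2L || anyNA(x))
        stop2("read_vcf_allele_depths: missing AD value for sample ",
              samples[j])
      as.integer(x[1L])
    }, integer(1))
    adp <- vapply(depths, function(x) as.integer(x[2L]), integer(1))
    out[[j]] <- data.frame(snp_id = ids[keep], chrom = chrom[keep],
                           pos = pos[keep], ref = ref[keep],
                           alt = alt_chr[keep],
                           sample_id = samples[j],
                           subgroup = unname(subgroup_map[samples[j]]),
                           tissue = tissue,
                           ref_depth = rd, alt_depth = adp,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$snp_id, res$sample_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Read an allele-count TSV
#'
#' Reads the tab-separated allele depth table written by
#' [write_fixture_bundle()] (columns snp_id, chrom, pos, ref, alt, sample_id,
#' subgroup, tissue, ref_depth, alt_depth) and validates it.
#'
#' @param path TSV path.
#' @return Allele depth record data frame.
#' @export
read_allele_counts_tsv <- function(path) {
  if (!file.exists(path)) stop2("allele count TSV not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer",
                                         ref_depth = "integer",
                                         alt_depth = "integer"))
  assert_columns(df, c("snp_id", "chrom", "pos", "ref", "alt", "sample_id",
                       "subgroup", "tissue", "ref_depth", "alt_depth"),
                 path)
  if (nrow(df)) {
    if (any(df$ref_depth < 0 | df$alt_depth < 0))
      stop2(path, ": negative depth")
    if (any(df$pos < 1)) stop2(path, ": position below 1")
    if (any(df$ref == df$alt)) stop2(path, ": ref allele equals alt allele")
  }
  df <- df[order(df$snp_id, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' N-mask SNP positions in a reference FASTA
#'
#' Replaces the base at each given (chrom, pos) with N, leaving every other
#' base, header and sequence order untouched. Masking a masked file again
#' with the same sites is a no-op. Used to mitigate reference-allele mapping
#' bias before re-mapping reads.
#'
#' @param fasta_path Input FASTA.
#' @param sites Data frame with columns \code{chrom} and \code{pos}
#'   (1-based).
#' @param out_path Output FASTA path.
#' @return \code{out_path}, invisibly.
#' @export
mask_reference_fasta <- function(fasta_path, sites, out_path) {
  assert_columns(sites, c("chrom", "pos"), "sites")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # match on the first whitespace-delimited token of each header
  seq_names <- sub("\\s.*$", "", names(seqs))
  bad_chrom <- setdiff(unique(sites$chrom), seq_names)
  if (length(bad_chrom))
    stop2("mask_reference_fasta: chrom not in FASTA: ",
          paste(bad_chrom, collapse = ", "))
  for (chrom in unique(sites$chrom)) {
    i <- match(chrom, seq_names)
    p <- sites$pos[sites$chrom == chrom]
    width <- Biostrings::width(seqs)[i]
    if (any(p < 1 | p > width))
      stop2(sprintf(
        "mask_reference_fasta: position(s) out of bounds on %s (length %d): %s",
        chrom, width, paste(p[p < 1 | p > width], collapse = ", ")))
    at <- rep(FALSE, width)
    at[p] <- TRUE
    seqs[[i]] <- Biostrings::replaceLetterAt(
      seqs[[i]], at, paste(rep("N", sum(at)), collapse = ""))
  }
  Biostrings::writeXStringSet(seqs, out_path, width = 60L)
  invisible(out_path)
}

classify_chrom <- function(chrom, x_label = "X") {
  stripped <- sub("^chr", "", chrom)
  ifelse(stripped == x_label, "X",
         ifelse(stripped == "Y", "Y",
                ifelse(stripped %in% c("M", "MT"), "MT", "autosome")))
}

#' Read gene models from GFF3 or BED
#'
#' Returns a unified 1-based inclusive gene model table. GFF3 is read via
#' rtracklayer (features of type \code{gene}, or all features if none are
#' typed \code{gene}); BED (0-based half-open) is converted on read. The
#' chromosome class (autosome/X/Y/MT) is inferred from the chromosome name,
#' with a configurable X label for genomes that use a different convention.
#'
#' @param path GFF3 (\code{.gff}/\code{.gff3}) or BED (\code{.bed}) file.
#' @param x_label Chromosome name (without "chr" prefix) treated as the X
#'   chromosome (default \code{"X"}).
#' @return Data frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{chromosome_class}.
#' @export
read_gene_models <- function(path, x_label = "X") {
  if (!file.exists(path)) stop2("gene model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(S4Vectors::mcols(gr)$type == "gene"))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    mc <- S4Vectors::mcols(gr)
    gene_id <- if ("gene_id" %in% names(mc) && !all(is.na(mc$gene_id))) {
      as.character(mc$gene_id)
    } else if ("ID" %in% names(mc) && !all(is.na(mc$ID))) {
      as.character(mc$ID)
    } else if ("Name" %in% names(mc)) {
      as.character(mc$Name)
    } else {
      stop2("read_gene_models: no gene_id/ID/Name attribute in ", path)
    }
    df <- data.frame(gene_id = gene_id,
                     chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
    df$strand[df$strand == "*"] <- "."
  } else if (ext == "bed") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 4L))
      stop2("read_gene_models: malformed BED line ",
            which(nf < 4L)[1L], " in ", path,
            " (need at least chrom, start, end, name)")
    start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0))
      stop2("read_gene_models: non-numeric coordinate at BED line ",
            which(is.na(start0) | is.na(end0))[1L], " in ", path)
    strand <- ifelse(nf >= 6L, vapply(fields, function(f)
      if (length(f) >= 6L) f[6L] else ".", ""), ".")
    strand[!strand %in% c("+", "-")] <- "."
    df <- data.frame(gene_id = vapply(fields, `[`, "", 4L),
                     chrom = vapply(fields, `[`, "", 1L),
                     start = start0 + 1L,
                     end = end0,
                     strand = strand,
                     stringsAsFactors = FALSE)
  } else {
    stop2("read_gene_models: unrecognised extension '.", ext,
          "' (expected .gff3/.gff or .bed)")
  }
  if (any(df$start > df$end))
    stop2("read_gene_models: start > end for gene(s) ",
          paste(utils::head(df$gene_id[df$start > df$end], 3),
                collapse = ", "))
  df$chromosome_class <- classify_chrom(df$chrom, x_label)
  rownames(df) <- NULL
  df
}

#' Write gene models as BED
#'
#' Inverse of the BED branch of [read_gene_models()]; 1-based inclusive
#' intervals are converted back to 0-based half-open.
#'
#' @param genes Gene model data frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_models_bed <- function(genes, path) {
  assert_columns(genes, c("gene_id", "chrom", "start", "end"), "gene models")
  strand <- if ("strand" %in% names(genes)) genes$strand else "."
  bed <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                    0L, strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assign SNPs to overlapping gene intervals
#'
#' A SNP is assigned to every gene whose interval, extended by
#' \code{flank_bp} on each side, contains its position (1-based inclusive).
#' Distance is 0 inside the gene body and the bp offset to the nearest body
#' edge within the flank otherwise. SNPs overlapping no interval are absent
#' from the result.
#'
#' @param snps Data frame with columns \code{snp_id}, \code{chrom},
#'   \code{pos} (one row per SNP; duplicates are collapsed).
#' @param gene_models Gene model table from [read_gene_models()].
#' @param flank_bp Non-negative flank in bp (default 0, gene body only).
#' @return Data frame with columns \code{snp_id}, \code{gene_id},
#'   \code{distance}.
#' @export
map_snps_to_genes <- function(snps, gene_models, flank_bp = 0L) {
  assert_columns(snps, c("snp_id", "chrom", "pos"), "SNP table")
  assert_columns(gene_models, c("gene_id", "chrom", "start", "end"),
                 "gene model table")
  flank_bp <- assert_count(flank_bp, "flank_bp")
  snps <- unique(snps[, c("snp_id", "chrom", "pos")])
  empty <- data.frame(snp_id = character(), gene_id = character(),
                      distance = integer(), stringsAsFactors = FALSE)
  if (!nrow(snps) || !nrow(gene_models)) return(empty)
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  gene_gr <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(pmax(1L, gene_models$start - flank_bp),
                     gene_models$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  if (!length(hits)) return(empty)
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  pos <- snps$pos[si]
  dist <- pmax(0L, pmax(gene_models$start[gi] - pos,
                        pos - gene_models$end[gi]))
  out <- data.frame(snp_id = snps$snp_id[si],
                    gene_id = gene_models$gene_id[gi],
                    distance = as.integer(dist),
                    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
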