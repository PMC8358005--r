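# End-to-end orchestration: a single JSON config drives
# extract -> aggregate -> filter -> AIE -> differential AIE -> gene mapping
# -> gene-level verdicts -> enrichment batteries -> DE integration, with a
# provenance manifest. Re-running with identical inputs and seed is
# bit-identical.

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration and collects all schema violations rather than
#' failing on the first. Required: \code{counts} (allele-count TSV) or
#' \code{vcf} plus \code{subgroup_map} and \code{tissue}; \code{out_dir}.
#' Optional: \code{gene_models}, \code{de_tables} (array of
#' \code{{path, label}}), \code{gene_sets}, \code{universe} (one-column TSV
#' of expressed gene ids), \code{thresholds} (\code{fdr}, \code{min_delta},
#' \code{strong_delta}, \code{min_depth}, \code{min_allele_depth},
#' \code{de_p}), \code{flank_bp}, \code{seed}.
#'
#' @param path JSON config path.
#' @return Validated config list of class \code{"pipeline_config"}, or an
#'   error listing every problem found.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop2("config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)

  defaults <- list(fdr = 0.05, min_delta = 0.1, strong_delta = 0.7,
                   min_depth = 20, min_allele_depth = 2, de_p = 0.05)
  thr <- utils::modifyList(defaults, as.list(cfg$thresholds %||% list()))
  for (nm in c("fdr", "de_p")) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1)
      note(sprintf("thresholds.%s must be a number in (0, 1], got %s",
                   nm, paste(v, collapse = ",")))
  }
  for (nm in c("min_delta", "strong_delta")) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      note(sprintf("thresholds.%s must be a number in [0, 1]", nm))
  }
  for (nm in c("min_depth", "min_allele_depth")) {
    v <- thr[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != as.integer(v))
      note(sprintf("thresholds.%s must be a non-negative integer", nm))
  }
  cfg$thresholds <- thr

  has_counts <- !is.null(cfg$counts)
  has_vcf <- !is.null(cfg$vcf)
  if (!has_counts && !has_vcf)
    note("one of 'counts' (TSV) or 'vcf' is required")
  if (has_vcf) {
    if (is.null(cfg$subgroup_map))
      note("'subgroup_map' is required with 'vcf'")
    if (is.null(cfg$tissue)) note("'tissue' is required with 'vcf'")
  }
  for (nm in c("counts", "vcf", "gene_models", "gene_sets", "universe")) {
    p <- cfg[[nm]]
    if (!is.null(p) && !file.exists(p))
      note(sprintf("'%s' path does not exist: %s", nm, p))
  }
  if (!is.null(cfg$de_tables)) {
    det <- cfg$de_tables
    if (is.data.frame(det)) det <- split(det, seq_len(nrow(det)))
    for (i in seq_along(det)) {
      d <- as.list(det[[i]])
      if (is.null(d$path) || is.null(d$label))
        note(sprintf("de_tables[%d] needs 'path' and 'label'", i))
      else if (!file.exists(d$path))
        note(sprintf("de_tables[%d] path does not exist: %s", i, d$path))
    }
    cfg$de_tables <- lapply(det, as.list)
  }
  if (is.null(cfg$out_dir)) note("'out_dir' is required")
  cfg$flank_bp <- cfg$flank_bp %||% 0L
  cfg$seed <- cfg$seed %||% 1L

  if (length(errors))
    stop2("invalid pipeline config:\n  - ",
          paste(errors, collapse = "\n  - "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full AIE pipeline
#'
#' Executes every configured stage and writes TSV outputs plus a JSON run
#' manifest (seed, thresholds, config hash, per-file md5) under
#' \code{out_dir}. Outputs: \code{aggregated.tsv}, \code{aie_calls.tsv},
#' \code{differential_aie.tsv}, and when inputs allow,
#' \code{snp_gene_assignments.tsv}, \code{gene_aie.tsv},
#' \code{crosswalk_enrichment.tsv}, \code{set_enrichment.tsv},
#' \code{de_correlations.tsv}, \code{de_overlap_counts.tsv}.
#'
#' @param config A \code{"pipeline_config"} from [validate_config()], or a
#'   path to one.
#' @return Named list of output paths, invisibly; the manifest is
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- validate_config(config)
  if (!inherits(config, "pipeline_config"))
    stop2("run_pipeline: expected a pipeline_config")
  cfg <- config
  thr <- cfg$thresholds
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e))))
  }

  records <- stage("extract", {
    if (!is.null(cfg$counts)) read_allele_counts_tsv(cfg$counts)
    else read_vcf_allele_depths(cfg$vcf, unlist(cfg$subgroup_map),
                                cfg$tissue)
  })

  tissues <- sort(unique(records$tissue))
  agg_all <- list(); aie_all <- list(); diff_all <- list()
  for (ts in tissues) {
    agg <- stage("aggregate",
                 aggregate_by_subgroup(records[records$tissue == ts, ]))
    filt <- stage("filter",
                  filter_sites(agg, min_depth = thr$min_depth,
                               min_allele_depth = thr$min_allele_depth))
    aie_all[[ts]] <- stage("aie", call_subgroup_aie(filt, fdr = thr$fdr))
    diff_all[[ts]] <- stage("diff-aie",
      call_differential_aie(filt, fdr = thr$fdr,
                            min_delta = thr$min_delta,
                            strong_delta = thr$strong_delta))
    agg_all[[ts]] <- agg
  }
  emit(do.call(rbind, agg_all), "aggregated.tsv")
  aie <- do.call(rbind, aie_all); rownames(aie) <- NULL
  emit(aie, "aie_calls.tsv")
  diff_aie <- do.call(rbind, diff_all); rownames(diff_aie) <- NULL
  emit(diff_aie, "differential_aie.tsv")

  gene_aie <- NULL
  if (!is.null(cfg$gene_models)) {
    genes <- stage("map-genes", read_gene_models(cfg$gene_models))
    snps <- unique(records[, c("snp_id", "chrom", "pos")])
    assign <- stage("map-genes",
                    map_snps_to_genes(snps, genes, flank_bp = cfg$flank_bp))
    emit(assign, "snp_gene_assignments.tsv")
    gene_aie <- stage("gene-aie", gene_level_aie(diff_aie, assign))
    emit(gene_aie, "gene_aie.tsv")
  }

  universe <- NULL
  if (!is.null(cfg$universe)) {
    uni_df <- utils::read.delim(cfg$universe, stringsAsFactors = FALSE)
    assert_columns(uni_df, "gene_id", cfg$universe)
    universe <- gene_set("expressed", uni_df$gene_id)
  }

  de_tabs <- NULL
  if (!is.null(cfg$de_tables)) {
    de_tabs <- stage("read-de", lapply(cfg$de_tables, function(d)
      read_de_table(d$path, d$label, significance_threshold = thr$de_p)))
    names(de_tabs) <- vapply(cfg$de_tables, `[[`, "", "label")
  }

  if (!is.null(gene_aie) && !is.null(de_tabs) && !is.null(universe)) {
    cw <- stage("crosswalk",
                crosswalk_aie_de_enrichment(gene_aie, de_tabs[[1]],
                                            universe, de_p = thr$de_p))
    emit(cw, "crosswalk_enrichment.tsv")
  }

  if (!is.null(cfg$gene_sets) && !is.null(universe) && !is.null(gene_aie)) {
    sets <- stage("enrich", read_gene_sets(cfg$gene_sets))
    queries <- list()
    for (ts in unique(gene_aie$tissue)) {
      for (cat in c("increasing_ref_frac", "decreasing_ref_frac")) {
        ids <- intersect(
          gene_aie$gene_id[gene_aie$tissue == ts &
                             gene_aie$category == cat],
          universe$gene_ids)
        if (length(ids))
          queries[[paste(ts, cat, sep = ".")]] <-
            gene_set(paste(ts, cat, sep = "."), ids)
      }
    }
    if (length(queries)) {
      bat <- stage("enrich", gene_set_battery(queries, sets, universe))
      emit(bat, "set_enrichment.tsv")
    }
  }

  if (!is.null(de_tabs) && length(de_tabs) >= 2) {
    pairs <- utils::combn(names(de_tabs), 2, simplify = FALSE)
    cor_rows <- lapply(pairs, function(pr) {
      shared <- overlapping_de_genes(de_tabs[[pr[1]]], de_tabs[[pr[2]]])
      if (length(shared) < 3)
        return(data.frame(contrast_x = pr[1], contrast_y = pr[2],
                          n_used = length(shared), pearson_r = NA_real_,
                          p_value = NA_real_, stringsAsFactors = FALSE))
      cc <- correlate_fold_changes(de_tabs[[pr[1]]], de_tabs[[pr[2]]],
                                   shared,
                                   exclude_ids = unlist(cfg$exclude_genes))
      data.frame(contrast_x = pr[1], contrast_y = pr[2],
                 n_used = cc$n_used, pearson_r = cc$pearson_r,
                 p_value = cc$p_value, stringsAsFactors = FALSE)
    })
    emit(do.call(rbind, cor_rows), "de_correlations.tsv")
    emit(stage("overlaps", overlap_counts(de_tabs)),
         "de_overlap_counts.tsv")
  }

  manifest <- list(
    package = "recipase",
    version = as.character(utils::packageVersion("recipase")),
    seed = cfg$seed,
    thresholds = thr,
    n_records = nrow(records),
    tissues = tissues,
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  outputs[["manifest.json"]] <- manifest_path
  invisible(outputs)
}
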