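# Fisher-exact gene-set enrichment with fold-enrichment statistics, the
# AIE-category x DE-direction crosswalk battery, and the generic
# query-set x annotation-set battery (GWAS-locus sets, ChrX genes, pathways).
#
# All tests are computed against an explicit expressed-gene universe supplied
# by the caller; the whole annotation is never used silently as background.

#' Construct a gene set
#'
#' @param name Set name.
#' @param gene_ids Character vector of gene ids (deduplicated).
#' @param description Optional free-text description.
#' @return List of class \code{"gene_set"} with unique ids.
#' @export
gene_set <- function(name, gene_ids, description = "") {
  if (!length(gene_ids)) stop2("gene_set '", name, "' is empty")
  structure(list(name = name,
                 gene_ids = unique(as.character(gene_ids)),
                 description = description),
            class = "gene_set")
}

#' Read named gene sets from a two-column TSV
#'
#' Expects columns \code{set_name} and \code{gene_id} (header required);
#' returns one [gene_set()] per distinct set name.
#'
#' @param path TSV path.
#' @return Named list of gene sets.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_columns(df, c("set_name", "gene_id"), path)
  sets <- lapply(split(df$gene_id, df$set_name),
                 function(ids) unique(as.character(ids)))
  mapply(gene_set, names(sets), sets, SIMPLIFY = FALSE)
}

# Two-sided Fisher exact p for a 2x2 table by minimum-likelihood enumeration
# over the hypergeometric distribution with margins fixed. Written directly
# (rather than delegating to fisher.test) so the test suite can check it
# against an independent implementation.
fisher_exact_p <- function(a, b, c_, d) {
  m <- a + c_        # annotated genes
  n <- b + d         # unannotated genes
  k <- a + b         # query size
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= obs * (1 + 1e-7)])
  min(p, 1)
}

#' Fisher's exact gene-set enrichment
#'
#' Tests whether a query gene set is enriched for an annotation set within a
#' universe of (typically expressed) genes. Genes outside the universe are
#' discarded from both sets before tabulation. The 2x2 table is
#' a = |query & annotation|, b = |query \\ annotation|,
#' c = |annotation \\ query|, d = the rest of the universe.
#'
#' @param query,annotation,universe [gene_set()] objects (or bare character
#'   vectors of gene ids).
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}.
#' @return One-row data frame with columns \code{query_name},
#'   \code{set_name}, \code{a}, \code{b}, \code{c}, \code{d},
#'   \code{odds_ratio}, \code{fold_enrichment}, \code{p_value}.
#' @export
fisher_enrichment <- function(query, annotation, universe,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  as_set <- function(x, nm) {
    if (inherits(x, "gene_set")) x
    else gene_set(nm, x)
  }
  query <- as_set(query, "query")
  annotation <- as_set(annotation, "annotation")
  universe <- as_set(universe, "universe")
  uni <- universe$gene_ids
  if (!length(uni)) stop2("fisher_enrichment: empty universe")
  q <- intersect(query$gene_ids, uni)
  s <- intersect(annotation$gene_ids, uni)
  if (!length(q))
    stop2("fisher_enrichment: query '", query$name,
          "' empty after intersecting with the universe")
  a <- length(intersect(q, s))
  b <- length(q) - a
  c_ <- length(s) - a
  d <- length(uni) - a - b - c_
  p <- if (alternative == "two.sided") {
    fisher_exact_p(a, b, c_, d)
  } else {
    # P(X >= a) under the hypergeometric null
    stats::phyper(a - 1L, a + c_, b + d, a + b, lower.tail = FALSE)
  }
  fold <- if (a + c_ == 0) 0 else
    (a / (a + b)) / ((a + c_) / (a + b + c_ + d))
  or <- if (b == 0 || c_ == 0) {
    if (a == 0 || d == 0) NaN else Inf
  } else a * d / (b * c_)
  if (a == 0 && (b == 0 || c_ == 0)) or <- 0
  data.frame(query_name = query$name, set_name = annotation$name,
             a = a, b = b, c = c_, d = d,
             odds_ratio = or, fold_enrichment = fold,
             p_value = max(p, .Machine$double.xmin),
             stringsAsFactors = FALSE)
}

#' Fold enrichment of an overlap over a background proportion
#'
#' Computes (overlap / query_size) / background_proportion on unrounded
#' arithmetic. For reporting, round with [round_half_away()] to one decimal,
#' matching the convention of published fold-enrichment figures (e.g. 5 of
#' 37 genes against a 4.1\% background reports as 3.3-fold).
#'
#' @param overlap Number of annotated genes in the query.
#' @param query_size Query size (>= 1, >= overlap).
#' @param background_proportion Background annotation rate in (0, 1].
#' @return Unrounded fold enrichment.
#' @export
#' @examples
#' fold_enrichment(5, 37, 0.041)        # 3.296...
#' round_half_away(fold_enrichment(5, 37, 0.041))  # 3.3
fold_enrichment <- function(overlap, query_size, background_proportion) {
  overlap <- assert_count(overlap, "overlap")
  query_size <- assert_count(query_size, "query_size", minimum = 1L)
  if (overlap > query_size)
    stop2("fold_enrichment: overlap exceeds query_size")
  assert_scalar_number(background_proportion, "background_proportion",
                       lower = 0, upper = 1, allow_equal_lower = FALSE)
  (overlap / query_size) / background_proportion
}

#' AIE-category x DE-direction enrichment crosswalk
#'
#' For each tissue and each differential-AIE gene category
#' (\code{increasing_ref_frac}, \code{decreasing_ref_frac}), tests enrichment
#' of up- and downregulated DE genes among the AIE genes by Fisher's exact
#' test against the expressed-gene universe, with BH correction across the
#' whole battery. Cells with no qualifying AIE genes yield a = 0 and p = 1.
#'
#' @param gene_aie Gene-level AIE table from [gene_level_aie()].
#' @param de_table DE table (columns gene_id, log2FC, pvalue).
#' @param universe [gene_set()] of expressed genes (or character vector).
#' @param de_p Nominal DE significance threshold (default 0.05).
#' @param alternative Passed to [fisher_enrichment()].
#' @return Data frame, one row per tissue x AIE category x DE direction,
#'   with the [fisher_enrichment()] columns plus \code{tissue},
#'   \code{aie_category}, \code{de_direction}, \code{q_fdr}.
#' @export
crosswalk_aie_de_enrichment <- function(gene_aie, de_table, universe,
                                        de_p = 0.05,
                                        alternative = "two.sided") {
  assert_columns(gene_aie, c("gene_id", "tissue", "category"),
                 "gene-level AIE table")
  assert_columns(de_table, c("gene_id", "log2FC", "pvalue"), "DE table")
  if (!inherits(universe, "gene_set")) universe <- gene_set("universe",
                                                            universe)
  sig <- de_table[de_table$pvalue < de_p, , drop = FALSE]
  de_dir <- list(up = sig$gene_id[sig$log2FC > 0],
                 down = sig$gene_id[sig$log2FC < 0])
  tissues <- sort(unique(gene_aie$tissue))
  rows <- list()
  for (ts in tissues) {
    for (cat in c("increasing_ref_frac", "decreasing_ref_frac")) {
      aie_genes <- gene_aie$gene_id[gene_aie$tissue == ts &
                                      gene_aie$category == cat]
      for (dir in c("up", "down")) {
        q_ids <- intersect(aie_genes, universe$gene_ids)
        s_ids <- intersect(de_dir[[dir]], universe$gene_ids)
        res <- if (length(q_ids) && length(s_ids)) {
          fisher_enrichment(gene_set(cat, q_ids),
                            gene_set(paste0("de_", dir), s_ids),
                            universe, alternative = alternative)
        } else {
          # degenerate cell: no qualifying AIE genes or no DE genes
          data.frame(query_name = cat, set_name = paste0("de_", dir),
                     a = 0L, b = length(q_ids), c = length(s_ids),
                     d = length(universe$gene_ids) -
                       length(q_ids) - length(s_ids),
                     odds_ratio = 0, fold_enrichment = 0, p_value = 1,
                     stringsAsFactors = FALSE)
        }
        res$tissue <- ts
        res$aie_category <- cat
        res$de_direction <- dir
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_name = character(), set_name = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      tissue = character(), aie_category = character(),
                      de_direction = character(), q_fdr = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$q_fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}

#' Full query x annotation Fisher battery
#'
#' Crosses every query set with every annotation set (GWAS-locus genes,
#' ChrX genes, pathway sets, ...) within the universe, reporting the Fisher
#' p, table-derived fold enrichment and BH q across the whole battery. The
#' BH adjustment is invariant to the order in which sets are supplied.
#'
#' @param query_sets,annotation_sets Lists of [gene_set()] objects.
#' @param universe [gene_set()] of expressed genes.
#' @param alternative Passed to [fisher_enrichment()].
#' @return Data frame of [fisher_enrichment()] rows plus \code{q_fdr},
#'   ordered by query then annotation name.
#' @export
gene_set_battery <- function(query_sets, annotation_sets, universe,
                             alternative = "two.sided") {
  if (inherits(query_sets, "gene_set")) query_sets <- list(query_sets)
  if (inherits(annotation_sets, "gene_set"))
    annotation_sets <- list(annotation_sets)
  rows <- list()
  for (q in query_sets) {
    for (s in annotation_sets) {
      rows[[length(rows) + 1L]] <-
        fisher_enrichment(q, s, universe, alternative = alternative)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$query_name, out$set_name), , drop = FALSE]
  out$q_fdr <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
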