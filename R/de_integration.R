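# Differential-expression table integration: overlaps of significant genes
# between contrasts, fold-change correlations with explicit outlier
# exclusion, and intersection-pattern ("upset") counts.
#
# DE fitting itself is out of scope; tables arrive as TSV with columns
# gene_id, log2FC, pvalue. Significance is the nominal p < 0.05 cut-off
# unless configured otherwise.

#' Read and validate a DE result table
#'
#' @param path TSV with columns \code{gene_id}, \code{log2FC},
#'   \code{pvalue}.
#' @param contrast_label Label for this contrast (tissue/sex/paradigm),
#'   stored as an attribute.
#' @param significance_threshold Nominal p cut-off stored with the table
#'   (default 0.05).
#' @return Data frame with a \code{direction} column (\code{"up"} when
#'   log2FC >= 0 — zero fold change maps to "up" by convention and is
#'   reported via message — else \code{"down"}), plus attributes
#'   \code{contrast_label} and \code{significance_threshold}.
#' @export
read_de_table <- function(path, contrast_label,
                          significance_threshold = 0.05) {
  if (!file.exists(path)) stop2("DE table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  de_table(df, contrast_label, significance_threshold)
}

#' Validate an in-memory DE table
#'
#' @param df Data frame with columns \code{gene_id}, \code{log2FC},
#'   \code{pvalue}.
#' @inheritParams read_de_table
#' @return Validated data frame (see [read_de_table()]).
#' @export
de_table <- function(df, contrast_label, significance_threshold = 0.05) {
  assert_columns(df, c("gene_id", "log2FC", "pvalue"), "DE table")
  if (!is.numeric(df$log2FC) || !is.numeric(df$pvalue))
    stop2("DE table: log2FC and pvalue must be numeric")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup))
    stop2("DE table: duplicated gene id(s): ",
          paste(utils::head(dup, 5), collapse = ", "))
  if (any(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1))
    stop2("DE table: pvalue must lie in (0, 1]")
  n_zero <- sum(df$log2FC == 0)
  if (n_zero > 0)
    message("de_table: ", n_zero,
            " gene(s) with log2FC == 0 assigned direction 'up' by convention")
  df$direction <- ifelse(df$log2FC >= 0, "up", "down")
  attr(df, "contrast_label") <- contrast_label
  attr(df, "significance_threshold") <- significance_threshold
  df
}

de_threshold <- function(tab) {
  attr(tab, "significance_threshold") %||% 0.05
}

#' Genes significant in both of two DE tables
#'
#' Intersection of gene ids passing each table's own nominal significance
#' threshold.
#'
#' @param table_x,table_y DE tables (see [de_table()]).
#' @return Sorted character vector of gene ids.
#' @export
overlapping_de_genes <- function(table_x, table_y) {
  assert_columns(table_x, c("gene_id", "pvalue"), "table_x")
  assert_columns(table_y, c("gene_id", "pvalue"), "table_y")
  sig_x <- table_x$gene_id[table_x$pvalue < de_threshold(table_x)]
  sig_y <- table_y$gene_id[table_y$pvalue < de_threshold(table_y)]
  sort(intersect(sig_x, sig_y))
}

#' Pearson correlation of log2 fold changes between two contrasts
#'
#' Correlates log2FC over the given genes present in both tables, after
#' removing any explicitly excluded ids (outlier removal is always
#' explicit-by-id, never automatic). The p-value comes from the t
#' transform t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom.
#'
#' @param table_x,table_y DE tables.
#' @param genes Gene ids to correlate over (e.g. from
#'   [overlapping_de_genes()]).
#' @param exclude_ids Gene ids to drop before correlating (default none).
#' @return List with \code{pearson_r}, \code{p_value}, \code{n_used}.
#' @export
correlate_fold_changes <- function(table_x, table_y, genes,
                                   exclude_ids = character(0)) {
  assert_columns(table_x, c("gene_id", "log2FC"), "table_x")
  assert_columns(table_y, c("gene_id", "log2FC"), "table_y")
  use <- setdiff(intersect(genes, intersect(table_x$gene_id,
                                            table_y$gene_id)),
                 exclude_ids)
  n <- length(use)
  if (n < 3) stop2("correlate_fold_changes: fewer than 3 genes after ",
                   "intersection and exclusions (n = ", n, ")")
  x <- table_x$log2FC[match(use, table_x$gene_id)]
  y <- table_y$log2FC[match(use, table_y$gene_id)]
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
    p <- max(min(p, 1), .Machine$double.xmin)
  }
  list(pearson_r = r, p_value = p, n_used = n)
}

#' Intersection-pattern counts of significant genes across DE tables
#'
#' For every non-empty membership pattern over the tables (as in an upset
#' plot), counts the genes significant in exactly that set of tables.
#' Pattern counts sum to the size of the union of significant genes.
#'
#' @param tables Named list of >= 2 DE tables.
#' @return Data frame with columns \code{pattern}
#'   (\code{"+"}-joined table names), \code{degree}, \code{count}, ordered
#'   by decreasing degree then pattern.
#' @export
overlap_counts <- function(tables) {
  if (length(tables) < 2) stop2("overlap_counts: need at least 2 tables")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- paste0("table", seq_along(tables))
  sig <- lapply(tables, function(tab) {
    assert_columns(tab, c("gene_id", "pvalue"), "DE table")
    unique(tab$gene_id[tab$pvalue < de_threshold(tab)])
  })
  all_genes <- unique(unlist(sig))
  if (!length(all_genes)) {
    return(data.frame(pattern = character(), degree = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  membership <- vapply(sig, function(s) all_genes %in% s,
                       logical(length(all_genes)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(row)
    paste(names(tables)[row], collapse = "+"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab),
                    degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
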