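# Core allelic-imbalance statistics: depth filtering, subgroup aggregation,
# exact binomial AIE calls, differential AIE between reciprocal subgroups,
# and gene-level summarisation.
#
# Conventions: "ref" is the allele matching the reference genome build (for a
# BN-derived reference, the BN copy). Subgroup A is the cross whose father
# carries the non-reference strain; delta = ref_frac_A - ref_frac_B, so a
# paternally expressed gene drives delta negative and a maternally expressed
# gene drives it positive.

#' Exact two-sided binomial test against 0.5
#'
#' Tests whether reference and alternate read depths are consistent with a
#' balanced (0.5/0.5) allelic origin. The two-sided p-value is computed by the
#' minimum-likelihood method: the sum of all binomial point probabilities no
#' larger than that of the observed count. At p0 = 0.5 this equals the doubled
#' single tail capped at 1.
#'
#' @param ref_depth Non-negative integer count of reference-allele reads.
#' @param alt_depth Non-negative integer count of alternate-allele reads.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' exact_binomial_test(15, 5)   # ~0.0414
#' exact_binomial_test(10, 10)  # 1
exact_binomial_test <- function(ref_depth, alt_depth) {
  ref_depth <- assert_count(ref_depth, "ref_depth")
  alt_depth <- assert_count(alt_depth, "alt_depth")
  n <- ref_depth + alt_depth
  if (n < 1L) stop2("exact_binomial_test: zero total depth")
  d <- stats::dbinom(0:n, n, 0.5)
  # relative tolerance guards against fp noise when comparing equal masses
  obs <- d[ref_depth + 1L]
  p <- sum(d[d <= obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic BH step-up: with order statistics p_(1) <= ... <= p_(m),
#' q_(i) = min_{j >= i} p_(j) * m / j, capped at 1. Values are returned in the
#' input order. Ties and repeated values are handled by the cumulative-minimum
#' construction.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop2("bh_fdr: all p-values must lie in (0, 1]")
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Pooled two-sample proportion test
#'
#' Two-tailed z (score) test for equality of two binomial proportions using
#' the pooled estimate of the common proportion. Used to compare the
#' reference-allele fraction between the reciprocal subgroups at a SNP. No
#' continuity correction by default; \code{correct = TRUE} applies the Yates
#' adjustment for parity with other software.
#'
#' @param ref_a,tot_a Reference depth and total depth in subgroup A.
#' @param ref_b,tot_b Reference depth and total depth in subgroup B.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A list with elements \code{z_stat} and \code{p_value}.
#' @export
#' @examples
#' two_proportion_test(80, 100, 50, 100)  # p ~ 8.7e-6
two_proportion_test <- function(ref_a, tot_a, ref_b, tot_b, correct = FALSE) {
  tot_a <- assert_count(tot_a, "tot_a", minimum = 1L)
  tot_b <- assert_count(tot_b, "tot_b", minimum = 1L)
  ref_a <- assert_count(ref_a, "ref_a")
  ref_b <- assert_count(ref_b, "ref_b")
  if (ref_a > tot_a || ref_b > tot_b)
    stop2("two_proportion_test: ref depth exceeds total depth")
  pa <- ref_a / tot_a
  pb <- ref_b / tot_b
  pooled <- (ref_a + ref_b) / (tot_a + tot_b)
  se <- sqrt(pooled * (1 - pooled) * (1 / tot_a + 1 / tot_b))
  diff <- pa - pb
  if (correct) {
    cc <- 0.5 * (1 / tot_a + 1 / tot_b)
    diff <- sign(diff) * max(0, abs(diff) - cc)
  }
  if (se == 0) {
    # pooled proportion 0 or 1: both groups fully concordant, no evidence
    z <- 0
  } else {
    z <- diff / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  list(z_stat = z, p_value = min(p, 1))
}

#' Sum allele depths across samples within each reciprocal subgroup
#'
#' Aggregates per-sample allele depth records into per-(SNP, subgroup) summed
#' depths and the resulting reference-allele fraction. All records in one call
#' must come from the same tissue; analyse tissues as separate strata.
#'
#' @param records Data frame of allele depth records with columns
#'   \code{snp_id}, \code{sample_id}, \code{subgroup} (\code{"A"}/\code{"B"}),
#'   \code{tissue}, \code{ref_depth}, \code{alt_depth}.
#' @return Data frame with columns \code{snp_id}, \code{tissue},
#'   \code{subgroup}, \code{ref_depth_sum}, \code{alt_depth_sum},
#'   \code{ref_frac}, ordered by snp_id then subgroup.
#' @export
aggregate_by_subgroup <- function(records) {
  assert_columns(records, c("snp_id", "subgroup", "tissue",
                            "ref_depth", "alt_depth"),
                 "allele depth record table")
  tissues <- unique(records$tissue)
  if (length(tissues) > 1L)
    stop2("aggregate_by_subgroup: mixed tissues in one call (",
          paste(tissues, collapse = ", "),
          "); aggregate each tissue separately")
  if (!all(records$subgroup %in% c("A", "B")))
    stop2("aggregate_by_subgroup: subgroup must be 'A' or 'B'")
  if (!nrow(records)) {
    return(data.frame(snp_id = character(), tissue = character(),
                      subgroup = character(), ref_depth_sum = integer(),
                      alt_depth_sum = integer(), ref_frac = numeric(),
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::as.data.table(records)
  agg <- dt[, list(ref_depth_sum = sum(as.integer(ref_depth)),
                   alt_depth_sum = sum(as.integer(alt_depth))),
            by = c("snp_id", "tissue", "subgroup")]
  data.table::setorderv(agg, c("snp_id", "subgroup"))
  data.table::setDF(agg)
  tot <- agg$ref_depth_sum + agg$alt_depth_sum
  agg$ref_frac <- ifelse(tot > 0, agg$ref_depth_sum / tot, NA_real_)
  agg
}

#' Depth filter for aggregated sites
#'
#' A SNP is retained only when, in each reciprocal subgroup, the aggregated
#' total depth is at least \code{min_depth} and each allele has at least
#' \code{min_allele_depth} reads. The filter is monotone: adding reads never
#' turns a kept site into a dropped one.
#'
#' @param agg Aggregated site table from [aggregate_by_subgroup()].
#' @param min_depth Minimum summed depth per subgroup (default 20).
#' @param min_allele_depth Minimum summed depth per allele per subgroup
#'   (default 2).
#' @param require_both Require both subgroups present and passing
#'   (default TRUE, the precondition of the differential test).
#' @return The subset of \code{agg} at SNPs that pass.
#' @export
filter_sites <- function(agg, min_depth = 20L, min_allele_depth = 2L,
                         require_both = TRUE) {
  assert_columns(agg, c("snp_id", "subgroup", "ref_depth_sum",
                        "alt_depth_sum"), "aggregated site table")
  min_depth <- assert_count(min_depth, "min_depth")
  min_allele_depth <- assert_count(min_allele_depth, "min_allele_depth")
  tot <- agg$ref_depth_sum + agg$alt_depth_sum
  row_pass <- tot >= min_depth &
    agg$ref_depth_sum >= min_allele_depth &
    agg$alt_depth_sum >= min_allele_depth
  if (require_both) {
    pass_a <- unique(agg$snp_id[row_pass & agg$subgroup == "A"])
    pass_b <- unique(agg$snp_id[row_pass & agg$subgroup == "B"])
    keep_snps <- intersect(pass_a, pass_b)
    agg[agg$snp_id %in% keep_snps, , drop = FALSE]
  } else {
    agg[row_pass, , drop = FALSE]
  }
}

#' Call subgroup-level allelic imbalance (AIE)
#'
#' Each aggregated (SNP, subgroup) site is tested for departure from the
#' balanced 0.5 reference fraction by the exact binomial test; BH FDR is
#' applied within each (tissue, subgroup) family and sites with q below
#' \code{fdr} are flagged as AIE.
#'
#' @param agg Filtered aggregated site table.
#' @param fdr FDR threshold (default 0.05).
#' @return \code{agg} with added columns \code{p_binomial}, \code{q_fdr},
#'   \code{is_aie}.
#' @export
call_subgroup_aie <- function(agg, fdr = 0.05) {
  assert_columns(agg, c("snp_id", "tissue", "subgroup", "ref_depth_sum",
                        "alt_depth_sum"), "aggregated site table")
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1,
                       allow_equal_lower = FALSE)
  if (!nrow(agg)) {
    agg$p_binomial <- numeric(0); agg$q_fdr <- numeric(0)
    agg$is_aie <- logical(0)
    return(agg)
  }
  agg$p_binomial <- mapply(exact_binomial_test,
                           agg$ref_depth_sum, agg$alt_depth_sum)
  fam <- interaction(agg$tissue, agg$subgroup, drop = TRUE)
  agg$q_fdr <- stats::ave(agg$p_binomial, fam, FUN = bh_fdr)
  agg$is_aie <- agg$q_fdr < fdr
  agg
}

#' Differential AIE between reciprocal subgroups
#'
#' For every SNP with both subgroups passing the depth filter, compares the
#' subgroup reference-allele fractions by the pooled two-proportion z-test,
#' adjusts p-values by BH within each tissue, and categorises SNPs:
#' \code{increasing_ref_frac} when q < \code{fdr} and delta > \code{min_delta},
#' \code{decreasing_ref_frac} when q < \code{fdr} and delta < -\code{min_delta},
#' otherwise \code{none}. delta is ref_frac_A - ref_frac_B on unrounded
#' fractions. SNPs with |delta| > \code{strong_delta} are additionally flagged
#' as strong imprinting candidates (the screen that recovers known imprinted
#' genes such as Snrpn and Trappc9).
#'
#' @param agg Aggregated site table containing both subgroups per SNP
#'   (pre-filtered with [filter_sites()], or pass \code{filter = TRUE}).
#' @param fdr FDR threshold (default 0.05).
#' @param min_delta Minimum |delta| to qualify (default 0.1, exclusive).
#' @param strong_delta Strong-imprinting |delta| threshold (default 0.7,
#'   exclusive).
#' @param correct Continuity correction for the z-test (default FALSE).
#' @param filter Apply [filter_sites()] first with its defaults
#'   (default FALSE).
#' @return Data frame with one row per tested SNP: \code{snp_id},
#'   \code{tissue}, \code{ref_frac_A}, \code{ref_frac_B}, \code{delta},
#'   \code{z_stat}, \code{p_value}, \code{q_fdr}, \code{category},
#'   \code{strong_imprinting}.
#' @export
call_differential_aie <- function(agg, fdr = 0.05, min_delta = 0.1,
                                  strong_delta = 0.7, correct = FALSE,
                                  filter = FALSE) {
  assert_columns(agg, c("snp_id", "tissue", "subgroup", "ref_depth_sum",
                        "alt_depth_sum"), "aggregated site table")
  assert_scalar_number(fdr, "fdr", lower = 0, upper = 1,
                       allow_equal_lower = FALSE)
  assert_scalar_number(min_delta, "min_delta", lower = 0, upper = 1)
  assert_scalar_number(strong_delta, "strong_delta", lower = 0, upper = 1)
  if (filter) agg <- filter_sites(agg)

  empty <- data.frame(snp_id = character(), tissue = character(),
                      ref_frac_A = numeric(), ref_frac_B = numeric(),
                      delta = numeric(), z_stat = numeric(),
                      p_value = numeric(), q_fdr = numeric(),
                      category = character(), strong_imprinting = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(agg)) return(empty)

  a <- agg[agg$subgroup == "A", , drop = FALSE]
  b <- agg[agg$subgroup == "B", , drop = FALSE]
  key_a <- paste(a$snp_id, a$tissue, sep = "\r")
  key_b <- paste(b$snp_id, b$tissue, sep = "\r")
  shared <- intersect(key_a, key_b)
  if (!length(shared)) return(empty)
  a <- a[match(shared, key_a), , drop = FALSE]
  b <- b[match(shared, key_b), , drop = FALSE]

  tot_a <- a$ref_depth_sum + a$alt_depth_sum
  tot_b <- b$ref_depth_sum + b$alt_depth_sum
  tests <- mapply(function(ra, ta, rb, tb)
    unlist(two_proportion_test(ra, ta, rb, tb, correct = correct)),
    a$ref_depth_sum, tot_a, b$ref_depth_sum, tot_b)
  res <- data.frame(
    snp_id = a$snp_id,
    tissue = a$tissue,
    ref_frac_A = a$ref_depth_sum / tot_a,
    ref_frac_B = b$ref_depth_sum / tot_b,
    z_stat = unname(tests["z_stat", ]),
    p_value = unname(tests["p_value", ]),
    stringsAsFactors = FALSE
  )
  res$delta <- res$ref_frac_A - res$ref_frac_B
  res$q_fdr <- stats::ave(res$p_value, res$tissue, FUN = bh_fdr)
  res$category <- ifelse(
    res$q_fdr < fdr & res$delta > min_delta, "increasing_ref_frac",
    ifelse(res$q_fdr < fdr & res$delta < -min_delta, "decreasing_ref_frac",
           "none"))
  res$strong_imprinting <- abs(res$delta) > strong_delta
  res <- res[order(res$tissue, res$snp_id),
             c("snp_id", "tissue", "ref_frac_A", "ref_frac_B", "delta",
               "z_stat", "p_value", "q_fdr", "category", "strong_imprinting")]
  rownames(res) <- NULL
  res
}

#' Summarise differential AIE to the gene level
#'
#' Each gene inherits the category of its best qualifying SNP: among assigned
#' SNPs with category other than \code{none}, the one with minimum q, ties
#' broken by larger |delta|, then lexicographic snp_id. Genes whose assigned
#' SNPs are all \code{none} get category \code{none} (best SNP chosen by the
#' same rule among them). Unassigned SNPs are ignored.
#'
#' @param results Differential AIE table from [call_differential_aie()].
#' @param assignments SNP-to-gene assignment table with columns
#'   \code{snp_id}, \code{gene_id} (see [map_snps_to_genes()]).
#' @return Data frame with columns \code{gene_id}, \code{tissue},
#'   \code{category}, \code{best_snp_id}, \code{best_q_fdr},
#'   \code{best_delta}, ordered by tissue then gene_id.
#' @export
gene_level_aie <- function(results, assignments) {
  assert_columns(results, c("snp_id", "tissue", "delta", "q_fdr", "category"),
                 "differential AIE table")
  assert_columns(assignments, c("snp_id", "gene_id"), "assignment table")
  merged <- merge(results, assignments[, c("snp_id", "gene_id")],
                  by = "snp_id")
  empty <- data.frame(gene_id = character(), tissue = character(),
                      category = character(), best_snp_id = character(),
                      best_q_fdr = numeric(), best_delta = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(merged)) return(empty)
  dt <- data.table::as.data.table(merged)
  pick_best <- function(sub) {
    qual <- sub[sub$category != "none", , drop = FALSE]
    cand <- if (nrow(qual)) qual else sub
    ord <- order(cand$q_fdr, -abs(cand$delta), cand$snp_id)
    best <- cand[ord[1L], ]
    list(category = best$category, best_snp_id = best$snp_id,
         best_q_fdr = best$q_fdr, best_delta = best$delta)
  }
  out <- dt[, pick_best(.SD), by = c("gene_id", "tissue"),
            .SDcols = c("snp_id", "q_fdr", "delta", "category")]
  data.table::setorderv(out, c("tissue", "gene_id"))
  data.table::setDF(out)
  out
}
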