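# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

# aggregated-site table built directly from counts:
# counts is a list of c(ref, alt) pairs, one per subgroup per snp
make_agg <- function(snp_id, subgroup, ref, alt, tissue = "T1") {
  tot <- ref + alt
  data.frame(snp_id = snp_id, tissue = tissue, subgroup = subgroup,
             ref_depth_sum = as.integer(ref), alt_depth_sum = as.integer(alt),
             ref_frac = ifelse(tot > 0, ref / tot, NA_real_),
             stringsAsFactors = FALSE)
}

# paired A/B aggregated rows for a vector of snps
make_paired_agg <- function(ids, ref_a, alt_a, ref_b, alt_b, tissue = "T1") {
  rbind(make_agg(ids, "A", ref_a, alt_a, tissue),
        make_agg(ids, "B", ref_b, alt_b, tissue))
}

# small allele-depth record table
make_records <- function(snp_id, sample_id, subgroup, ref_depth, alt_depth,
                         tissue = "T1") {
  data.frame(snp_id = snp_id, chrom = "chr1",
             pos = 100L + as.integer(factor(snp_id)),
             ref = "A", alt = "G",
             sample_id = sample_id, subgroup = subgroup, tissue = tissue,
             ref_depth = as.integer(ref_depth),
             alt_depth = as.integer(alt_depth),
             stringsAsFactors = FALSE)
}

# independent brute-force BH step-up (oracle; loop form, no cummin tricks)
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# independent Pearson r from the textbook sum formula
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}
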