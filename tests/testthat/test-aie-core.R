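test_that("exact binomial test matches frozen enumerated values", {
  # enumerated: sum of C(20,k)/2^20 over k >= 15 and k <= 5 = 43400/1048576
  expect_equal(exact_binomial_test(15, 5), 43400 / 1048576)
  expect_equal(exact_binomial_test(10, 10), 1)
  expect_equal(exact_binomial_test(20, 0), 2 * 2^-20)
  expect_equal(exact_binomial_test(0, 20), 2 * 2^-20)
  expect_error(exact_binomial_test(0, 0), "zero total depth")
})

test_that("exact binomial test agrees with binom.test for all totals <= 30", {
  for (n in 1:30) {
    for (k in 0:n) {
      expect_equal(exact_binomial_test(k, n - k),
                   stats::binom.test(k, n, 0.5)$p.value,
                   tolerance = 1e-12,
                   info = sprintf("ref=%d alt=%d", k, n - k))
    }
  }
})

test_that("bh_fdr matches frozen examples and brute-force step-up", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(42)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # and against stats::p.adjust as a second, independent route
  set.seed(43)
  p <- stats::runif(500)
  expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
})

test_that("two-proportion z test matches closed forms and prop.test", {
  res <- two_proportion_test(50, 100, 50, 100)
  expect_equal(res$z_stat, 0)
  expect_equal(res$p_value, 1)

  # z = 0.3 / sqrt(0.65 * 0.35 * (1/100 + 1/100)), doubled normal tail
  res <- two_proportion_test(80, 100, 50, 100)
  z_expected <- 0.3 / sqrt(0.65 * 0.35 * 0.02)
  expect_equal(res$z_stat, z_expected, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-z_expected), tolerance = 1e-12)

  res <- two_proportion_test(100, 100, 0, 100)
  expect_lt(res$p_value, 1e-15)
  expect_gt(res$p_value, 0)

  # uncorrected z^2 equals prop.test's chi-squared statistic
  set.seed(1)
  for (i in 1:50) {
    na <- sample(20:200, 1); nb <- sample(20:200, 1)
    ra <- sample(0:na, 1); rb <- sample(0:nb, 1)
    if ((ra + rb) %in% c(0, na + nb)) next
    pt <- suppressWarnings(
      stats::prop.test(c(ra, rb), c(na, nb), correct = FALSE))
    res <- two_proportion_test(ra, na, rb, nb)
    expect_equal(res$z_stat^2, unname(pt$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, pt$p.value, tolerance = 1e-10)
  }

  # Yates flag reproduces prop.test(correct = TRUE)
  pt <- stats::prop.test(c(80, 50), c(100, 100), correct = TRUE)
  res <- two_proportion_test(80, 100, 50, 100, correct = TRUE)
  expect_equal(res$z_stat^2, unname(pt$statistic), tolerance = 1e-10)
})

test_that("aggregate_by_subgroup sums depths per (snp, subgroup)", {
  rec <- make_records(rep("s1", 3), c("a1", "a2", "b1"), c("A", "A", "B"),
                      c(10, 20, 7), c(5, 15, 3))
  agg <- aggregate_by_subgroup(rec)
  a <- agg[agg$subgroup == "A", ]
  expect_equal(a$ref_depth_sum, 30L)
  expect_equal(a$alt_depth_sum, 20L)
  expect_equal(a$ref_frac, 0.6)
  b <- agg[agg$subgroup == "B", ]
  expect_equal(b$ref_depth_sum, 7L)

  # single sample passes through; absent subgroup emits no row
  rec1 <- make_records("s2", "a1", "A", 4, 6)
  agg1 <- aggregate_by_subgroup(rec1)
  expect_equal(nrow(agg1), 1L)
  expect_equal(agg1$ref_depth_sum, 4L)
  expect_false("B" %in% agg1$subgroup)

  expect_error(
    aggregate_by_subgroup(rbind(make_records("s1", "a1", "A", 1, 1, "T1"),
                                make_records("s1", "a1", "A", 1, 1, "T2"))),
    "mixed tissues")
})

test_that("filter_sites applies the 20-read / 2-per-allele rule per subgroup", {
  keep <- make_paired_agg("s1", 18, 2, 30, 30)
  expect_equal(nrow(filter_sites(keep)), 2L)
  drop_allele <- make_paired_agg("s2", 19, 1, 30, 30)
  expect_equal(nrow(filter_sites(drop_allele)), 0L)
  drop_total <- make_paired_agg("s3", 10, 9, 30, 30)
  expect_equal(nrow(filter_sites(drop_total)), 0L)
  # a SNP needs both subgroups passing
  one_sided <- make_agg("s4", "A", 50, 50)
  expect_equal(nrow(filter_sites(one_sided)), 0L)
  expect_equal(nrow(filter_sites(one_sided, require_both = FALSE)), 1L)
})

test_that("filters are monotone: adding reads never drops a kept site", {
  set.seed(7)
  for (i in 1:200) {
    ra <- sample(0:40, 1); aa <- sample(0:40, 1)
    rb <- sample(0:40, 1); ab <- sample(0:40, 1)
    base <- make_paired_agg("s", ra, aa, rb, ab)
    kept <- nrow(filter_sites(base)) > 0
    if (kept) {
      extra <- make_paired_agg("s", ra + sample(0:10, 1), aa + sample(0:10, 1),
                               rb + sample(0:10, 1), ab + sample(0:10, 1))
      expect_gt(nrow(filter_sites(extra)), 0)
    }
  }
})

test_that("call_subgroup_aie flags imbalance at FDR 0.05", {
  balanced <- make_agg("s1", "A", 50, 50)
  expect_false(call_subgroup_aie(balanced)$is_aie)
  skewed <- make_agg("s2", "A", 90, 10)
  expect_true(call_subgroup_aie(skewed)$is_aie)
  # BH within (tissue, subgroup) family: q of the balanced site unaffected
  # by a highly significant site in the other subgroup
  two_fam <- rbind(make_agg("s1", "A", 55, 45), make_agg("s1", "B", 100, 0))
  res <- call_subgroup_aie(two_fam)
  expect_equal(res$q_fdr[res$subgroup == "A"],
               res$p_binomial[res$subgroup == "A"])
})

test_that("subgroup AIE false positives stay near nominal under the null", {
  # 200 simulated families of 100 null sites at depth 100
  set.seed(11)
  fp <- vapply(1:200, function(i) {
    refs <- stats::rbinom(100, 100, 0.5)
    agg <- make_agg(sprintf("s%d", 1:100), "A", refs, 100 - refs)
    sum(call_subgroup_aie(agg)$is_aie)
  }, numeric(1))
  # BH controls expected FDR at 5 of 100 under the full null
  expect_lte(mean(fp), 5 + 3 * stats::sd(fp) / sqrt(200))
})

test_that("call_differential_aie categorises by q, delta and thresholds", {
  sole <- make_paired_agg("s1", 80, 20, 50, 50)
  res <- call_differential_aie(sole)
  expect_equal(res$category, "increasing_ref_frac")
  expect_equal(res$delta, 0.3)
  expect_equal(res$p_value, 2 * pnorm(-0.3 / sqrt(0.65 * 0.35 * 0.02)),
               tolerance = 1e-12)
  expect_false(res$strong_imprinting)

  # |delta| = 0.04 <= 0.1: never categorised regardless of depth
  tiny <- make_paired_agg("s2", 5200, 4800, 4800, 5200)
  expect_equal(call_differential_aie(tiny)$category, "none")

  # delta +0.85: increasing AND strong imprinting
  strong <- make_paired_agg("s3", 950, 50, 100, 900)
  res <- call_differential_aie(strong)
  expect_equal(res$category, "increasing_ref_frac")
  expect_true(res$strong_imprinting)
  expect_equal(res$delta, 0.85)
})

test_that("delta antisymmetry: swapping subgroup labels negates delta", {
  set.seed(5)
  ids <- sprintf("s%02d", 1:30)
  ra <- sample(20:200, 30); aa <- sample(20:200, 30)
  rb <- sample(20:200, 30); ab <- sample(20:200, 30)
  agg <- make_paired_agg(ids, ra, aa, rb, ab)
  swapped <- agg
  swapped$subgroup <- ifelse(agg$subgroup == "A", "B", "A")
  r1 <- call_differential_aie(agg)
  r2 <- call_differential_aie(swapped)
  r2 <- r2[match(r1$snp_id, r2$snp_id), ]
  expect_equal(r2$delta, -r1$delta)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
  flip <- c(increasing_ref_frac = "decreasing_ref_frac",
            decreasing_ref_frac = "increasing_ref_frac", none = "none")
  expect_equal(unname(flip[r1$category]), r2$category)
})

test_that("gene_level_aie picks the best qualifying SNP with stated ties", {
  diff <- data.frame(
    snp_id = c("s1", "s2", "s3", "s4", "s5"),
    tissue = "T1",
    delta = c(-0.2, 0.15, -0.3, 0.15, 0.05),
    q_fdr = c(0.01, 0.001, 0.002, 0.002, 0.5),
    category = c("decreasing_ref_frac", "increasing_ref_frac",
                 "decreasing_ref_frac", "increasing_ref_frac", "none"),
    stringsAsFactors = FALSE)
  asg <- data.frame(snp_id = c("s1", "s2", "s3", "s4", "s5"),
                    gene_id = c("g1", "g1", "g2", "g2", "g3"),
                    stringsAsFactors = FALSE)
  out <- gene_level_aie(diff, asg)
  # g1: min q wins (s2, increasing)
  expect_equal(out$category[out$gene_id == "g1"], "increasing_ref_frac")
  expect_equal(out$best_snp_id[out$gene_id == "g1"], "s2")
  # g2: equal q, |delta| tiebreak (s3, decreasing)
  expect_equal(out$category[out$gene_id == "g2"], "decreasing_ref_frac")
  expect_equal(out$best_snp_id[out$gene_id == "g2"], "s3")
  # g3: only none SNPs
  expect_equal(out$category[out$gene_id == "g3"], "none")
})
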