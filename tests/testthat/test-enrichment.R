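test_that("fisher_enrichment builds the 2x2 table within the universe", {
  uni <- gene_set("u", sprintf("g%03d", 1:100))
  query <- gene_set("q", sprintf("g%03d", 1:10))
  anno <- gene_set("s", sprintf("g%03d", 6:20))
  res <- fisher_enrichment(query, anno, uni)
  expect_equal(c(res$a, res$b, res$c, res$d), c(5, 5, 10, 80))
  expect_equal(res$fold_enrichment, (5 / 10) / (15 / 100))
  # genes outside the universe are discarded first
  query2 <- gene_set("q", c(query$gene_ids, "offworld1", "offworld2"))
  expect_equal(fisher_enrichment(query2, anno, uni)$a, 5)
  # flat table: no association
  u4 <- gene_set("u", c("a", "b", "c", "d"))
  res <- fisher_enrichment(gene_set("q", c("a", "b")),
                           gene_set("s", c("a", "c")), u4)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p_value, 1)
  # annotation = universe: fold enrichment is exactly 1
  expect_equal(fisher_enrichment(query, uni, uni)$fold_enrichment, 1)
  expect_error(fisher_enrichment(gene_set("q", "nowhere"), anno, uni),
               "empty after intersecting")
})

test_that("Fisher p agrees with fisher.test for random tables with N <= 200", {
  set.seed(13)
  for (i in 1:300) {
    n_total <- sample(4:200, 1)
    a <- sample(0:min(50, n_total - 3), 1)
    rest <- n_total - a
    b <- sample(0:rest, 1)
    c_ <- sample(0:(rest - b), 1)
    d <- rest - b - c_
    expect_equal(
      recipase:::fisher_exact_p(a, b, c_, d),
      stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
      tolerance = 1e-9,
      info = sprintf("table %d,%d,%d,%d", a, b, c_, d))
  }
})

test_that("one-sided Fisher matches the hypergeometric upper tail", {
  uni <- gene_set("u", sprintf("g%03d", 1:60))
  q <- gene_set("q", sprintf("g%03d", 1:12))
  s <- gene_set("s", sprintf("g%03d", 9:24))
  res <- fisher_enrichment(q, s, uni, alternative = "greater")
  expect_equal(res$p_value,
               stats::fisher.test(matrix(c(res$a, res$b, res$c, res$d), 2,
                                         byrow = TRUE),
                                  alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("fold_enrichment reproduces the published worked arithmetic", {
  # 5 of 37 genes vs a 4.1% background: 3.296... reported as 3.3
  expect_equal(round_half_away(fold_enrichment(5, 37, 0.041)), 3.3)
  # 4 of 37 ChrX genes vs 3.4%: reported as 3.2
  expect_equal(round_half_away(fold_enrichment(4, 37, 0.034)), 3.2)
  # 10 of 97 vs 1/34: reported as 3.5
  expect_equal(round_half_away(fold_enrichment(10, 97, 1 / 34)), 3.5)
  # self-background is always 1
  for (k in c(1, 5, 12)) expect_equal(fold_enrichment(k, 20, k / 20), 1)
  expect_error(fold_enrichment(10, 5, 0.1), "exceeds")
  expect_error(fold_enrichment(1, 5, 0), "background_proportion")
})

test_that("table-derived and proportion-derived fold enrichment agree", {
  set.seed(19)
  uni_ids <- sprintf("g%04d", 1:500)
  for (i in 1:25) {
    q <- sample(uni_ids, sample(10:80, 1))
    s <- sample(uni_ids, sample(10:200, 1))
    res <- fisher_enrichment(gene_set("q", q), gene_set("s", s),
                             gene_set("u", uni_ids))
    if (res$a + res$c == 0) next
    expect_equal(res$fold_enrichment,
                 fold_enrichment(res$a, res$a + res$b,
                                 (res$a + res$c) / 500),
                 tolerance = 1e-12)
  }
})

test_that("crosswalk battery flags the planted AIE/DE coupling", {
  uni_ids <- sprintf("g%04d", 1:400)
  # plant: all 25 decreasing-AIE genes are up-DE; everything else null
  dec_genes <- uni_ids[1:25]
  gene_aie <- data.frame(
    gene_id = c(dec_genes, uni_ids[26:40]),
    tissue = "NAcc",
    category = c(rep("decreasing_ref_frac", 25),
                 rep("increasing_ref_frac", 15)),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = uni_ids,
                   log2FC = c(rep(1, 30), rep(-1, 30), rep(0.1, 340)),
                   pvalue = c(rep(0.001, 60), rep(0.9, 340)),
                   stringsAsFactors = FALSE)
  out <- crosswalk_aie_de_enrichment(gene_aie, de, gene_set("u", uni_ids))
  expect_equal(nrow(out), 4L)
  best <- out[which.min(out$q_fdr), ]
  expect_equal(best$aie_category, "decreasing_ref_frac")
  expect_equal(best$de_direction, "up")
  expect_equal(best$a, 25L)
})

test_that("crosswalk yields p = 1, a = 0 cells when no AIE genes qualify", {
  uni <- gene_set("u", sprintf("g%04d", 1:100))
  gene_aie <- data.frame(gene_id = "g0001", tissue = "VTA",
                         category = "none", stringsAsFactors = FALSE)
  de <- data.frame(gene_id = sprintf("g%04d", 1:100),
                   log2FC = rnorm(100), pvalue = runif(100, 0.001, 0.04),
                   stringsAsFactors = FALSE)
  out <- crosswalk_aie_de_enrichment(gene_aie, de, uni)
  expect_equal(nrow(out), 4L)
  expect_true(all(out$a == 0))
  expect_true(all(out$p_value == 1))
})

test_that("crosswalk false-positive rate is nominal under label shuffles", {
  # permutation oracle: randomised AIE labels should give ~5% of cells
  # with p < 0.05
  set.seed(23)
  uni_ids <- sprintf("g%04d", 1:300)
  de <- data.frame(gene_id = uni_ids,
                   log2FC = rnorm(300),
                   pvalue = runif(300),
                   stringsAsFactors = FALSE)
  hits <- 0L; cells <- 0L
  for (perm in 1:200) {
    aie_genes <- sample(uni_ids, 40)
    gene_aie <- data.frame(
      gene_id = aie_genes, tissue = "T1",
      category = sample(c("increasing_ref_frac", "decreasing_ref_frac"),
                        40, replace = TRUE),
      stringsAsFactors = FALSE)
    out <- crosswalk_aie_de_enrichment(gene_aie, de, gene_set("u", uni_ids))
    hits <- hits + sum(out$p_value < 0.05)
    cells <- cells + nrow(out)
  }
  # exact-test discreteness makes the attained rate conservative
  expect_lte(hits / cells, 0.07)
})

test_that("gene_set_battery crosses sets with order-invariant BH", {
  uni_ids <- sprintf("g%04d", 1:200)
  queries <- list(gene_set("q1", uni_ids[1:30]),
                  gene_set("q2", uni_ids[31:70]))
  annos <- list(gene_set("chrx", uni_ids[c(1:10, 100:120)]),
                gene_set("gwas", uni_ids[c(25:40, 150:160)]))
  bat <- gene_set_battery(queries, annos, gene_set("u", uni_ids))
  expect_equal(nrow(bat), 4L)
  bat_rev <- gene_set_battery(rev(queries), rev(annos),
                              gene_set("u", uni_ids))
  bat_rev <- bat_rev[match(paste(bat$query_name, bat$set_name),
                           paste(bat_rev$query_name, bat_rev$set_name)), ]
  expect_equal(bat$q_fdr, bat_rev$q_fdr)
  # disjoint query and rare annotation: a = 0, fold 0
  uni2 <- gene_set("u", sprintf("h%03d", 1:150))
  bat2 <- gene_set_battery(gene_set("q", sprintf("h%03d", 1:20)),
                           gene_set("s", "h150"), uni2)
  expect_equal(bat2$a, 0L)
  expect_equal(bat2$fold_enrichment, 0)
  expect_equal(bat2$p_value, 1)
})
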