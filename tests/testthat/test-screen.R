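test_that("VAF is alt/total with zero-depth treated as missing", {
  tab <- tiny_table(rbind(c(4L, 0L, 7L)), rbind(c(8L, 0L, 7L)), pos = 5L)
  v <- compute_vaf(tab)$vaf[1, ]
  expect_equal(unname(v), c(0.5, NA, 1.0))
})

test_that("worked example: graded VAF vs labels", {
  v <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  y <- c(0, 0, 0, 1, 1, 1)
  cfg <- screen_config(min_informative_samples = 4)
  rec <- correlate_variant(v, y, cfg)
  expect_equal(rec$r_s, oracle_spearman(v, y), tolerance = 1e-12)
  expect_equal(rec$r_s, 0.8783101, tolerance = 1e-6)
  expect_equal(rec$p_mwu, oracle_mwu_exact_p(v[y == 1], v[y == 0]),
               tolerance = 1e-12)
  expect_equal(rec$p_mwu, 0.1, tolerance = 1e-12)
  # perfect separation on binary VAF
  rec2 <- correlate_variant(c(0, 0, 0, 1, 1, 1), y, cfg)
  expect_equal(rec2$r_s, 1)
  expect_equal(classify_fta(rec2$r_s), "very_strong")
})

test_that("degenerate rows are flagged, not crashed", {
  cfg <- screen_config(min_informative_samples = 4)
  expect_equal(correlate_variant(rep(0.5, 6), c(0, 0, 0, 1, 1, 1), cfg)$status,
               "undefined")
  expect_equal(correlate_variant(runif(6), rep(1, 6), cfg)$status,
               "untestable")
  expect_equal(correlate_variant(c(0.2, 0.4, NA, NA, NA, NA),
                                 c(0, 0, 0, 1, 1, 1), cfg)$status,
               "untestable")
  # n_used counts only informative samples
  rec <- correlate_variant(c(0.1, NA, 0.3, 0.7, NA, 0.9),
                           c(0, 0, 0, 1, 1, 1), cfg)
  expect_equal(rec$n_used, 4)
})

test_that("coefficients and exact MWU match brute-force oracles on random instances", {
  set.seed(123)
  cfg <- screen_config(min_informative_samples = 4)
  for (i in 1:200) {
    n1 <- sample(2:5, 1); n0 <- sample(2:5, 1)
    v <- round(runif(n0 + n1), 3)
    if (anyDuplicated(v)) next   # oracles assume tie-free VAF
    y <- c(rep(0, n0), rep(1, n1))
    rec <- correlate_variant(v, y, cfg)
    expect_equal(rec$r_s, oracle_spearman(v, y), tolerance = 1e-12)
    expect_equal(rec$tau, oracle_kendall_taub(v, y), tolerance = 1e-12)
    expect_equal(rec$p_mwu, oracle_mwu_exact_p(v[y == 1], v[y == 0]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.5), 0.5)
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
  p <- sort(runif(10))
  expect_true(all(diff(adjust_bh(p)) >= 0))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("FTA classification uses inclusive |r_s| thresholds", {
  expect_equal(classify_fta(c(-0.63, 0.64, -0.44, 0.39, 0.4, 0.6, NA)),
               c("very_strong", "very_strong", "strong", "none", "strong",
                 "very_strong", "none"))
})

test_that("swapping the type coding negates coefficients, keeps p and FTA", {
  set.seed(31)
  cfg <- screen_config(min_informative_samples = 4)
  flipped <- screen_config(min_informative_samples = 4,
                           type_coding = c(linseed = 1, fiber = 0))
  for (i in 1:20) {
    v <- runif(12)
    y <- sample(rep(0:1, 6))
    a <- correlate_variant(v, y, cfg)
    b <- correlate_variant(v, 1 - y, cfg)
    expect_equal(a$r_s, -b$r_s, tolerance = 1e-12)
    expect_equal(a$r_p, -b$r_p, tolerance = 1e-12)
    expect_equal(a$tau, -b$tau, tolerance = 1e-12)
    expect_equal(a$p_s, b$p_s, tolerance = 1e-12)
    expect_equal(a$p_mwu, b$p_mwu, tolerance = 1e-10)
    expect_equal(classify_fta(a$r_s, cfg), classify_fta(b$r_s, flipped))
  }
})

test_that("|r_s| ordering matches Mann-Whitney separation on tie-free data", {
  set.seed(57)
  y <- sample(rep(0:1, c(7, 8)))
  n0 <- sum(y == 0); n1 <- sum(y == 1)
  stat <- t(sapply(1:30, function(i) {
    v <- runif(15)
    u <- sum(outer(v[y == 1], v[y == 0], ">"))
    c(abs(oracle_spearman(v, y)), abs(u - n0 * n1 / 2))
  }))
  expect_equal(order(stat[, 1]), order(stat[, 2]))
})

test_that("gene and family summaries tally per-variant records", {
  panel <- tibble::tibble(chrom = "Lu1",
                          start = c(0L, 5000L, 10000L), gene_id = c("a", "b", "c"),
                          end = c(1000L, 6000L, 11000L),
                          family = c("f1", "f1", "f2"), strand = "+")
  records <- tibble::tibble(
    variant_id = paste0("v", 1:4),
    gene_ids = c("a", "a", "a", "b"),
    r_s = c(0.45, -0.62, 0.1, NA))
  genes <- summarize_genes(records, panel)
  a <- genes[genes$gene_id == "a", ]
  expect_equal(a$n_fta_strong, 2L)
  expect_equal(a$n_fta_very_strong, 1L)
  expect_equal(a$max_abs_rs, 0.62)
  expect_equal(genes$n_fta_strong[genes$gene_id == "c"], 0L)
  # report omits FTA-free genes, full table keeps them
  expect_equal(fta_report(genes)$gene_id, "a")
  fam <- summarize_families(genes, panel)
  expect_equal(fam$fraction[fam$family == "f1"], 0.5)
  expect_equal(fam$fraction[fam$family == "f2"], 0)
})

test_that("the screen recovers associated variants on a synthetic cohort", {
  cfg <- cohort_config(panel = flax_gene_panel()[seq(1, 424, 18), ],
                       delta = 1, base_error = 0, seed = 61,
                       frac_associated_genes = 0.3)
  cohort <- simulate_cohort(cfg)
  scr <- screen_associations(filter_supported(simulate_read_support(cohort, cfg)),
                             cohort$manifest, cohort$panel)
  j <- dplyr::left_join(scr$variants,
                        cohort$truth[, c("variant_id", "is_associated")],
                        by = "variant_id")
  assoc <- j[j$is_associated & j$status == "ok", ]
  expect_true(all(assoc$fta_class == "very_strong"))
  expect_true(all(abs(assoc$r_s) == 1))
  # per-gene counts equal a brute-force recount from per-variant records
  recount <- table(j$gene_ids[j$fta_class != "none"])
  for (g in names(recount))
    expect_equal(scr$genes$n_fta_strong[scr$genes$gene_id == g],
                 unname(recount[g]))
  # family fractions recover the designated fraction (gene subsets are small,
  # so allow one gene of slack per family)
  expect_equal(sum(scr$genes$n_fta_strong >= 1),
               length(unique(cohort$truth$gene_id[cohort$truth$is_associated])))
  # glance is internally consistent
  g <- glance(scr)
  expect_equal(g$n_genes_with_fta, sum(scr$genes$n_fta_strong >= 1))
  expect_equal(g$n_fta_strong, sum(scr$variants$fta_class != "none"))
})

test_that("detection power is monotone in the group frequency difference", {
  panel <- flax_gene_panel()[seq(1, 424, 18), ]
  rates <- sapply(c(0.1, 0.3, 0.5, 1.0), function(d) {
    cfg <- cohort_config(panel = panel, delta = d, seed = 71,
                         frac_associated_genes = 0.5)
    cohort <- simulate_cohort(cfg)
    scr <- screen_associations(
      filter_supported(simulate_read_support(cohort, cfg)),
      cohort$manifest, cohort$panel)
    j <- dplyr::left_join(scr$variants,
                          cohort$truth[, c("variant_id", "is_associated")],
                          by = "variant_id")
    mean(j$fta_class[j$is_associated] != "none")
  })
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[4], 0.95)
})
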