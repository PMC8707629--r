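small_cfg <- function(...) {
  # 12-gene panel keeps simulation tests fast
  cohort_config(panel = flax_gene_panel()[seq(1, 424, by = 36), ], ...)
}

test_that("simulated cohorts honour group sizes and truth invariants", {
  cfg <- small_cfg(seed = 3)
  cohort <- simulate_cohort(cfg)
  expect_equal(sum(cohort$manifest$type_label == "fiber"), 79)
  expect_equal(sum(cohort$manifest$type_label == "linseed"), 112)
  truth <- cohort$truth
  gap <- abs(truth$p_fiber - truth$p_linseed)
  expect_true(all(abs(gap[truth$is_associated] - cfg$delta) < 1e-12))
  expect_true(all(gap[!truth$is_associated] == 0))
  expect_true(all(truth$genotype %in% 0:2))
  # all placements inside flanked regions of their gene
  reg <- flaxfta:::flanked_regions(cohort$panel)
  j <- match(truth$gene_id, reg$gene_id)
  expect_true(all(truth$pos >= reg$region_start[j] &
                    truth$pos < reg$region_end[j]))
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_read_support(a, cfg), simulate_read_support(b, cfg))
  c <- simulate_cohort(small_cfg(seed = 6))
  expect_false(identical(a$truth$pos, c$truth$pos))
})

test_that("degenerate settings behave as constructed", {
  cfg0 <- small_cfg(frac_associated_genes = 0, seed = 9)
  expect_equal(sum(simulate_cohort(cfg0)$truth$is_associated), 0)
  cfg1 <- small_cfg(delta = 1, seed = 9)
  truth <- simulate_cohort(cfg1)$truth
  fib <- grepl("^F", colnames(truth$genotype))
  at <- which(truth$is_associated & truth$p_fiber == 1)
  expect_true(all(truth$genotype[at, fib] == 2))
  expect_true(all(truth$genotype[at, !fib] == 0))
})

test_that("read support follows the binomial depth model", {
  cfg <- small_cfg(base_error = 0, seed = 13)
  cohort <- simulate_cohort(cfg)
  tab <- simulate_read_support(cohort, cfg)
  g <- cohort$truth$genotype
  # genotype 2, no error: every read is alt; genotype 0: none
  expect_true(all(tab$ad[g == 2] == tab$dp[g == 2]))
  expect_true(all(tab$ad[g == 0] == 0))
  # Monte-Carlo: VAF at heterozygous sites averages 0.5 within 3 SE
  cfg_het <- small_cfg(base_error = 0, inbreeding = 0, seed = 17,
                       base_freq = c(5, 5), mean_depth = 20)
  cohort <- simulate_cohort(cfg_het)
  tab <- simulate_read_support(cohort, cfg_het)
  het <- cohort$truth$genotype == 1 & tab$dp > 0
  vafs <- (tab$ad / tab$dp)[het]
  n <- sum(het)
  expect_gt(n, 10000)
  se <- stats::sd(vafs) / sqrt(n)
  expect_lt(abs(mean(vafs) - 0.5), 3 * se)
})

test_that("per-group allele frequencies converge to truth at large n", {
  cfg <- cohort_config(n_fiber = 2000, n_linseed = 2000,
                       panel = flax_gene_panel()[1:3, ],
                       variants_per_gene = 4, delta = 0.5, seed = 21)
  cohort <- simulate_cohort(cfg)
  truth <- cohort$truth
  fib <- cohort$manifest$type_label == "fiber"
  emp_f <- rowMeans(truth$genotype[, fib]) / 2
  emp_l <- rowMeans(truth$genotype[, !fib]) / 2
  # inbred lines: genotype/2 is Bernoulli(p); binomial 99.9% CI half-width
  ci <- 3.3 * sqrt(truth$p_fiber * (1 - truth$p_fiber) / 2000 + 1e-6)
  expect_true(all(abs(emp_f - truth$p_fiber) < ci))
  expect_true(all(abs(emp_l - truth$p_linseed) < ci))
})

test_that("a less diverse fiber group yields fewer fiber-only polymorphisms", {
  # lower allele-frequency diversity for fiber emulated by copying fiber
  # genotypes from a near-monomorphic spectrum
  cfg_div <- small_cfg(seed = 25, frac_associated_genes = 0)
  cohort <- simulate_cohort(cfg_div)
  tab <- simulate_read_support(cohort, cfg_div)
  fib <- cohort$manifest$type_label == "fiber"
  # make the fiber group near-monomorphic: keep only its major allele state
  g <- cohort$truth$genotype
  major <- ifelse(rowMeans(g[, fib]) >= 1, 2L, 0L)
  g_mono <- g
  g_mono[, fib] <- matrix(major, nrow(g), sum(fib))
  cohort$truth$genotype <- g_mono
  tab2 <- simulate_read_support(cohort, cfg_div)
  poly_in <- function(t, idx) {
    sub <- t; sub$ad <- t$ad[, idx, drop = FALSE]; sub$dp <- t$dp[, idx, drop = FALSE]
    nrow(filter_supported(sub))
  }
  expect_lt(poly_in(tab2, fib), poly_in(tab2, !fib))
})

test_that("expression simulation has tissue-structured markers", {
  e <- simulate_expression(n_genes = 150, samples_per_tissue = 3, seed = 31)
  expect_equal(dim(e$counts), c(150, 3 * length(flax_tissues())))
  cpm <- cpm_normalize(e$counts, e$library_sizes)
  agg <- tissue_aggregate(cpm, e$sample_meta)
  markers <- which(e$truth$is_marker)
  top <- colnames(agg)[apply(agg[markers, , drop = FALSE], 1, which.max)]
  expect_gt(mean(top == e$truth$marker_tissue[markers]), 0.95)
})
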