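test_that("Fisher p-values match closed-form extreme and modal tables", {
  # (10,0 | 0,10): only the two extreme tables qualify; p = 2 / choose(20,10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / 184756, tolerance = 1e-12)
  # balanced table is the mode: every table qualifies, p = 1
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  expect_error(fisher_exact_2x2(0, 0, 3, 4), "empty")
})

test_that("Fisher p matches enumeration and stats::fisher.test on random tables", {
  set.seed(61)
  n <- 500L
  a <- sample(0:25, n, replace = TRUE); b <- sample(0:25, n, replace = TRUE)
  cc <- sample(0:25, n, replace = TRUE); d <- sample(0:25, n, replace = TRUE)
  bad <- (a + b == 0) | (cc + d == 0)
  a[bad] <- 1L
  cc[bad] <- 1L
  p <- fisher_exact_2x2(a, b, cc, d)
  for (i in seq_len(n)) {
    expect_equal(p[i], oracle_fisher(a[i], b[i], cc[i], d[i]),
                 tolerance = 1e-9)
  }
  # spot-check against the reference implementation
  for (i in sample(n, 50)) {
    ref <- stats::fisher.test(matrix(c(a[i], b[i], cc[i], d[i]), 2,
                                     byrow = TRUE))$p.value
    expect_equal(p[i], ref, tolerance = 1e-9)
  }
})

test_that("Fisher test is symmetric under sample swap", {
  set.seed(67)
  a <- sample(0:30, 100, TRUE) + 1L; b <- sample(0:30, 100, TRUE)
  cc <- sample(0:30, 100, TRUE) + 1L; d <- sample(0:30, 100, TRUE)
  expect_equal(fisher_exact_2x2(a, b, cc, d),
               fisher_exact_2x2(cc, d, a, b), tolerance = 1e-12)
})

test_that("a difference of exactly one third is not a strong DMC", {
  cnt <- data.table::rbindlist(list(
    counts_fixture("chr1", 1L, "A", 25L, 30L),   # level 5/6
    counts_fixture("chr1", 1L, "B", 15L, 30L)))  # level 1/2
  dmc <- call_strong_dmcs(cnt, c("A", "B"))
  expect_equal(dmc$delta, 1 / 3)
  expect_lt(dmc$p_value, 0.05)
  expect_false(dmc$is_strong)          # strict > on |delta|
  # identical counts: delta 0, p 1, never strong
  cnt2 <- counts_fixture("chr1", c(1L, 1L), c("A", "B"), 12L, 30L)
  dmc2 <- call_strong_dmcs(cnt2, c("A", "B"))
  expect_equal(dmc2$delta, 0)
  expect_equal(dmc2$p_value, 1)
  expect_false(dmc2$is_strong)
})

test_that("direction follows the sign of delta (A minus B)", {
  cnt <- data.table::rbindlist(list(
    counts_fixture("chr1", c(1L, 2L), "A", c(28L, 2L), 30L),
    counts_fixture("chr1", c(1L, 2L), "B", c(2L, 28L), 30L)))
  dmc <- call_strong_dmcs(cnt, c("A", "B"))
  expect_equal(dmc$direction, c("hyper", "hypo"))
  expect_true(all(dmc$is_strong))
})

test_that("strong DMCs chain into DMRs by gap and direction", {
  mk_dmc <- function(pos, dir) data.table::data.table(
    chrom = "chr1", pos = pos,
    delta = if (dir == "hyper") 0.5 else -0.5,
    p_value = 1e-4, direction = dir, is_strong = TRUE,
    comparison = "A_vs_B")
  lv <- data.table::data.table(chrom = "chr1",
                               pos = c(100L, 250L, 420L, 2000L, 2100L),
                               A = c(0.2, 0.4, 0.6, 0.9, 0.9),
                               B = c(0.7, 0.8, 0.9, 0.2, 0.2))
  dmcs <- mk_dmc(c(100L, 250L, 420L), "hyper")
  dmrs <- call_dmrs(dmcs, lv, max_gap = 300L, min_cpgs = 3L)
  expect_equal(nrow(dmrs), 1L)
  expect_equal(c(dmrs$start, dmrs$end), c(100L, 421L))
  expect_equal(dmrs$n_cpgs, 3L)
  # region level is the unweighted mean of constituent CpG levels
  expect_equal(dmrs$level_A, mean(c(0.2, 0.4, 0.6)))
  expect_equal(dmrs$level_B, mean(c(0.7, 0.8, 0.9)))
  # two DMCs are below min_cpgs
  expect_equal(nrow(call_dmrs(mk_dmc(c(2000L, 2100L), "hypo"), lv)), 0L)
  # a gap beyond max_gap splits the chain
  dmcs3 <- mk_dmc(c(100L, 250L, 420L, 2000L, 2100L), "hyper")
  lv2 <- data.table::rbindlist(list(lv))
  dmrs3 <- call_dmrs(dmcs3, lv2, max_gap = 300L, min_cpgs = 3L)
  expect_equal(nrow(dmrs3), 1L)   # trailing pair too short
})

test_that("DMR constituents are same-direction strong DMCs within bounds", {
  set.seed(71)
  pos <- sort(sample(1:50000, 400))
  cntA <- counts_fixture("chr1", pos, "A", rbinom(400, 30, 0.8), 30L)
  cntB <- counts_fixture("chr1", pos, "B", rbinom(400, 30, 0.2), 30L)
  cnt <- data.table::rbindlist(list(cntA, cntB))
  dmc <- call_strong_dmcs(cnt, c("A", "B"))
  lv <- methylation_levels(cnt)
  dmrs <- call_dmrs(dmc, lv)
  expect_gt(nrow(dmrs), 0L)
  strong_pos <- dmc[is_strong == TRUE & direction == "hyper", pos]
  for (i in seq_len(nrow(dmrs))) {
    cp <- dmrs$cpg_pos[[i]]
    expect_true(all(cp %in% strong_pos))
    expect_true(all(diff(cp) <= 300L))
    # region level inside the convex hull of constituent levels
    sub <- lv[pos %in% cp]
    expect_gte(dmrs$level_A[i], min(sub$A))
    expect_lte(dmrs$level_A[i], max(sub$A))
  }
})

test_that("overlapping DMRs merge transitively with recomputed levels", {
  lv <- data.table::data.table(chrom = "chr1",
                               pos = c(120L, 180L, 320L, 390L),
                               A = c(0.1, 0.9, 0.5, 0.5),
                               B = c(0.2, 0.2, 0.2, 0.2))
  mk <- function(start, end) data.table::data.table(
    chrom = "chr1", start = start, end = end, comparison = "x",
    direction = "hyper", n_cpgs = 2L, level_A = 0.99, level_B = 0.01)
  merged <- merge_dmr_sets(mk(100L, 200L), mk(150L, 250L), lv)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(100L, 250L))
  # level recomputed from the CpG table, not from the parents
  expect_equal(merged$level_A, mean(c(0.1, 0.9)))
  expect_equal(merged$n_cpgs, 2L)
  # disjoint DMRs pass through unchanged
  kept <- merge_dmr_sets(mk(100L, 200L), mk(300L, 400L), lv)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$level_A, c(0.99, 0.99))
  expect_false(any(kept$merged))
})

test_that("DMC set comparison is exact set algebra", {
  a <- data.table::data.table(chrom = "chr1", pos = c(1L, 2L, 3L))
  b <- data.table::data.table(chrom = "chr1", pos = c(2L, 3L, 4L))
  cmp <- compare_dmc_sets(a, b)
  expect_equal(cmp$n_common, 2L)
  expect_equal(cmp$n_only_a, 1L)
  expect_equal(cmp$n_only_b, 1L)
  expect_equal(cmp$n_common + cmp$n_only_a, nrow(a))
  expect_equal(cmp$n_common + cmp$n_only_b, nrow(b))
  same <- compare_dmc_sets(a, a)
  expect_equal(same$n_common, 3L)
  expect_equal(same$n_only_a + same$n_only_b, 0L)
  disj <- compare_dmc_sets(a, data.table::data.table(chrom = "chr2",
                                                     pos = 1:3))
  expect_equal(disj$n_common, 0L)
  # brute-force set-algebra oracle on random site sets
  set.seed(79)
  pa <- sample(1:500, 200); pb <- sample(1:500, 200)
  cmp2 <- compare_dmc_sets(data.table::data.table(chrom = "c", pos = pa),
                           data.table::data.table(chrom = "c", pos = pb))
  expect_equal(cmp2$n_common, length(intersect(pa, pb)))
  expect_equal(cmp2$n_only_a, length(setdiff(pa, pb)))
  expect_equal(cmp2$n_only_b, length(setdiff(pb, pa)))
})

test_that("volcano table reports delta and Fisher p per common site", {
  cnt <- data.table::rbindlist(list(
    counts_fixture("chr1", c(1L, 2L), "s1", c(30L, 10L), 30L),
    counts_fixture("chr1", c(1L, 2L), "s2", c(0L, 10L), 30L)))
  sites <- data.table::data.table(chrom = "chr1", pos = c(1L, 2L, 9L))
  expect_message(vt <- volcano_table(sites, cnt, c("s1", "s2")), "skipped")
  expect_equal(nrow(vt), 2L)   # row conservation: |common| - |skipped|
  expect_equal(vt[pos == 1L, delta], 1)
  expect_equal(vt[pos == 1L, p_value], oracle_fisher(30L, 0L, 0L, 30L),
               tolerance = 1e-9)
  expect_equal(vt[pos == 2L, .(delta, p_value)],
               data.table::data.table(delta = 0, p_value = 1))
})
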