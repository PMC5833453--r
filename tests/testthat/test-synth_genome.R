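test_that("generated promoters span exactly TSS +/- 1 kb and counts match", {
  g <- generate_genome(n_contigs = 1L, contig_length = 250000L,
                       n_promoters = 10L, n_repeats = 5L,
                       n_imprinted_clusters = 1L, seed = 42L)
  proms <- g$catalogue[feature_class == "promoter"]
  expect_equal(nrow(proms), 10L)
  expect_true(all(proms$end - proms$start == 2000L))
  # promoter interval anchored on the recorded TSS
  m <- merge(proms, g$tss, by.x = "name", by.y = "gene")
  expect_true(all(m$start == m$pos - 1000L & m$end == m$pos + 1000L))
  # every imprinted cluster contains a gDMR sub-interval
  imp <- g$catalogue[feature_class == "imprinted_cluster"]
  gd <- g$catalogue[feature_class == "gDMR"]
  expect_equal(nrow(imp), 1L)
  expect_true(all(gd$start >= imp$start & gd$end <= imp$end))
})

test_that("genome generation is deterministic given the seed", {
  g1 <- generate_genome(n_contigs = 2L, contig_length = 50000L,
                        n_promoters = 4L, n_repeats = 6L,
                        n_imprinted_clusters = 1L, seed = 7L)
  g2 <- generate_genome(n_contigs = 2L, contig_length = 50000L,
                        n_promoters = 4L, n_repeats = 6L,
                        n_imprinted_clusters = 1L, seed = 7L)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$catalogue, g2$catalogue)
  g3 <- generate_genome(n_contigs = 2L, contig_length = 50000L,
                        n_promoters = 4L, n_repeats = 6L,
                        n_imprinted_clusters = 1L, seed = 8L)
  expect_false(identical(g1$genome, g3$genome))
})

test_that("CpG-rich promoters contain a window passing the island rule", {
  g <- generate_genome(n_contigs = 1L, contig_length = 200000L,
                       n_promoters = 12L, n_repeats = 0L,
                       n_imprinted_clusters = 0L,
                       cpg_island_fraction = 1, seed = 3L)
  proms <- g$catalogue[feature_class == "promoter"]
  # exhaustive window scan: some 500-bp window with O/E >= 0.75 and GC >= 0.55
  for (i in seq_len(nrow(proms))) {
    s <- substr(g$genome[[proms$chrom[i]]], proms$start[i] + 1L, proms$end[i])
    expect_identical(oracle_promoter_class(s), "HCP")
  }
})

test_that("infeasible feature packing raises a sizing error", {
  expect_error(
    generate_genome(n_contigs = 1L, contig_length = 10000L,
                    n_promoters = 50L, n_repeats = 0L,
                    n_imprinted_clusters = 0L, seed = 1L),
    "packing|capacity")
})

test_that("cpg_sites equals a brute-force forward-strand scan", {
  set.seed(11)
  for (rep in 1:5) {
    s <- random_seq(2000)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    expected <- which(chars[-length(chars)] == "C" & chars[-1] == "G") - 1L
    got <- cpg_sites(c(chr1 = s))
    expect_identical(got$pos, as.integer(expected))
  }
})

test_that("state map covers the CpG universe once per cell type", {
  g <- generate_genome(n_contigs = 1L, contig_length = 60000L,
                       n_promoters = 4L, n_repeats = 8L,
                       n_imprinted_clusters = 1L, seed = 5L)
  sm <- assign_methylation_states(g$genome, g$catalogue, seed = 5L)
  n_cpg <- nrow(cpg_sites(g$genome))
  for (ct in unique(sm$cell_type)) {
    sub <- sm[cell_type == ct]
    expect_equal(nrow(sub), n_cpg)
    expect_false(anyDuplicated(paste(sub$chrom, sub$pos)) > 0)
    expect_true(all(sub$m_true >= 0 & sub$m_true <= 1))
  }
  # deterministic given seed
  sm2 <- assign_methylation_states(g$genome, g$catalogue, seed = 5L)
  expect_identical(sm, sm2)
})

test_that("an all-low profile yields near-zero methylation everywhere", {
  g <- generate_genome(n_contigs = 1L, contig_length = 1000000L,
                       n_promoters = 4L, n_repeats = 8L,
                       n_imprinted_clusters = 1L, seed = 2L)
  prof <- default_profiles()[1]
  prof[[1]]$params[, `:=`(weight_high = 0, alpha_low = 1, beta_low = 99)]
  sm <- assign_methylation_states(g$genome, g$catalogue, prof, seed = 2L)
  expect_gt(nrow(sm), 1e4)            # enough CpGs for the mean to settle
  expect_lt(mean(sm$m_true), 0.05)    # Beta(1, 99) expectation is 0.01
})

test_that("gDMRs under a forced-high profile are near-fully methylated", {
  g <- generate_genome(n_contigs = 1L, contig_length = 100000L,
                       n_promoters = 2L, n_repeats = 2L,
                       n_imprinted_clusters = 2L, seed = 9L)
  prof <- default_profiles()["4F-like"]
  prof[[1]]$params[feature_class == "gDMR",
                   `:=`(weight_high = 1, alpha_high = 99, beta_high = 1)]
  sm <- assign_methylation_states(g$genome, g$catalogue, prof, seed = 9L)
  gd <- g$catalogue[feature_class == "gDMR"]
  in_gdmr <- rep(FALSE, nrow(sm))
  for (i in seq_len(nrow(gd)))
    in_gdmr <- in_gdmr | (sm$chrom == gd$chrom[i] & sm$pos >= gd$start[i] &
                            sm$pos < gd$end[i])
  expect_gt(sum(in_gdmr), 10)
  expect_gt(mean(sm$m_true[in_gdmr]), 0.9)   # Beta(99, 1) mean = 0.99
})

test_that("default profiles order the high-methylation fraction 4F > C > ESC", {
  g <- generate_genome(n_contigs = 1L, contig_length = 400000L,
                       n_promoters = 10L, n_repeats = 30L,
                       n_imprinted_clusters = 2L, seed = 13L)
  sm <- assign_methylation_states(g$genome, g$catalogue, seed = 13L)
  frac <- sapply(split(sm$m_true, sm$cell_type), function(m) mean(m >= 0.8))
  expect_gt(frac[["4F-like"]], frac[["C-like"]])
  expect_gt(frac[["C-like"]], frac[["ESC-like"]])
})

test_that("raising weight_high raises the >= 0.8 fraction of a class", {
  g <- generate_genome(n_contigs = 1L, contig_length = 200000L,
                       n_promoters = 4L, n_repeats = 30L,
                       n_imprinted_clusters = 1L, seed = 21L)
  fracs <- sapply(c(0.1, 0.5, 0.9), function(w) {
    prof <- default_profiles()[1]
    prof[[1]]$params[grepl("^repeat", feature_class), weight_high := w]
    sm <- assign_methylation_states(g$genome, g$catalogue, prof, seed = 21L)
    reps <- g$catalogue[grepl("^repeat", feature_class)]
    inside <- rep(FALSE, nrow(sm))
    for (i in seq_len(nrow(reps)))
      inside <- inside | (sm$chrom == reps$chrom[i] & sm$pos >= reps$start[i] &
                            sm$pos < reps$end[i])
    mean(sm$m_true[inside] >= 0.8)
  })
  expect_true(all(diff(fracs) > 0))
})

test_that("a CpG class missing from the profile is a configuration error", {
  g <- generate_genome(n_contigs = 1L, contig_length = 50000L,
                       n_promoters = 2L, n_repeats = 2L,
                       n_imprinted_clusters = 1L, seed = 1L)
  prof <- default_profiles()[1]
  prof[[1]]$params <- prof[[1]]$params[feature_class != "background"]
  expect_error(assign_methylation_states(g$genome, g$catalogue, prof,
                                         seed = 1L),
               "no entry for class")
})
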