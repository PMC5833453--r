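#' Two-sided Fisher's exact test for 2x2 count tables, vectorised
#'
#' For each table (meth_A, unmeth_A | meth_B, unmeth_B) the conditional
#' distribution of meth_A given the margins is hypergeometric; the
#' two-sided p-value is the sum of the point probabilities of every table
#' with the same margins whose probability does not exceed that of the
#' observed table (with a 1e-7 relative tolerance for floating-point ties,
#' the convention of standard implementations). Tables sharing margins are
#' evaluated in one pass, so the function scales to genome-wide site sets.
#'
#' @param meth_a,unmeth_a,meth_b,unmeth_b non-negative integer vectors
#'   (recycled to a common length); both sample margins must be positive.
#' @return numeric vector of p-values in (0, 1].
#' @export
fisher_exact_2x2 <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- max(length(meth_a), length(unmeth_a), length(meth_b), length(unmeth_b))
  a <- rep_len(as.integer(meth_a), n); b <- rep_len(as.integer(unmeth_a), n)
  cc <- rep_len(as.integer(meth_b), n); d <- rep_len(as.integer(unmeth_b), n)
  if (any(a < 0L | b < 0L | cc < 0L | d < 0L))
    stop("counts must be non-negative")
  if (any(a + b == 0L | cc + d == 0L))
    stop("undefined test: empty sample margin")
  m <- a + cc          # methylated column margin
  nn <- b + d          # unmethylated column margin
  k <- a + b           # sample A row margin
  p <- numeric(n)
  grp <- paste(m, nn, k)
  rel <- 1 + 1e-7
  for (g in unique(grp)) {
    idx <- which(grp == g)
    mi <- m[idx[1L]]; ni <- nn[idx[1L]]; ki <- k[idx[1L]]
    lo <- max(0L, ki - ni); hi <- min(ki, mi)
    supp <- lo:hi
    dens <- dhyper(supp, mi, ni, ki)
    o <- order(dens)
    cums <- cumsum(dens[o])
    dx <- dens[a[idx] - lo + 1L]
    pos <- findInterval(dx * rel, dens[o])
    p[idx] <- cums[pos]
  }
  pmin(p, 1)
}

#' Call strong differentially methylated CpGs between two samples
#'
#' Per CpG present (and coverage-gated) in both samples, computes the
#' level difference delta = level_A - level_B and a two-sided Fisher's
#' exact p-value on the (meth, unmeth) counts. A site is a strong DMC when
#' |delta| strictly exceeds `delta_threshold` and p is strictly below
#' `p_threshold`. Benjamini-Hochberg q-values are reported for
#' transparency but do not gate the call. Sites missing in either sample
#' are skipped with a message.
#'
#' @param counts gated long count table (chrom, pos, sample, meth, total).
#' @param comparison character vector c(A, B); "hyper" means A > B.
#' @param delta_threshold strong-effect threshold on |delta| (strict >).
#' @param p_threshold significance threshold (strict <).
#' @return data.table of DMC records: chrom, pos, counts and levels per
#'   side, delta, p_value, q_value, direction, is_strong, comparison.
#' @export
call_strong_dmcs <- function(counts, comparison,
                             delta_threshold = 1 / 3, p_threshold = 0.05) {
  stopifnot(length(comparison) == 2L)
  counts <- as.data.table(counts)
  a <- counts[sample == comparison[1L],
              .(chrom, pos, meth_a = meth, total_a = total)]
  b <- counts[sample == comparison[2L],
              .(chrom, pos, meth_b = meth, total_b = total)]
  if (!nrow(a) || !nrow(b))
    stop("comparison sample(s) not found in count table: ",
         paste(comparison, collapse = ", "))
  dt <- merge(a, b, by = c("chrom", "pos"))
  skipped <- nrow(a) + nrow(b) - 2L * nrow(dt)
  if (skipped > 0L)
    message(skipped, " site record(s) missing in one sample; skipped")
  dt[, `:=`(level_a = meth_a / total_a, level_b = meth_b / total_b)]
  dt[, delta := level_a - level_b]
  dt[, p_value := fisher_exact_2x2(meth_a, total_a - meth_a,
                                   meth_b, total_b - meth_b)]
  dt[, q_value := p.adjust(p_value, method = "BH")]
  dt[, direction := data.table::fifelse(delta > 0, "hyper",
                       data.table::fifelse(delta < 0, "hypo", NA_character_))]
  # exact strict-> on |delta|: cross-multiplied integer comparison against
  # the rationalised threshold, so a difference of exactly the threshold
  # (e.g. one third from 25/30 vs 15/30) is never called strong by float
  # round-off
  rat <- as_rational(delta_threshold)
  dt[, is_strong := abs(meth_a * as.numeric(total_b) -
                          meth_b * as.numeric(total_a)) * rat[["den"]] >
       rat[["num"]] * as.numeric(total_a) * total_b & p_value < p_threshold]
  dt[, comparison := paste(comparison, collapse = "_vs_")]
  setorder(dt, chrom, pos)[]
}

#' Chain strong DMCs into differentially methylated regions
#'
#' Same-direction strong DMCs on one chromosome whose consecutive
#' positions are at most `max_gap` bp apart are chained; chains with at
#' least `min_cpgs` CpGs become DMRs spanning the first to the last CpG
#' (half-open, end = last position + 1). The region level per sample is
#' the unweighted mean of the constituent CpG levels.
#'
#' @param dmcs DMC table from [call_strong_dmcs()].
#' @param levels wide level table covering the DMC sites.
#' @param max_gap maximum gap between consecutive constituent CpGs (bp).
#' @param min_cpgs minimum number of CpGs per DMR.
#' @return data.table: chrom, start, end, comparison, direction, n_cpgs,
#'   one level column per sample in `levels`, and cpg_pos (list column of
#'   constituent positions).
#' @export
call_dmrs <- function(dmcs, levels, max_gap = 300L, min_cpgs = 3L) {
  strong <- as.data.table(dmcs)[is_strong == TRUE]
  scols <- sample_columns(levels)
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), comparison = character(),
                      direction = character(), n_cpgs = integer())
  for (s in scols) empty[[paste0("level_", s)]] <- numeric()
  empty[["cpg_pos"]] <- list()
  if (!nrow(strong)) return(empty)
  setorder(strong, chrom, direction, pos)
  strong[, chain := cumsum(c(1L, diff(pos) > max_gap | diff(pos) < 0L)),
         by = .(chrom, direction)]
  lv <- as.data.table(levels)
  out <- strong[, {
    if (.N >= min_cpgs) {
      sub <- lv[chrom == .BY$chrom & pos %in% .SD$pos]
      means <- lapply(scols, function(s) mean(sub[[s]]))
      names(means) <- paste0("level_", scols)
      c(list(start = min(pos), end = max(pos) + 1L,
             comparison = comparison[1L], n_cpgs = .N),
        means, list(cpg_pos = list(sort(pos))))
    }
  }, by = .(chrom, direction, chain)]
  if (!nrow(out)) return(empty)
  out[, chain := NULL]
  setcolorder(out, c("chrom", "start", "end", "comparison", "direction",
                     "n_cpgs"))
  setorder(out, chrom, start)[]
}

#' Merge overlapping DMRs across two call sets
#'
#' Intervals overlapping by >= 1 bp (within or across the two sets) are
#' unioned transitively. For each interval produced from more than one
#' parent, the region level per sample is re-computed as the unweighted
#' mean over all gated CpGs of the level table inside the merged interval
#' (not from the parents' levels); DMRs that overlap nothing pass through
#' unchanged. The direction of a merged interval is that of its parents
#' when they agree, otherwise "mixed".
#'
#' @param dmr_set_1,dmr_set_2 DMR tables from [call_dmrs()].
#' @param levels wide gated level table used to re-compute merged levels.
#' @return data.table of merged DMRs with a `merged` flag and `source`.
#' @export
merge_dmr_sets <- function(dmr_set_1, dmr_set_2, levels) {
  s1 <- copy(as.data.table(dmr_set_1))[, source := "set1"]
  s2 <- copy(as.data.table(dmr_set_2))[, source := "set2"]
  all_dmrs <- rbindlist(list(s1, s2), fill = TRUE)
  if (!nrow(all_dmrs)) return(all_dmrs)
  gr <- dt_to_granges(all_dmrs)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  revmap <- S4Vectors::mcols(red)$revmap
  lv <- as.data.table(levels)
  scols <- sample_columns(lv)
  rows <- lapply(seq_along(red), function(i) {
    parents <- revmap[[i]]
    if (length(parents) == 1L) return(all_dmrs[parents])
    ch <- as.character(GenomicRanges::seqnames(red)[i])
    st <- GenomicRanges::start(red)[i] - 1L   # back to 0-based
    en <- GenomicRanges::end(red)[i]
    sub <- lv[chrom == ch & pos >= st & pos < en]
    dirs <- unique(all_dmrs$direction[parents])
    row <- data.table(chrom = ch, start = st, end = en,
                      comparison = paste(sort(unique(
                        all_dmrs$comparison[parents])), collapse = "+"),
                      direction = if (length(dirs) == 1L) dirs else "mixed",
                      n_cpgs = nrow(sub), source = "merged")
    for (s in scols)
      row[[paste0("level_", s)]] <- if (nrow(sub)) mean(sub[[s]]) else NA_real_
    row[["cpg_pos"]] <- list(sub$pos)
    row
  })
  out <- rbindlist(rows, fill = TRUE)
  out[, merged := source == "merged"]
  setorder(out, chrom, start)[]
}

#' Compare two DMC site sets
#'
#' Exact set algebra on (chrom, pos) keys, as behind a Venn diagram of
#' strong hypermethylated CpGs.
#'
#' @param set_a,set_b data.tables with chrom and pos columns.
#' @return list with n_common, n_only_a, n_only_b and the three site
#'   tables.
#' @export
compare_dmc_sets <- function(set_a, set_b) {
  ka <- unique(as.data.table(set_a)[, .(chrom, pos)])
  kb <- unique(as.data.table(set_b)[, .(chrom, pos)])
  common <- merge(ka, kb, by = c("chrom", "pos"))
  only_a <- ka[!common, on = c("chrom", "pos")]
  only_b <- kb[!common, on = c("chrom", "pos")]
  list(n_common = nrow(common), n_only_a = nrow(only_a),
       n_only_b = nrow(only_b),
       common = common, only_a = only_a, only_b = only_b)
}

#' Per-site effect/p-value table for a volcano plot
#'
#' For each provided site gated in both contrasted samples, computes
#' delta = level(sample1) - level(sample2) and the Fisher's exact p-value
#' of the count pair; sites ungated in either sample are skipped with a
#' message. Rendering (e.g. the p = 0.05 reference line) is left to the
#' caller.
#'
#' @param sites data.table of sites (chrom, pos), e.g. common strong DMCs.
#' @param counts gated long count table containing both samples.
#' @param samples character vector c(sample1, sample2).
#' @return data.table (chrom, pos, delta, p_value).
#' @export
volcano_table <- function(sites, counts, samples) {
  stopifnot(length(samples) == 2L)
  counts <- as.data.table(counts)
  key <- unique(as.data.table(sites)[, .(chrom, pos)])
  a <- merge(key, counts[sample == samples[1L]], by = c("chrom", "pos"))
  b <- merge(key, counts[sample == samples[2L]], by = c("chrom", "pos"))
  dt <- merge(a[, .(chrom, pos, meth_a = meth, total_a = total)],
              b[, .(chrom, pos, meth_b = meth, total_b = total)],
              by = c("chrom", "pos"))
  skipped <- nrow(key) - nrow(dt)
  if (skipped > 0L)
    message(skipped, " site(s) ungated in a contrasted sample; skipped")
  if (!nrow(dt)) return(data.table(chrom = character(), pos = integer(),
                                   delta = numeric(), p_value = numeric()))
  dt[, delta := meth_a / total_a - meth_b / total_b]
  dt[, p_value := fisher_exact_2x2(meth_a, total_a - meth_a,
                                   meth_b, total_b - meth_b)]
  dt[, .(chrom, pos, delta, p_value)][order(chrom, pos)]
}
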