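#' Merge replicate count columns by pooling reads
#'
#' Per CpG site and replicate group, methylated and total counts are summed
#' across replicates, so the merged level is the coverage-weighted mean of
#' the replicate levels.
#'
#' @param counts long count table (chrom, pos, sample, meth, total).
#' @param replicate_groups named list mapping each output sample name to
#'   the character vector of replicate sample ids it pools; the groups must
#'   partition the samples present in `counts`.
#' @return long count table with `sample` set to the group names.
#' @export
merge_replicates <- function(counts, replicate_groups) {
  counts <- as.data.table(counts)
  ids <- unlist(replicate_groups, use.names = FALSE)
  if (!length(ids) || any(lengths(replicate_groups) == 0L))
    stop("every replicate group must be non-empty")
  if (anyDuplicated(ids))
    stop("replicate groups must not share sample ids")
  present <- unique(counts$sample)
  unknown <- setdiff(ids, present)
  if (length(unknown))
    stop("unknown replicate id(s): ", paste(unknown, collapse = ", "))
  uncovered <- setdiff(present, ids)
  if (length(uncovered))
    stop("replicate groups must partition the samples; not covered: ",
         paste(uncovered, collapse = ", "))
  map <- data.table(sample = ids,
                    grp = rep(names(replicate_groups), lengths(replicate_groups)))
  merged <- merge(counts, map, by = "sample")[
    , .(meth = sum(meth), total = sum(total)), by = .(chrom, pos, grp)]
  setnames(merged, "grp", "sample")
  setcolorder(merged, c("chrom", "pos", "sample", "meth", "total"))
  setorder(merged, chrom, pos, sample)[]
}

#' Coverage gate: keep CpGs covered >= min_cov in every sample
#'
#' The bound is inclusive (a site with exactly `min_cov` reads in each
#' sample is kept), and a site missing from any sample is dropped.
#'
#' @param counts long count table (after replicate merging).
#' @param min_cov minimum per-sample total count.
#' @return the gated long count table.
#' @export
filter_coverage <- function(counts, min_cov = 10L) {
  counts <- as.data.table(counts)
  if (!nrow(counts)) return(counts)
  n_samples <- length(unique(counts$sample))
  ok <- counts[, .(keep = .N == n_samples && min(total) >= min_cov),
               by = .(chrom, pos)][keep == TRUE, .(chrom, pos)]
  merge(counts, ok, by = c("chrom", "pos"))[order(chrom, pos, sample)]
}

#' Per-CpG methylation levels
#'
#' level = meth / total, computed exactly on the counts; sites are rows,
#' samples are columns. Sites absent from a sample get NA.
#'
#' @param counts long count table; every retained cell must have total > 0.
#' @return wide data.table: chrom, pos, then one level column per sample.
#' @export
methylation_levels <- function(counts) {
  counts <- as.data.table(counts)
  if (any(counts$total <= 0L))
    stop("methylation level undefined at total = 0")
  if (any(counts$meth > counts$total | counts$meth < 0L))
    stop("invalid counts: need 0 <= meth <= total")
  wide <- data.table::dcast(counts[, .(chrom, pos, sample, level = meth / total)],
                            chrom + pos ~ sample, value.var = "level")
  setorder(wide, chrom, pos)[]
}

sample_columns <- function(levels) setdiff(names(levels), c("chrom", "pos"))

#' Fractions of CpGs in low / intermediate / high methylation categories
#'
#' high: level >= high_cut; intermediate: low_cut <= level < high_cut;
#' low: level < low_cut. The three fractions partition the sites with a
#' defined level in each sample and sum to 1.
#'
#' @param levels wide level table from [methylation_levels()].
#' @param low_cut,high_cut category boundaries.
#' @return data.table (sample, low, intermediate, high, n_sites).
#' @export
categorize_levels <- function(levels, low_cut = 0.3, high_cut = 0.8) {
  stopifnot(low_cut < high_cut)
  cols <- sample_columns(levels)
  rbindlist(lapply(cols, function(s) {
    x <- levels[[s]]
    x <- x[!is.na(x)]
    if (any(x < 0 | x > 1)) stop("levels must lie in [0, 1]")
    n <- length(x)
    hi <- sum(x >= high_cut)
    lo <- sum(x < low_cut)
    data.table(sample = s, low = lo / n,
               intermediate = (n - hi - lo) / n, high = hi / n,
               n_sites = n)
  }))
}

#' Pairwise sample correlation of methylation levels
#'
#' Spearman by default: Pearson correlation of mid-ranks, with average
#' ranks for ties, computed per pair over the sites where both samples
#' have a defined level.
#'
#' @param levels wide level table.
#' @param method "spearman" or "pearson".
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlation <- function(levels, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  cols <- sample_columns(levels)
  if (length(cols) < 2L) stop("need at least two samples")
  m <- as.matrix(levels[, cols, with = FALSE])
  common <- crossprod(!is.na(m))
  if (any(common[upper.tri(common)] < 3L))
    stop("fewer than 3 common sites for at least one sample pair")
  r <- cor(m, method = method, use = "pairwise.complete.obs")
  diag(r) <- 1
  r
}

#' Histogram of methylation levels per sample
#'
#' Equal-width bins on [0, 1]; all bins are left-closed/right-open except
#' the last, which is right-closed so that level 1 is counted. Optionally
#' restricted to CpGs inside (or outside) a feature class via
#' [region_restricted_summary()].
#'
#' @param levels wide level table.
#' @param n_bins number of bins (>= 2).
#' @return tidy data.table (sample, bin, bin_start, bin_end, count).
#' @export
level_histogram <- function(levels, n_bins = 20L) {
  stopifnot(n_bins >= 2L)
  cols <- sample_columns(levels)
  rbindlist(lapply(cols, function(s) {
    x <- levels[[s]]
    x <- x[!is.na(x)]
    bin <- pmin(floor(x * n_bins), n_bins - 1L) + 1L
    cnt <- tabulate(bin, nbins = n_bins)
    data.table(sample = s, bin = seq_len(n_bins),
               bin_start = (seq_len(n_bins) - 1L) / n_bins,
               bin_end = seq_len(n_bins) / n_bins,
               count = cnt)
  }))
}
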