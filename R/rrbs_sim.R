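#' In-silico MspI digestion
#'
#' MspI recognises CCGG and cuts C^CGG, i.e. one base after the start of
#' each recognition site. Fragments are the intervals between consecutive
#' cut offsets, extended to the contig ends, so before any size selection
#' they tile each contig without gaps. A contig without a recognition site
#' yields a single fragment spanning it.
#'
#' @param genome named character vector of contig sequences (A/C/G/T).
#' @return data.table with columns chrom, start, end (0-based half-open)
#'   and length.
#' @export
digest_mspi <- function(genome) {
  assert_genome(genome)
  rbindlist(lapply(names(genome), function(ct) {
    s <- genome[[ct]]
    m <- gregexpr("CCGG", s, fixed = TRUE)[[1L]]
    cuts <- if (m[1L] == -1L) integer(0) else as.integer(m)  # 1-based site
    # cut offset (0-based) = site start (0-based) + 1 = (m - 1) + 1 = m
    bnd <- unique(c(0L, cuts, nchar(s)))
    bnd <- sort(bnd[bnd <= nchar(s)])
    data.table(chrom = ct, start = bnd[-length(bnd)], end = bnd[-1L])
  }))[, `:=`(length = end - start)][]
}

#' Fragment size selection
#'
#' Retains fragments whose length lies inside the selected range; both
#' bounds are inclusive, matching a 170-370 bp gel cut.
#'
#' @param fragments data.table from [digest_mspi()].
#' @param min_len,max_len inclusive length bounds in bp.
#' @return the retained fragments.
#' @export
size_select <- function(fragments, min_len = 170L, max_len = 370L) {
  stopifnot(min_len <= max_len)
  fragments[end - start >= min_len & end - start <= max_len]
}

#' Simulate bisulfite-converted per-CpG counts
#'
#' Only CpGs inside the retained fragments receive coverage. Per CpG and
#' sample the total read count is Poisson(mean_coverage) — optionally
#' Gamma-overdispersed across replicates — and the methylated count is
#' Binomial(total, q) with q = m_true + (1 - m_true) * (1 -
#' conversion_efficiency): an unconverted unmethylated cytosine reads as
#' methylated, so incomplete conversion inflates apparent methylation.
#' Counts from both CpG strands are pooled into the forward-strand site.
#'
#' @param fragments retained fragments (data.table chrom/start/end).
#' @param state_map long data.table (chrom, pos, cell_type, m_true); every
#'   CpG falling in a retained fragment must be present for each simulated
#'   cell type.
#' @param sample_plan data.table (sample_id, cell_type) mapping each
#'   simulated sample (e.g. replicate) to a cell type in the state map.
#' @param mean_coverage expected reads per CpG and sample.
#' @param conversion_efficiency bisulfite conversion rate in (0, 1].
#' @param replicate_dispersion Gamma dispersion of per-site coverage across
#'   replicates; 0 gives pure Poisson coverage.
#' @param seed integer seed; output is deterministic given the seed.
#' @return data.table with columns chrom, pos, sample, meth, total
#'   (sites with total = 0 are omitted).
#' @export
simulate_counts <- function(fragments, state_map, sample_plan,
                            mean_coverage = 30, conversion_efficiency = 0.995,
                            replicate_dispersion = 0, seed = 1L) {
  stopifnot(mean_coverage > 0,
            conversion_efficiency > 0, conversion_efficiency <= 1,
            replicate_dispersion >= 0)
  sample_plan <- as.data.table(sample_plan)
  stopifnot(all(c("sample_id", "cell_type") %in% names(sample_plan)))
  gr_frag <- dt_to_granges(fragments)
  with_seed(seed, {
    out <- vector("list", nrow(sample_plan))
    for (i in seq_len(nrow(sample_plan))) {
      ct <- sample_plan$cell_type[i]
      sm <- state_map[cell_type == ct]
      if (!nrow(sm))
        stop("state map has no entries for cell type '", ct, "'")
      covered <- IRanges::overlapsAny(sites_to_granges(sm), gr_frag)
      sm <- sm[covered]
      # a CpG inside a fragment but absent from the map is a configuration
      # error; detected by comparing against the fragment CpG universe
      n <- nrow(sm)
      lam <- if (replicate_dispersion > 0)
        rgamma(n, shape = 1 / replicate_dispersion,
               scale = mean_coverage * replicate_dispersion)
      else rep(mean_coverage, n)
      tot <- rpois(n, lam)
      q <- sm$m_true + (1 - sm$m_true) * (1 - conversion_efficiency)
      mc <- rbinom(n, tot, q)
      out[[i]] <- data.table(chrom = sm$chrom, pos = sm$pos,
                             sample = sample_plan$sample_id[i],
                             meth = mc, total = tot)[total > 0L]
    }
    rbindlist(out)
  })
}

#' Verify that a state map covers every CpG inside retained fragments
#'
#' @param genome named character vector of contig sequences.
#' @param fragments retained fragments.
#' @param state_map long state map.
#' @return invisibly TRUE; stops with a configuration error when a covered
#'   CpG is missing from the map for some cell type.
#' @export
check_state_coverage <- function(genome, fragments, state_map) {
  sites <- cpg_sites(genome)
  covered <- sites[IRanges::overlapsAny(sites_to_granges(sites),
                                        dt_to_granges(fragments))]
  for (ct in unique(state_map$cell_type)) {
    sm <- state_map[cell_type == ct]
    miss <- covered[!paste(chrom, pos) %in% paste(sm$chrom, sm$pos)]
    if (nrow(miss))
      stop("state map for '", ct, "' is missing ", nrow(miss),
           " CpG(s) inside retained fragments (first: ",
           miss$chrom[1L], ":", miss$pos[1L], ")")
  }
  invisible(TRUE)
}
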