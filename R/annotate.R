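#' Define promoters as TSS +/- flank
#'
#' The interval is [TSS - flank, TSS + flank), clipped at contig ends;
#' strand is retained but does not change the (symmetric) interval.
#'
#' @param tss data.table (gene, chrom, pos, strand) of transcription start
#'   sites.
#' @param contig_len named integer vector of contig lengths.
#' @param flank half-width in bp.
#' @return data.table (gene, chrom, tss, strand, start, end).
#' @export
define_promoters <- function(tss, contig_len, flank = 1000L) {
  tss <- as.data.table(tss)
  len <- contig_len[tss$chrom]
  if (any(is.na(len)) || any(tss$pos < 0L | tss$pos >= len))
    stop("TSS outside contig bounds")
  data.table(gene = tss$gene, chrom = tss$chrom, tss = tss$pos,
             strand = tss$strand,
             start = pmax(tss$pos - flank, 0L),
             end = pmin(tss$pos + flank, as.integer(len)))
}

# window statistics for one sequence: per offset, C count, G count and
# count of CpG dinucleotides fully inside the window
window_stats <- function(seq_chars, window, offsets) {
  n <- length(seq_chars)
  isC <- as.integer(seq_chars == "C")
  isG <- as.integer(seq_chars == "G")
  isCpG <- c(as.integer(seq_chars[-n] == "C" & seq_chars[-1L] == "G"), 0L)
  cumC <- c(0L, cumsum(isC)); cumG <- c(0L, cumsum(isG))
  cumCpG <- c(0L, cumsum(isCpG))
  nc <- cumC[offsets + window + 1L] - cumC[offsets + 1L]
  ng <- cumG[offsets + window + 1L] - cumG[offsets + 1L]
  # CpG starts in [o, o + window - 2]: dinucleotide fully inside the window
  ncpg <- cumCpG[offsets + window] - cumCpG[offsets + 1L]
  gc <- (nc + ng) / window
  oe <- ifelse(nc * ng > 0, ncpg * window / (nc * ng), 0)
  data.table(offset = offsets, n_cpg = ncpg, gc = gc, cpg_oe = oe)
}

#' Classify promoter CpG density (HCP / ICP / LCP)
#'
#' Slides windows of `window` bp at offsets 0, step, 2*step, ... across
#' each promoter and computes, per window, the GC fraction and the CpG
#' observed/expected ratio O/E = (N_CpG * L) / (N_C * N_G) (0 when the
#' window lacks C or G; only dinucleotides fully inside the window are
#' counted). A promoter is HCP if some window has O/E >= oe_rich and
#' GC >= gc_rich; LCP if no window reaches O/E >= oe_poor; ICP otherwise.
#' When the promoter is shorter than `window` the whole interval is the
#' single window.
#'
#' @param promoters data.table from [define_promoters()].
#' @param genome named character vector of contig sequences.
#' @param window window length (bp).
#' @param step offset step (bp); step = 1 is the exhaustive scan.
#' @param oe_rich,oe_poor,gc_rich classing thresholds.
#' @return the promoter table with added columns cpg_class, best_offset,
#'   best_gc, best_cpg_oe (the window maximising O/E; ties -> smallest
#'   offset).
#' @export
classify_promoter_cpg_density <- function(promoters, genome, window = 500L,
                                          step = 5L, oe_rich = 0.75,
                                          oe_poor = 0.48, gc_rich = 0.55) {
  stopifnot(window >= 2L, step >= 1L)
  promoters <- copy(as.data.table(promoters))
  res <- lapply(seq_len(nrow(promoters)), function(i) {
    p <- promoters[i]
    s <- substr(genome[[p$chrom]], p$start + 1L, p$end)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(chars)
    w <- min(window, L)
    offs <- if (L <= w) 0L else seq.int(0L, L - w, by = step)
    st <- window_stats(chars, w, offs)
    rich <- st$cpg_oe >= oe_rich & st$gc >= gc_rich
    cls <- if (any(rich)) "HCP"
           else if (all(st$cpg_oe < oe_poor)) "LCP"
           else "ICP"
    best <- which.max(st$cpg_oe)
    data.table(cpg_class = cls, best_offset = st$offset[best],
               best_gc = st$gc[best], best_cpg_oe = st$cpg_oe[best])
  })
  cbind(promoters, rbindlist(res))
}

#' Assign an exclusive genomic location to each site
#'
#' Every site receives exactly one of promoter / exon / intron /
#' intergenic by precedence (promoter wins over exon wins over intron);
#' overlaps with repeats, imprinted clusters and gDMRs are reported as
#' additional non-exclusive flags.
#'
#' @param sites data.table (chrom, pos).
#' @param catalogue feature table.
#' @return the sites with columns location, in_repeat, in_imprinted,
#'   in_gdmr added.
#' @export
assign_genomic_location <- function(sites, catalogue) {
  sites <- copy(as.data.table(sites))
  gr <- sites_to_granges(sites)
  hit <- function(classes) {
    sub <- catalogue[feature_class %in% classes]
    if (!nrow(sub)) return(rep(FALSE, nrow(sites)))
    IRanges::overlapsAny(gr, dt_to_granges(sub))
  }
  loc <- rep("intergenic", nrow(sites))
  loc[hit("intron")] <- "intron"
  loc[hit("exon")] <- "exon"
  loc[hit("promoter")] <- "promoter"
  sites[, location := loc]
  sites[, in_repeat := hit(c("repeat_LINE", "repeat_SINE", "repeat_LTR"))]
  sites[, in_imprinted := hit("imprinted_cluster")]
  sites[, in_gdmr := hit("gDMR")]
  sites[]
}

#' Label DMRs by feature overlap
#'
#' A DMR receives a (non-exclusive) label whenever it overlaps the
#' corresponding feature by at least 1 bp: promoter_dmr, imprinted_dmr,
#' gdmr_overlap and repeat_overlap.
#'
#' @param dmrs DMR table (chrom, start, end, ...).
#' @param catalogue feature table.
#' @return the DMR table with the four logical label columns added.
#' @export
annotate_dmrs <- function(dmrs, catalogue) {
  dmrs <- copy(as.data.table(dmrs))
  if (!nrow(dmrs)) {
    dmrs[, `:=`(promoter_dmr = logical(), imprinted_dmr = logical(),
                gdmr_overlap = logical(), repeat_overlap = logical())]
    return(dmrs)
  }
  gr <- dt_to_granges(dmrs)
  hit <- function(classes) {
    sub <- catalogue[feature_class %in% classes]
    if (!nrow(sub)) return(rep(FALSE, nrow(dmrs)))
    IRanges::overlapsAny(gr, dt_to_granges(sub))
  }
  dmrs[, promoter_dmr := hit("promoter")]
  dmrs[, imprinted_dmr := hit("imprinted_cluster")]
  dmrs[, gdmr_overlap := hit("gDMR")]
  dmrs[, repeat_overlap := hit(c("repeat_LINE", "repeat_SINE", "repeat_LTR"))]
  dmrs[]
}

#' Level summaries restricted to a feature class
#'
#' Restricts the gated level table to CpGs inside the intervals of one
#' feature class — or, for the pseudo-class "other", to CpGs outside every
#' promoter and repeat interval (the complement used for genome
#' compartment histograms) — and delegates to the standard summaries.
#'
#' @param levels wide gated level table.
#' @param catalogue feature table.
#' @param feature_class one of the catalogue classes, "repeat_any", or
#'   "other".
#' @param n_bins histogram bin count.
#' @return list with n_sites, categories (from [categorize_levels()]) and
#'   histogram (from [level_histogram()]); empty summaries carry zero
#'   counts.
#' @export
region_restricted_summary <- function(levels, catalogue, feature_class,
                                      n_bins = 20L) {
  vocab <- c(.class_precedence, "repeat_any", "other")
  if (!feature_class %in% vocab)
    stop("unknown feature class: ", feature_class)
  lv <- as.data.table(levels)
  gr <- sites_to_granges(lv)
  rep_classes <- c("repeat_LINE", "repeat_SINE", "repeat_LTR")
  sel_classes <- switch(feature_class,
                        repeat_any = rep_classes,
                        other = c("promoter", rep_classes),
                        feature_class)
  sub <- catalogue[feature_class %in% sel_classes]
  inside <- if (nrow(sub)) IRanges::overlapsAny(gr, dt_to_granges(sub))
            else rep(FALSE, nrow(lv))
  keep <- if (identical(feature_class, "other")) !inside else inside
  lvs <- lv[keep]
  if (!nrow(lvs)) {
    scols <- sample_columns(lv)
    return(list(n_sites = 0L,
                categories = data.table(sample = scols, low = NA_real_,
                                        intermediate = NA_real_,
                                        high = NA_real_, n_sites = 0L),
                histogram = level_histogram(lv[0], n_bins)))
  }
  list(n_sites = nrow(lvs),
       categories = categorize_levels(lvs),
       histogram = level_histogram(lvs, n_bins))
}
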