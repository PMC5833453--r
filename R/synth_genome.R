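#' Generate a seeded toy genome with a feature catalogue
#'
#' Builds a small random genome that carries the structural features the
#' downstream methylation analysis expects: promoters spanning exactly
#' TSS +/- 1 kb (a configurable fraction of them CpG-island-like, i.e.
#' containing a 500-bp window with CpG observed/expected >= 0.75 and
#' GC >= 55%), gene bodies split into exons and introns, interspersed
#' repeats (LINE/SINE/LTR), and imprinted clusters each containing a
#' germline DMR (gDMR) sub-interval. The background sequence is
#' CpG-depleted, mimicking the genome-wide CpG deficit of mammalian DNA,
#' and MspI recognition sites (CCGG) are planted at quasi-regular spacing
#' so that an in-silico reduced-representation digest recovers fragments
#' in the size-selectable range.
#'
#' All coordinates are 0-based, half-open. A CpG site is identified by the
#' 0-based position of the C on the forward strand; reverse-strand
#' information is pooled into the same site throughout the package
#' (symmetric-CpG convention).
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param n_promoters total number of genes/promoters to place.
#' @param n_repeats total number of interspersed repeats.
#' @param n_imprinted_clusters total number of imprinted clusters (each with
#'   one gDMR sub-interval).
#' @param cpg_island_fraction fraction of promoters rewritten with a
#'   CpG-island-like core.
#' @param cut_spacing length-2 vector; MspI sites are planted with
#'   consecutive spacings drawn uniformly from this range (bp).
#' @param cpg_depletion probability that the G of a background CpG is
#'   mutated away, emulating genome-wide CpG depletion.
#' @param seed integer seed; the genome and catalogue are deterministic
#'   given the seed.
#'
#' @return a list with elements `genome` (named character vector of
#'   uppercase contig sequences), `catalogue` (data.table with columns
#'   chrom, start, end, strand, feature_class, name) and `tss`
#'   (data.table gene, chrom, pos, strand).
#' @export
generate_genome <- function(n_contigs = 2L, contig_length = 1000000L,
                            n_promoters = 60L, n_repeats = 120L,
                            n_imprinted_clusters = 6L,
                            cpg_island_fraction = 0.5,
                            cut_spacing = c(180L, 360L),
                            cpg_depletion = 0.8,
                            seed = 1L) {
  stopifnot(n_contigs >= 1L, contig_length >= 5000L,
            n_promoters >= 0L, n_repeats >= 0L, n_imprinted_clusters >= 0L,
            cpg_island_fraction >= 0, cpg_island_fraction <= 1,
            length(cut_spacing) == 2L, cut_spacing[1] <= cut_spacing[2])
  with_seed(seed, {
    contigs <- paste0("chr", seq_len(n_contigs))
    seqs <- lapply(contigs, function(ct) {
      s <- sample(c("A", "C", "G", "T"), contig_length, replace = TRUE,
                  prob = c(0.3, 0.2, 0.2, 0.3))
      # CpG depletion: mutate the G of most CpG dinucleotides
      cg <- which(s[-length(s)] == "C" & s[-1L] == "G")
      if (length(cg)) {
        hit <- cg[runif(length(cg)) < cpg_depletion]
        if (length(hit))
          s[hit + 1L] <- sample(c("A", "T"), length(hit), replace = TRUE)
      }
      s
    })
    names(seqs) <- contigs

    # distribute feature counts across contigs as evenly as possible
    split_count <- function(n) {
      base <- n %/% n_contigs
      extra <- n %% n_contigs
      base + (seq_len(n_contigs) <= extra)
    }
    prom_per <- split_count(as.integer(n_promoters))
    rep_per <- split_count(as.integer(n_repeats))
    imp_per <- split_count(as.integer(n_imprinted_clusters))

    feat <- list()
    tss_rows <- list()
    gene_i <- 0L; rep_i <- 0L; imp_i <- 0L

    for (ci in seq_len(n_contigs)) {
      ct <- contigs[ci]
      occupied <- IRanges::IRanges()
      place_block <- function(len) {
        # returns 0-based start or NA after too many failures
        for (tr in 1:2000) {
          st <- sample.int(contig_length - len - 1L, 1L)  # 1-based
          cand <- IRanges::IRanges(st, st + len - 1L)
          if (!any(IRanges::overlapsAny(cand, occupied))) {
            occupied <<- c(occupied, IRanges::IRanges(st - 50L, st + len + 49L))
            return(st - 1L)
          }
        }
        NA_integer_
      }

      ## genes: promoter (TSS +/- 1 kb) + body with exons/introns
      for (g in seq_len(prom_per[ci])) {
        gene_i <- gene_i + 1L
        gid <- sprintf("g%03d", gene_i)
        strand <- sample(c("+", "-"), 1L)
        body_len <- sample(3000:6000, 1L)
        block_len <- body_len + 1000L
        bs <- place_block(block_len + 100L)
        if (is.na(bs))
          stop("infeasible packing: requested features exceed genome capacity")
        if (strand == "+") {
          tss <- bs + 1000L
          body <- c(tss, tss + body_len)
        } else {
          tss <- bs + body_len
          body <- c(bs, tss)
        }
        prom <- c(tss - 1000L, tss + 1000L)
        # exon/intron segmentation of the body (starts and ends with an exon)
        n_ex <- sample(2:4, 1L)
        w <- runif(2L * n_ex - 1L, 0.5, 1.5)
        seg <- diff(round(c(0, cumsum(w) / sum(w)) * body_len))
        seg[seg < 1L] <- 1L
        bnd <- body[1] + c(0, cumsum(seg))
        bnd[length(bnd)] <- body[2]
        for (k in seq_len(2L * n_ex - 1L)) {
          cls <- if (k %% 2L == 1L) "exon" else "intron"
          nm <- sprintf("%s_%s%d", gid, substr(cls, 1, 2), (k + 1L) %/% 2L)
          feat[[length(feat) + 1L]] <- data.table(
            chrom = ct, start = bnd[k], end = bnd[k + 1L],
            strand = strand, feature_class = cls, name = nm)
        }
        feat[[length(feat) + 1L]] <- data.table(
          chrom = ct, start = prom[1], end = prom[2], strand = strand,
          feature_class = "promoter", name = gid)
        tss_rows[[length(tss_rows) + 1L]] <- data.table(
          gene = gid, chrom = ct, pos = tss, strand = strand)
        # CpG-island core for a fraction of promoters
        if (runif(1) < cpg_island_fraction) {
          core <- island_sequence(600L)
          seqs[[ct]][(tss - 300L + 1L):(tss + 300L)] <- core
        }
      }

      ## interspersed repeats
      for (r in seq_len(rep_per[ci])) {
        rep_i <- rep_i + 1L
        len <- sample(300:800, 1L)
        st <- place_block(len)
        if (is.na(st))
          stop("infeasible packing: requested features exceed genome capacity")
        cls <- sample(c("repeat_LINE", "repeat_SINE", "repeat_LTR"), 1L)
        feat[[length(feat) + 1L]] <- data.table(
          chrom = ct, start = st, end = st + len, strand = ".",
          feature_class = cls, name = sprintf("rep%03d", rep_i))
      }

      ## imprinted clusters, each with one gDMR sub-interval
      for (im in seq_len(imp_per[ci])) {
        imp_i <- imp_i + 1L
        len <- sample(6000:10000, 1L)
        st <- place_block(len)
        if (is.na(st))
          stop("infeasible packing: requested features exceed genome capacity")
        nm <- sprintf("imp%02d", imp_i)
        feat[[length(feat) + 1L]] <- data.table(
          chrom = ct, start = st, end = st + len, strand = ".",
          feature_class = "imprinted_cluster", name = nm)
        g_len <- 1500L
        g_st <- st + sample.int(len - g_len, 1L)
        feat[[length(feat) + 1L]] <- data.table(
          chrom = ct, start = g_st, end = g_st + g_len, strand = ".",
          feature_class = "gDMR", name = paste0(nm, "_gDMR"))
      }

      ## plant MspI sites last so cut spacing survives feature rewrites
      p <- sample(seq.int(cut_spacing[1], cut_spacing[2]), 1L)
      while (p + 4L <= contig_length) {
        seqs[[ct]][(p + 1L):(p + 4L)] <- c("C", "C", "G", "G")
        p <- p + sample(seq.int(cut_spacing[1], cut_spacing[2]), 1L)
      }
    }

    genome <- vapply(seqs, paste0, character(1L), collapse = "")
    catalogue <- if (length(feat)) rbindlist(feat) else
      data.table(chrom = character(), start = integer(), end = integer(),
                 strand = character(), feature_class = character(),
                 name = character())
    setorder(catalogue, chrom, start, end)
    tss <- if (length(tss_rows)) rbindlist(tss_rows) else
      data.table(gene = character(), chrom = character(), pos = integer(),
                 strand = character())
    list(genome = assert_genome(genome), catalogue = catalogue, tss = tss)
  })
}

# CpG-island-like sequence of exactly n bases: sampled from a dinucleotide
# alphabet rich in CG, giving GC ~ 0.65 and CpG O/E well above 1.
island_sequence <- function(n) {
  toks <- sample(c("CG", "C", "G", "A", "T"), n, replace = TRUE,
                 prob = c(0.22, 0.18, 0.18, 0.21, 0.21))
  s <- strsplit(paste0(toks, collapse = ""), "", fixed = TRUE)[[1L]]
  s[seq_len(n)]
}

#' Locate CpG sites on the forward strand
#'
#' @param genome named character vector of contig sequences.
#' @return data.table with columns chrom and pos (0-based position of the C
#'   of each CpG dinucleotide).
#' @export
cpg_sites <- function(genome) {
  assert_genome(genome)
  rbindlist(lapply(names(genome), function(ct) {
    m <- gregexpr("CG", genome[[ct]], fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    data.table(chrom = ct, pos = as.integer(m) - 1L)
  }))
}

# precedence order for methylation-state assignment (highest first)
.class_precedence <- c("gDMR", "imprinted_cluster", "promoter",
                       "repeat_LINE", "repeat_SINE", "repeat_LTR",
                       "exon", "intron", "other")

#' Default cell-type methylation profiles
#'
#' Beta-mixture parameters per feature class for the three simulated cell
#' archetypes: a globally hypermethylated, bimodal "4F-like" type; a
#' hypomethylated "ESC-like" type; and an intermediate "C-like" type.
#' Each row gives the probability `weight_high` of drawing the true
#' methylation from the high component Beta(alpha_high, beta_high) rather
#' than the low component Beta(alpha_low, beta_low). These are generator
#' settings chosen to reproduce the qualitative orderings the analysis is
#' meant to detect (repeats and gDMRs hypermethylated in 4F-like,
#' demethylated in ESC-like, intermediate in C-like); they are not
#' measurements.
#'
#' @return named list of profiles; each profile is a list with `name` and
#'   `params`, a data.table keyed by feature_class (including "background").
#' @export
default_profiles <- function() {
  classes <- c("background", .class_precedence)
  mk <- function(name, w) {
    stopifnot(length(w) == length(classes))
    list(name = name, params = data.table(
      feature_class = classes,
      weight_high = w,
      alpha_high = 18, beta_high = 2,
      alpha_low = 1.5, beta_low = 15))
  }
  #              bg   gDMR  imp  prom  LINE SINE LTR  exon intr other
  list(
    `4F-like` = mk("4F-like",
                   c(0.25, 0.90, 0.80, 0.12, 0.85, 0.85, 0.85, 0.30, 0.30, 0.25)),
    `C-like`  = mk("C-like",
                   c(0.12, 0.70, 0.50, 0.05, 0.40, 0.40, 0.40, 0.15, 0.15, 0.12)),
    `ESC-like` = mk("ESC-like",
                    c(0.02, 0.50, 0.10, 0.01, 0.05, 0.05, 0.05, 0.02, 0.02, 0.02))
  )
}

#' Assign ground-truth methylation states per cell type
#'
#' Every forward-strand CpG in the genome receives one true methylation
#' probability per cell type, drawn from the Beta mixture of its enclosing
#' feature class. When features nest or overlap, the most specific class
#' wins by the fixed precedence gDMR > imprinted_cluster > promoter >
#' repeat_* > exon > intron > other; CpGs outside every feature use the
#' "background" entry of the profile.
#'
#' @param genome named character vector of contig sequences.
#' @param catalogue feature data.table (chrom, start, end, strand,
#'   feature_class, name).
#' @param profiles named list of cell-type profiles as returned by
#'   [default_profiles()].
#' @param seed integer seed; the map is deterministic given the seed.
#' @return data.table with columns chrom, pos, cell_type, m_true.
#' @export
assign_methylation_states <- function(genome, catalogue,
                                      profiles = default_profiles(),
                                      seed = 1L) {
  sites <- cpg_sites(genome)
  if (!nrow(sites)) stop("genome contains no CpG sites")
  cls <- rep("background", nrow(sites))
  gr_sites <- sites_to_granges(sites)
  # lowest precedence first so later (higher-precedence) classes overwrite
  for (fc in rev(.class_precedence)) {
    sub <- catalogue[feature_class == fc]
    if (!nrow(sub)) next
    hit <- IRanges::overlapsAny(gr_sites, dt_to_granges(sub))
    cls[hit] <- fc
  }
  with_seed(seed, {
    out <- vector("list", length(profiles))
    for (i in seq_along(profiles)) {
      prof <- profiles[[i]]
      par <- prof$params
      missing_cls <- setdiff(unique(cls), par$feature_class)
      if (length(missing_cls))
        stop("profile '", prof$name, "' has no entry for class(es): ",
             paste(missing_cls, collapse = ", "))
      idx <- match(cls, par$feature_class)
      if (any(par$weight_high < 0 | par$weight_high > 1) ||
          any(par$alpha_high <= 0 | par$beta_high <= 0 |
              par$alpha_low <= 0 | par$beta_low <= 0))
        stop("invalid Beta-mixture parameters in profile '", prof$name, "'")
      hi <- runif(nrow(sites)) < par$weight_high[idx]
      m <- numeric(nrow(sites))
      if (any(hi))
        m[hi] <- rbeta(sum(hi), par$alpha_high[idx][hi], par$beta_high[idx][hi])
      if (any(!hi))
        m[!hi] <- rbeta(sum(!hi), par$alpha_low[idx][!hi], par$beta_low[idx][!hi])
      out[[i]] <- data.table(chrom = sites$chrom, pos = sites$pos,
                             cell_type = prof$name, m_true = m)
    }
    rbindlist(out)
  })
}

#' Simulate an expression (FPKM) table tied to promoter methylation
#'
#' Convenience generator for exercising the expression-integration stage:
#' per gene and cell type, FPKM decays log-linearly with the mean true
#' methylation of the gene's promoter CpGs, plus log-normal noise. A small
#' fraction of genes is silenced (FPKM 0) in every cell type so the
#' all-zero-removal rule is exercised.
#'
#' @param tss data.table (gene, chrom, pos, strand) as from
#'   [generate_genome()].
#' @param state_map long data.table (chrom, pos, cell_type, m_true).
#' @param flank promoter half-width in bp.
#' @param base_fpkm median FPKM of an unmethylated promoter.
#' @param silencing_slope log-scale decay per unit methylation.
#' @param zero_fraction fraction of genes set to 0 in all cell types.
#' @param seed integer seed.
#' @return data.table with column gene plus one FPKM column per cell type.
#' @export
simulate_expression <- function(tss, state_map, flank = 1000L,
                                base_fpkm = 20, silencing_slope = 4,
                                zero_fraction = 0.05, seed = 1L) {
  stopifnot(nrow(tss) > 0L)
  cts <- unique(state_map$cell_type)
  with_seed(seed, {
    out <- data.table(gene = tss$gene)
    gr_prom <- GenomicRanges::GRanges(
      tss$chrom, IRanges::IRanges(pmax(tss$pos - flank, 0L) + 1L,
                                  tss$pos + flank))
    for (ct in cts) {
      sm <- state_map[cell_type == ct]
      ov <- GenomicRanges::findOverlaps(gr_prom, sites_to_granges(sm))
      mmean <- rep(0.1, nrow(tss))
      agg <- tapply(sm$m_true[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), mean)
      mmean[as.integer(names(agg))] <- agg
      fpkm <- base_fpkm * exp(-silencing_slope * mmean) *
        exp(rnorm(nrow(tss), 0, 0.4))
      out[[ct]] <- round(fpkm, 3)
    }
    zero <- runif(nrow(out)) < zero_fraction
    for (ct in cts) out[[ct]][zero] <- 0
    out
  })
}
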