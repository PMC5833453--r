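#' Read a genome from FASTA
#'
#' Sequences are uppercased and contig order preserved. Duplicate
#' headers, empty records and characters outside A/C/G/T/N are rejected.
#'
#' @param path FASTA file.
#' @return named character vector of contig sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA headers: ", paste(unique(nm[duplicated(nm)]),
                                            collapse = ", "))
  if (any(Biostrings::width(ss) == 0L))
    stop("empty FASTA record: ", nm[Biostrings::width(ss) == 0L][1L])
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in contig ", nm[bad][1L])
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a feature catalogue from BED
#'
#' Accepts 3- or 6-column BED (0-based half-open). The name field is
#' parsed as "feature_class:name"; records without a name get class
#' "other". When a genome is supplied, chromosome names and bounds are
#' validated.
#'
#' @param path BED file.
#' @param genome optional named character vector for validation.
#' @return data.table (chrom, start, end, strand, feature_class, name).
#' @export
read_bed <- function(path, genome = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns: ", path)
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end = as.integer(dt[[3L]]))
  out[, strand := if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."]
  nm <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else
    rep("other:feature", nrow(dt))
  has_class <- grepl(":", nm, fixed = TRUE)
  out[, feature_class := ifelse(has_class, sub(":.*$", "", nm), "other")]
  out[, name := ifelse(has_class, sub("^[^:]*:", "", nm), nm)]
  if (any(out$start < 0L | out$start >= out$end))
    stop("invalid BED interval (need 0 <= start < end) at line ",
         which(out$start < 0L | out$start >= out$end)[1L])
  if (!is.null(genome)) {
    len <- contig_lengths(genome)
    if (any(!out$chrom %in% names(len)))
      stop("unknown chromosome in BED: ",
           setdiff(out$chrom, names(len))[1L])
    if (any(out$end > len[out$chrom]))
      stop("BED interval beyond contig end at line ",
           which(out$end > len[out$chrom])[1L])
  }
  out[]
}

#' Write a feature catalogue to 6-column BED
#'
#' The name column carries "feature_class:name" so the classing survives a
#' round trip.
#'
#' @param features data.table (chrom, start, end, strand, feature_class,
#'   name).
#' @param path output file.
#' @export
write_bed <- function(features, path) {
  bed <- data.table(features$chrom, features$start, features$end,
                    paste0(features$feature_class, ":", features$name),
                    0L, features$strand)
  fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read / write long count tables
#'
#' Tab-separated with header (chrom, pos, sample, meth, total); the
#' simplest lossless superset of bedGraph-style methylation dialects.
#'
#' @param path file path.
#' @return data.table (chrom, pos, sample, meth, total).
#' @export
read_counts <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "sample", "meth", "total")
  if (!all(need %in% names(dt)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(dt$meth < 0L | dt$meth > dt$total))
    stop("invalid counts: need 0 <= meth <= total")
  dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
         sample = as.character(sample), meth = as.integer(meth),
         total = as.integer(total))]
}

#' @rdname read_counts
#' @param counts long count table.
#' @export
write_counts <- function(counts, path) {
  fwrite(counts, path, sep = "\t")
  invisible(path)
}

#' Read a 6-column methylation bedGraph dialect
#'
#' Shim for "chrom start end level meth unmeth" files (one sample per
#' file); returns the package's long count-table format with pos = start.
#'
#' @param path file path.
#' @param sample_id sample name to attach.
#' @return long count table.
#' @export
read_meth_bedgraph <- function(path, sample_id) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6L) stop("expected 6 columns (chrom start end level meth unmeth)")
  data.table(chrom = as.character(dt[[1L]]), pos = as.integer(dt[[2L]]),
             sample = sample_id, meth = as.integer(dt[[5L]]),
             total = as.integer(dt[[5L]]) + as.integer(dt[[6L]]))
}

#' Read / write a methylation state map
#'
#' Tab-separated (chrom, pos, cell_type, m_true).
#'
#' @param path file path.
#' @export
read_state_map <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "pos", "cell_type", "m_true")
  if (!all(need %in% names(dt)))
    stop("state map must have columns: ", paste(need, collapse = ", "))
  dt
}

#' @rdname read_state_map
#' @param state_map long state-map table.
#' @export
write_state_map <- function(state_map, path) {
  fwrite(state_map, path, sep = "\t")
  invisible(path)
}
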