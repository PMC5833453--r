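# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Named integer vector of contig lengths from a genome (named character vector).
contig_lengths <- function(genome) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  setNames(nchar(genome), names(genome))
}

assert_genome <- function(genome) {
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector of contig sequences")
  if (anyDuplicated(names(genome)))
    stop("contig names must be unique")
  if (any(nchar(genome) == 0L))
    stop("contig sequences must be non-empty")
  bad <- grepl("[^ACGT]", genome)
  if (any(bad))
    stop("genome alphabet restricted to A/C/G/T; offending contig: ",
         names(genome)[bad][1L])
  invisible(genome)
}

# GRanges from a data.table with chrom/start/end (0-based half-open in tables;
# GRanges is 1-based closed, so start+1..end).
dt_to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end)
  )
}

# GRanges of width-1 sites at the C of each CpG (0-based pos -> 1-based).
sites_to_granges <- function(dt) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$pos + 1L, width = 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Best rational approximation num/den of x with den <= max_den (continued
# fractions). Used so that effect-size thresholds stated as simple
# fractions (1/3, 0.333, 0.8) compare exactly against count ratios.
as_rational <- function(x, max_den = 1000000L) {
  stopifnot(is.finite(x), x >= 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps * max(1, x)) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(num = p1, den = q1)
}
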