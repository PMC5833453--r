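# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the base
# functions) used by the package.

# Two-sided Fisher p by explicit enumeration with binomial coefficients.
oracle_fisher <- function(a, b, cc, d) {
  m <- a + cc; n <- b + d; k <- a + b; N <- m + n
  lo <- max(0L, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(N, k)
  probs <- exp(logp)
  pobs <- probs[xs == a]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# MspI digest by a character-wise scan (no regex): a site starting at
# 0-based p cuts at offset p + 1.
oracle_digest <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cuts <- integer(0)
  if (n >= 4L) {
    i <- seq_len(n - 3L)
    site <- ch[i] == "C" & ch[i + 1L] == "C" & ch[i + 2L] == "G" &
      ch[i + 3L] == "G"
    cuts <- which(site)            # 1-based start = 0-based p + 1 = offset
  }
  bnd <- sort(unique(c(0L, cuts, n)))
  data.frame(start = bnd[-length(bnd)], end = bnd[-1L])
}

# Spearman correlation via explicit mid-ranks and the Pearson formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Average-linkage agglomeration recomputing all pairwise distances each
# step; returns the sequence of merge heights and final leaf groups.
oracle_average_linkage <- function(m) {
  groups <- as.list(seq_len(nrow(m)))
  d <- function(g1, g2) {
    tot <- 0
    for (i in g1) for (j in g2)
      tot <- tot + sqrt(sum((m[i, ] - m[j, ])^2))
    tot / (length(g1) * length(g2))
  }
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i < j) {
        dd <- d(groups[[i]], groups[[j]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# Exhaustive (step = 1) promoter CpG-density classing on a sequence,
# counting windows by direct substring inspection.
oracle_promoter_class <- function(seq, window = 500L, oe_rich = 0.75,
                                  oe_poor = 0.48, gc_rich = 0.55) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  w <- min(window, L)
  offs <- if (L <= w) 0L else 0L:(L - w)
  any_rich <- FALSE; any_mid <- FALSE
  for (o in offs) {
    win <- chars[(o + 1L):(o + w)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncpg <- sum(win[-w] == "C" & win[-1L] == "G")
    oe <- if (nc * ng > 0) ncpg * w / (nc * ng) else 0
    gc <- (nc + ng) / w
    if (oe >= oe_rich && gc >= gc_rich) any_rich <- TRUE
    if (oe >= oe_poor) any_mid <- TRUE
  }
  if (any_rich) "HCP" else if (!any_mid) "LCP" else "ICP"
}

# random DNA sequence
random_seq <- function(n, probs = c(0.3, 0.2, 0.2, 0.3)) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
         collapse = "")
}

# Long count table from explicit vectors, for small fixtures.
counts_fixture <- function(chrom, pos, sample, meth, total) {
  data.table::data.table(chrom = chrom, pos = pos, sample = sample,
                         meth = meth, total = total)
}

# Single-contig fragment table covering [0, len).
full_fragment <- function(len, chrom = "chr1") {
  data.table::data.table(chrom = chrom, start = 0L, end = as.integer(len),
                         length = as.integer(len))
}

# State map at given positions with constant m per cell type.
flat_state_map <- function(pos, m_by_type, chrom = "chr1") {
  data.table::rbindlist(lapply(names(m_by_type), function(ct)
    data.table::data.table(chrom = chrom, pos = as.integer(pos),
                           cell_type = ct, m_true = m_by_type[[ct]])))
}

# all permutations of 1..n (tiny n), for label-permutation matching
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in combinat_perms(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
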