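#' K-means clustering of matrix rows
#'
#' Lloyd's algorithm (via [stats::kmeans()]) with k-means++ seeding,
#' squared-Euclidean distance, and the best of `n_restarts` runs by total
#' within-cluster sum of squares. Runs that converge with an empty cluster
#' are discarded and re-seeded. Within each cluster the rows are ordered
#' by identifier. Deterministic given the seed.
#'
#' @param m numeric matrix with unique rownames; rows are clustered.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts number of independent seedings.
#' @param iter_max maximum Lloyd iterations per run.
#' @return list with `cluster` (named integer vector, rows ordered by
#'   cluster then identifier), `centers`, `tot_withinss`.
#' @export
kmeans_rows <- function(m, k = 3L, seed = 1L, n_restarts = 10L,
                        iter_max = 100L) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (nrow(m) < k) stop("fewer rows than clusters requested")
  with_seed(seed, {
    best <- NULL
    done <- 0L
    guard <- 0L
    while (done < n_restarts && guard < 10L * n_restarts) {
      guard <- guard + 1L
      init <- kmeanspp_centers(m, k)
      fit <- tryCatch(
        suppressWarnings(kmeans(m, centers = init, iter.max = iter_max,
                                algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(fit) || any(fit$size == 0L)) next  # empty cluster: re-seed
      done <- done + 1L
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) stop("k-means failed to produce k non-empty clusters")
    cl <- best$cluster
    names(cl) <- rownames(m)
    cl <- cl[order(cl, names(cl))]
    list(cluster = cl, centers = best$centers,
         tot_withinss = best$tot.withinss)
  })
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((m - matrix(m[idx[1L], ], n, ncol(m), byrow = TRUE))^2)
  if (k > 1L) for (j in 2:k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1L, prob = prob)
    dj <- rowSums((m - matrix(m[idx[j], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  m[idx, , drop = FALSE] + 0  # plain matrix of k starting centers
}

#' Hierarchical clustering of matrix rows
#'
#' Agglomerative clustering via [stats::hclust()] on the chosen row
#' distance; merge heights are checked to be non-decreasing (average
#' linkage on Euclidean distances is monotone here).
#'
#' @param m numeric matrix with >= 2 rows.
#' @param linkage linkage method passed to hclust (default "average").
#' @param distance distance method passed to [stats::dist()].
#' @return list with the `hclust` object, `order` (leaf labels in
#'   dendrogram order) and `heights`.
#' @export
hierarchical_rows <- function(m, linkage = "average", distance = "euclidean") {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two rows")
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  hc <- hclust(dist(m, method = distance), method = linkage)
  if (is.unsorted(hc$height, strictly = FALSE))
    stop("internal error: merge heights decreased")
  list(hclust = hc, order = rownames(m)[hc$order], heights = hc$height)
}

#' Convert an FPKM table to per-gene expression Z-scores
#'
#' Genes with zero FPKM in every sample are removed first (unexpressed);
#' each remaining row is centred and scaled with the sample standard
#' deviation (n - 1 denominator). Rows with zero variance but non-zero
#' expression cannot be scaled and are removed with a message.
#'
#' @param fpkm data.table with a `gene` column and one numeric FPKM column
#'   per sample (>= 2 samples).
#' @return data.table (gene + Z-score columns); attribute
#'   "removed_zero_variance" carries the count of dropped constant rows.
#' @export
expression_zscore <- function(fpkm) {
  fpkm <- as.data.table(fpkm)
  scols <- setdiff(names(fpkm), "gene")
  if (length(scols) < 2L) stop("Z-score undefined with fewer than 2 samples")
  m <- as.matrix(fpkm[, scols, with = FALSE])
  rownames(m) <- fpkm$gene
  m <- m[rowSums(m != 0) > 0L, , drop = FALSE]     # no expression anywhere
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  flat <- s == 0
  if (any(flat))
    message(sum(flat), " gene(s) with zero expression variance removed")
  m <- m[!flat, , drop = FALSE]
  z <- (m - mu[!flat]) / s[!flat]
  out <- data.table(gene = rownames(m))
  for (j in seq_along(scols)) out[[scols[j]]] <- z[, j]
  attr(out, "removed_zero_variance") <- sum(flat)
  out
}

#' Assemble tidy heatmap/report tables
#'
#' Joins DMR methylation levels with cluster labels and imprinted-cluster
#' names into a (region x sample) matrix table, and passes through the
#' (gene x sample) expression Z-score matrix. Row counts are conserved
#' from the inputs; any key mismatch between the cluster assignment and
#' the DMR table is reported.
#'
#' @param dmrs annotated DMR table (with level_* columns; optionally
#'   imprinted_dmr flags).
#' @param clusters optional result of [kmeans_rows()] on the DMR level
#'   matrix.
#' @param expression_z optional Z-score table from [expression_zscore()].
#' @return list with `methylation` (region table with region_id, levels,
#'   cluster) and `expression` (the Z table or NULL), plus `join_report`.
#' @export
build_report_tables <- function(dmrs, clusters = NULL, expression_z = NULL) {
  dmrs <- copy(as.data.table(dmrs))
  lvl_cols <- grep("^level_", names(dmrs), value = TRUE)
  if (nrow(dmrs))
    dmrs[, region_id := sprintf("%s:%d-%d", chrom, start, end)]
  else dmrs[, region_id := character()]
  join_report <- list(n_regions = nrow(dmrs), n_unmatched_clusters = 0L)
  if (!is.null(clusters)) {
    cl <- data.table(region_id = names(clusters$cluster),
                     cluster = as.integer(clusters$cluster))
    unmatched <- setdiff(cl$region_id, dmrs$region_id)
    join_report$n_unmatched_clusters <- length(unmatched)
    dmrs <- merge(dmrs, cl, by = "region_id", all.x = TRUE, sort = FALSE)
  }
  keep <- c("region_id", "chrom", "start", "end",
            intersect(c("comparison", "direction", "n_cpgs", "promoter_dmr",
                        "imprinted_dmr", "gdmr_overlap", "repeat_overlap",
                        "cluster"), names(dmrs)), lvl_cols)
  meth <- dmrs[, keep, with = FALSE]
  setorder(meth, chrom, start)
  list(methylation = meth,
       expression = expression_z,
       join_report = join_report)
}

#' Row-level matrix from a DMR table
#'
#' @param dmrs DMR table with level_* columns.
#' @return numeric matrix (regions x samples) with region_id rownames.
#' @export
dmr_level_matrix <- function(dmrs) {
  dmrs <- as.data.table(dmrs)
  lvl_cols <- grep("^level_", names(dmrs), value = TRUE)
  m <- as.matrix(dmrs[, lvl_cols, with = FALSE])
  colnames(m) <- sub("^level_", "", lvl_cols)
  rownames(m) <- sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end)
  m
}
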