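#' Default pipeline configuration
#'
#' All analysis thresholds default to the printed protocol values
#' (coverage gate 10, strong-DMC delta one third (>33.3%) and p 0.05, level categories
#' 0.3/0.8, size selection 170-370 bp, promoter flank 1000 bp, classing
#' windows 500 bp at 5-bp step with O/E cuts 0.75/0.48 and GC 0.55, DMR
#' chaining gap 300 bp with >= 3 CpGs, K-means K = 3); simulator settings
#' are generator choices documented in the package vignette.
#'
#' @param seed master seed for the run.
#' @return named list of configuration values.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    # simulator
    n_contigs = 2L, contig_length = 500000L,
    n_promoters = 40L, n_repeats = 80L, n_imprinted_clusters = 4L,
    cpg_island_fraction = 0.5,
    mean_coverage = 30, conversion_efficiency = 0.995,
    replicate_dispersion = 0.05, n_replicates = 2L,
    # thresholds (protocol constants)
    min_cov = 10L, delta_threshold = 1 / 3, p_threshold = 0.05,
    low_cut = 0.3, high_cut = 0.8,
    size_min = 170L, size_max = 370L,
    promoter_flank = 1000L, class_window = 500L, class_step = 5L,
    oe_rich = 0.75, oe_poor = 0.48, gc_rich = 0.55,
    max_gap = 300L, min_cpgs = 3L, kmeans_k = 3L
  )
}

.required_config <- names(default_config())

#' @rdname default_config
#' @param config configuration list to validate.
#' @export
validate_config <- function(config) {
  missing <- setdiff(.required_config, names(config))
  if (length(missing))
    stop("configuration missing required field(s): ",
         paste(missing, collapse = ", "))
  invisible(config)
}

#' Read / write a pipeline configuration (JSON, lossless round trip)
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("seed", "n_contigs", "contig_length", "n_promoters",
              "n_repeats", "n_imprinted_clusters", "n_replicates",
              "min_cov", "size_min", "size_max", "promoter_flank",
              "class_window", "class_step", "max_gap", "min_cpgs",
              "kmeans_k"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- as.integer(cfg[[f]])
  validate_config(cfg)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

write_table <- function(dt, dir, file, thresholds = NULL) {
  path <- file.path(dir, file)
  if (!is.null(thresholds)) {
    hdr <- paste0("# thresholds: ",
                  paste(names(thresholds), unlist(thresholds),
                        sep = "=", collapse = " "))
    writeLines(hdr, path)
    dt2 <- copy(as.data.table(dt))
    listcols <- names(dt2)[vapply(dt2, is.list, logical(1L))]
    if (length(listcols)) dt2[, (listcols) := NULL]
    fwrite(dt2, path, sep = "\t", append = TRUE, col.names = TRUE)
  } else {
    dt2 <- copy(as.data.table(dt))
    listcols <- names(dt2)[vapply(dt2, is.list, logical(1L))]
    if (length(listcols)) dt2[, (listcols) := NULL]
    fwrite(dt2, path, sep = "\t")
  }
  path
}

#' Run the full RRBS analysis pipeline
#'
#' Chains simulate -> quantify -> DMC -> DMR -> merge -> annotate ->
#' cluster -> report on the synthetic study design (three cell
#' archetypes, replicated), writing tab-separated artifacts plus a JSON
#' manifest (package version, seed, thresholds, per-stage row counts) to
#' `out_dir`. Deterministic given config + seed: re-running with the same
#' configuration yields byte-identical tabular outputs.
#'
#' @param config configuration list from [default_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "rrbspipe",
                   version = as.character(packageVersion("rrbspipe")),
                   seed = config$seed,
                   thresholds = config[c("min_cov", "delta_threshold",
                                         "p_threshold", "low_cut", "high_cut",
                                         "size_min", "size_max", "max_gap",
                                         "min_cpgs", "kmeans_k")],
                   stages = list())
  thr <- manifest$thresholds
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## simulate
  sim <- stage("simulate", {
    g <- generate_genome(n_contigs = config$n_contigs,
                         contig_length = config$contig_length,
                         n_promoters = config$n_promoters,
                         n_repeats = config$n_repeats,
                         n_imprinted_clusters = config$n_imprinted_clusters,
                         cpg_island_fraction = config$cpg_island_fraction,
                         seed = config$seed)
    profiles <- default_profiles()
    states <- assign_methylation_states(g$genome, g$catalogue, profiles,
                                        seed = config$seed + 1L)
    frag <- digest_mspi(g$genome)
    kept <- size_select(frag, config$size_min, config$size_max)
    plan <- data.table(
      sample_id = unlist(lapply(names(profiles), function(ct)
        paste0(ct, "_rep", seq_len(config$n_replicates)))),
      cell_type = rep(names(profiles), each = config$n_replicates))
    counts <- simulate_counts(kept, states, plan,
                              mean_coverage = config$mean_coverage,
                              conversion_efficiency = config$conversion_efficiency,
                              replicate_dispersion = config$replicate_dispersion,
                              seed = config$seed + 2L)
    write_fasta(g$genome, file.path(out_dir, "genome.fa"))
    write_bed(g$catalogue, file.path(out_dir, "features.bed"))
    write_state_map(states, file.path(out_dir, "state_map.tsv"))
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    manifest$stages$simulate <- list(
      status = "ok", n_fragments = nrow(frag), n_fragments_selected = nrow(kept),
      n_count_records = nrow(counts))
    list(g = g, states = states, kept = kept, counts = counts, plan = plan,
         cell_types = names(profiles))
  })

  ## quantify
  qt <- stage("quantify", {
    groups <- split(sim$plan$sample_id, sim$plan$cell_type)
    merged <- merge_replicates(sim$counts, groups)
    gated <- filter_coverage(merged, config$min_cov)
    levels <- methylation_levels(gated)
    sites_in <- length(unique(paste(merged$chrom, merged$pos)))
    cats <- categorize_levels(levels, config$low_cut, config$high_cut)
    corr <- sample_correlation(levels)
    hist <- level_histogram(levels, 20L)
    write_table(gated, out_dir, "counts_gated.tsv",
                thr["min_cov"])
    write_table(levels, out_dir, "levels.tsv", thr["min_cov"])
    write_table(cats, out_dir, "category_fractions.tsv",
                thr[c("low_cut", "high_cut")])
    write_table(hist, out_dir, "level_histogram.tsv", NULL)
    fwrite(data.table(sample = rownames(corr), corr),
           file.path(out_dir, "spearman.tsv"), sep = "\t")
    manifest$stages$quantify <- list(
      status = "ok", sites_in = sites_in,
      sites_gated = nrow(levels),
      sites_dropped = sites_in - nrow(levels))
    list(merged = merged, gated = gated, levels = levels, cats = cats,
         corr = corr)
  })

  ## differential methylation
  cts <- sim$cell_types
  comparisons <- list(c(cts[1L], cts[3L]),   # 4F-like vs ESC-like
                      c(cts[2L], cts[3L]),   # C-like vs ESC-like
                      c(cts[1L], cts[2L]))   # 4F-like vs C-like
  dm <- stage("dmc_dmr", {
    res <- lapply(comparisons, function(cmp) {
      dmcs <- call_strong_dmcs(qt$gated, cmp,
                               delta_threshold = config$delta_threshold,
                               p_threshold = config$p_threshold)
      dmrs <- call_dmrs(dmcs, qt$levels, max_gap = config$max_gap,
                        min_cpgs = config$min_cpgs)
      tag <- paste(cmp, collapse = "_vs_")
      write_table(dmcs, out_dir, paste0("dmc_", tag, ".tsv"),
                  thr[c("delta_threshold", "p_threshold")])
      write_table(dmrs, out_dir, paste0("dmr_", tag, ".tsv"),
                  thr[c("max_gap", "min_cpgs")])
      list(comparison = tag, dmcs = dmcs, dmrs = dmrs)
    })
    manifest$stages$dmc_dmr <- lapply(res, function(r)
      list(comparison = r$comparison,
           n_tested = nrow(r$dmcs),
           n_strong = sum(r$dmcs$is_strong),
           n_dmrs = nrow(r$dmrs)))
    res
  })

  ## merge promoter-overlapping DMR sets of the two vs-ESC comparisons
  mg <- stage("merge", {
    ann1 <- annotate_dmrs(dm[[1L]]$dmrs, sim$g$catalogue)
    ann2 <- annotate_dmrs(dm[[2L]]$dmrs, sim$g$catalogue)
    p1 <- ann1[promoter_dmr == TRUE & direction == "hyper"]
    p2 <- ann2[promoter_dmr == TRUE & direction == "hyper"]
    merged <- merge_dmr_sets(p1, p2, qt$levels)
    write_table(merged, out_dir, "merged_promoter_dmrs.tsv", NULL)
    manifest$stages$merge <- list(status = "ok",
                                   n_set1 = nrow(p1), n_set2 = nrow(p2),
                                   n_merged = nrow(merged))
    merged
  })

  ## annotation
  an <- stage("annotate", {
    proms <- define_promoters(sim$g$tss, contig_lengths(sim$g$genome),
                              config$promoter_flank)
    classed <- classify_promoter_cpg_density(
      proms, sim$g$genome, window = config$class_window,
      step = config$class_step, oe_rich = config$oe_rich,
      oe_poor = config$oe_poor, gc_rich = config$gc_rich)
    strong1 <- dm[[3L]]$dmcs[is_strong == TRUE & direction == "hyper"]
    locs <- assign_genomic_location(strong1[, .(chrom, pos)],
                                    sim$g$catalogue)
    write_table(classed, out_dir, "promoters_classed.tsv", NULL)
    write_table(locs, out_dir, "dmc_locations.tsv", NULL)
    manifest$stages$annotate <- list(
      status = "ok", n_promoters = nrow(classed),
      class_counts = as.list(table(classed$cpg_class)),
      location_counts = as.list(table(locs$location)))
    list(promoters = classed, locations = locs)
  })

  ## clustering + report
  rp <- stage("cluster_report", {
    clusters <- NULL
    if (nrow(mg) >= config$kmeans_k) {
      m <- dmr_level_matrix(mg)
      clusters <- kmeans_rows(m, k = config$kmeans_k,
                              seed = config$seed + 3L)
    }
    fpkm <- simulate_expression(sim$g$tss, sim$states,
                                seed = config$seed + 4L)
    write_table(fpkm, out_dir, "fpkm.tsv", NULL)
    z <- expression_zscore(fpkm)
    annotated <- annotate_dmrs(mg, sim$g$catalogue)
    tabs <- build_report_tables(annotated, clusters, z)
    write_table(tabs$methylation, out_dir, "report_methylation.tsv", NULL)
    write_table(tabs$expression, out_dir, "report_expression_z.tsv", NULL)
    if (!is.null(clusters))
      write_table(data.table(region_id = names(clusters$cluster),
                             cluster = as.integer(clusters$cluster)),
                  out_dir, "kmeans_clusters.tsv", thr["kmeans_k"])
    if (nrow(mg) >= 2L) {
      hy <- hierarchical_rows(dmr_level_matrix(mg))
      writeLines(hy$order, file.path(out_dir, "dmr_leaf_order.txt"))
    }
    manifest$stages$cluster_report <- list(
      status = "ok", n_regions = nrow(tabs$methylation),
      n_expression_rows = nrow(tabs$expression))
    tabs
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, quant = qt, diff = dm, merged = mg,
                 annotation = an, report = rp, manifest = manifest))
}
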