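#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors the arguments of [run_pipeline()]: either a `sim` block
#' (simulation settings and planted effects) or an `inputs` block (paths to
#' a marker file and a pool-counts manifest), plus optional `lod` settings
#' and `thresholds`.
#'
#' @param path YAML file.
#' @return a nested list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (sum(c("sim", "inputs") %in% names(cfg)) != 1L)
    stop("configuration must contain exactly one of 'sim' or 'inputs'")
  cfg
}

default_thresholds <- function(th = NULL) {
  utils::modifyList(list(lod = 5, drop = 2, alpha = 0.01, min_depth = 10),
                    th %||% list())
}

# simulate one cross's MAT-sorted control and selected pools and return
# their binned counts plus per-pool count tables
simulate_cross_pools <- function(design, k, markers, scfg, effects, condition,
                                 seed) {
  info <- cross_info(design, k)
  pools <- list()
  for (mt in c("a", "alpha")) {
    sub <- derive_seed(seed, paste0("cross", k, "/", mt))
    pop <- simulate_segregants(info, markers, n = scfg$pool_size,
                               model = scfg$model,
                               seed = derive_seed(sub, "meiosis"))
    sorted <- apply_selection(pop, markers, effects = list(), mat_filter = mt,
                              pool_size = scfg$pool_size,
                              seed = derive_seed(sub, "sort"))
    selected <- apply_selection(sorted, markers, effects = effects,
                                pool_size = scfg$pool_size,
                                seed = derive_seed(sub, "select"))
    pools[[mt]] <- list(
      control = sequence_pool(sorted, markers, scfg, condition = "YPD",
                              mating_type = mt,
                              seed = derive_seed(sub, "seq-control")),
      selected = sequence_pool(selected, markers, scfg, condition = condition,
                               mating_type = mt,
                               seed = derive_seed(sub, "seq-selected")))
  }
  pools
}

#' Run the full round-robin X-QTL pipeline
#'
#' Orchestrates the analysis stages in order: allele frequencies from pool
#' counts, selection-versus-control contrasts, binned LOD scans, QTL calls
#' with mating-type replication, QTL groups across crosses, and the
#' segregation-pattern association for each group. With a `sim` block the
#' input pools are generated by the synthetic-data module; with an `inputs`
#' block they are read from disk. All result tables are written under
#' `out_dir` in the package's text formats, together with a run log
#' recording the seed and thresholds; a run is deterministic given its
#' seed.
#'
#' @param config nested list (see [read_pipeline_config()]). Supported
#'   keys: `seed`; `sim` with `n_strains`, `chrom_lengths`,
#'   `markers_per_chrom`, `pool_size`, `depth`, `private_frac`,
#'   `condition`, `crosses` and `effects` (list of lists with `chrom`,
#'   `pos`, `beta`); `inputs` with `markers` (path) and `manifest` (path to
#'   a TSV with a `file` column of pool-counts paths); `lod` with
#'   `bin_bp`, `grid_size`, `bp_per_cM`; `thresholds` with `lod`, `drop`,
#'   `alpha`, `min_depth`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the calls, groups and association tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (sum(c("sim", "inputs") %in% names(config)) != 1L)
    stop("config must contain exactly one of 'sim' or 'inputs'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  th <- default_thresholds(config$thresholds)

  if (!is.null(config$sim)) {
    s <- config$sim
    scfg_args <- s[intersect(names(s), names(formals(sim_config)))]
    if (!is.null(scfg_args$chrom_lengths))
      scfg_args$chrom_lengths <- unlist(scfg_args$chrom_lengths)
    scfg <- do.call(sim_config, scfg_args)
    markers <- simulate_parent_genomes(scfg, seed = derive_seed(seed, "genomes"))
    design <- build_round_robin(attr(markers, "strains"))
    effects <- lapply(s$effects %||% list(), function(e)
      qtl_effect(e$chrom, e$pos, unlist(e$beta)))
    # plant effects at the nearest marker so selection can act on them
    effects <- lapply(effects, function(e) {
      on_chrom <- which(markers$chrom == e$chrom)
      if (!length(on_chrom)) stop("effect chromosome not simulated: ", e$chrom)
      j <- on_chrom[which.min(abs(markers$pos[on_chrom] - e$pos))]
      qtl_effect(e$chrom, markers$pos[j], e$beta, e$condition)
    })
    condition <- s$condition %||% "stress"
    cross_ids <- s$crosses %||% design$crosses$cross
    counts <- list()
    for (k in cross_ids) {
      pools <- simulate_cross_pools(design, k, markers, scfg, effects,
                                    condition, seed)
      for (mt in names(pools)) for (cc in names(pools[[mt]]))
        counts[[paste(k, mt, cc, sep = "_")]] <- pools[[mt]][[cc]]
    }
    write_marker_vcf(markers, file.path(out_dir, "markers.vcf"))
    lcfg <- do.call(lod_config, utils::modifyList(
      list(pool_size = scfg$pool_size), config$lod %||% list()))
  } else {
    markers <- read_markers(config$inputs$markers)
    design <- if (length(attr(markers, "strains")) >= 3L)
      build_round_robin(attr(markers, "strains")) else NULL
    manifest <- read.delim(config$inputs$manifest, stringsAsFactors = FALSE)
    tables <- lapply(manifest$file, read_pool_counts)
    counts <- list()
    for (tab in tables) {
      key <- paste(attr(tab, "cross"), attr(tab, "mating_type"),
                   if (identical(attr(tab, "condition"), "YPD")) "control"
                   else "selected", sep = "_")
      counts[[key]] <- tab
    }
    lcfg <- do.call(lod_config, config$lod %||% list())
    cross_ids <- sort(unique(vapply(tables, function(x) attr(x, "cross"), 1L)))
  }

  # frequencies, contrasts, LOD scans and calls per cross and mating type
  all_calls <- list()
  cross_tracks <- list()
  log_lines <- c("rrqtl pipeline run",
                 paste0("package_version=", as.character(utils::packageVersion("rrqtl"))),
                 paste0("seed=", seed),
                 paste0("thresholds: lod=", th$lod, " drop=", th$drop,
                        " alpha=", th$alpha, " min_depth=", th$min_depth),
                 paste0("lod_config: pool_size=", lcfg$pool_size,
                        " bin_bp=", lcfg$bin_bp, " grid_size=", lcfg$grid_size,
                        " bp_per_cM=", lcfg$model$bp_per_cM))
  for (k in cross_ids) {
    per_mt <- list()
    for (mt in c("a", "alpha")) {
      sel <- counts[[paste(k, mt, "selected", sep = "_")]]
      con <- counts[[paste(k, mt, "control", sep = "_")]]
      if (is.null(sel) || is.null(con)) next
      f_sel <- compute_frequencies(sel, th$min_depth)
      f_con <- compute_frequencies(con, th$min_depth)
      contrast <- contrast_frequencies(f_sel, f_con)
      lod <- contrast_lod(bin_counts(sel, lcfg), bin_counts(con, lcfg), lcfg)
      calls <- call_qtl(lod, threshold = th$lod, drop = th$drop,
                        contrast = contrast)
      stem <- file.path(out_dir, sprintf("cross%02d_MAT%s", k, mt))
      write_track_tsv(f_sel, paste0(stem, "_freq_selected.tsv"))
      write_track_tsv(f_con, paste0(stem, "_freq_control.tsv"))
      write_track_tsv(contrast, paste0(stem, "_contrast.tsv"))
      write_lod_bedgraph(lod, paste0(stem, "_lod.bedgraph"))
      per_mt[[mt]] <- calls
      cross_tracks[[as.character(k)]] <-
        c(cross_tracks[[as.character(k)]] %||% list(), list(lod))
    }
    if (length(per_mt) == 2L) {
      merged <- replicate_support(per_mt$a, per_mt$alpha)
      merged$cross <- rep(k, nrow(merged))
      all_calls[[as.character(k)]] <- merged
    } else if (length(per_mt) == 1L) {
      all_calls[[as.character(k)]] <- per_mt[[1L]]
    }
    log_lines <- c(log_lines, sprintf("cross %d: %d call(s)", k,
                                      nrow(all_calls[[as.character(k)]] %||%
                                             data.frame())))
  }
  calls <- do.call(rbind, all_calls)
  result <- list(calls = calls, groups = NULL, association = NULL)
  if (!is.null(calls) && nrow(calls) > 0L) {
    write_qtl_bed(calls, file.path(out_dir, "qtl_calls.bed"))
    replicated <- calls[!is.na(calls$replicated) & calls$replicated, ]
    grouping_calls <- if (nrow(replicated) > 0L) replicated else calls
    groups <- group_across_crosses(grouping_calls, cross_tracks)
    write.table(cbind(groups$groups, groups$lod),
                file.path(out_dir, "qtl_groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    result$groups <- groups
    if (!is.null(design)) {
      assoc <- list()
      for (gi in seq_len(nrow(groups$groups))) {
        gr <- groups$groups[gi, ]
        region <- list(chrom = gr$chrom, lower = gr$lower, upper = gr$upper)
        seg <- tryCatch(segregation_matrix(markers, design, region),
                        error = function(e) NULL)
        if (is.null(seg)) next
        lodvec <- setNames(numeric(nrow(design$crosses)),
                           design$crosses$cross)
        common <- intersect(colnames(groups$lod), names(lodvec))
        lodvec[common] <- groups$lod[gi, common]
        res <- significant_variants(seg, lodvec, alpha = th$alpha,
                                    n_perm = 1000,
                                    seed = derive_seed(seed, paste0("assoc", gi)))
        res$group <- gr$group
        assoc[[length(assoc) + 1L]] <- as.data.frame(res)
      }
      if (length(assoc)) {
        assoc <- do.call(rbind, assoc)
        write.table(assoc, file.path(out_dir, "association.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        result$association <- assoc
      }
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(result)
}
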