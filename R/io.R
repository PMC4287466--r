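# metadata comment header shared by the TSV writers
meta_header <- function(x, keys) {
  vals <- lapply(keys, function(k) attr(x, k))
  keep <- !vapply(vals, is.null, TRUE)
  sprintf("#%s=%s", keys[keep], vapply(vals[keep], as.character, ""))
}

read_meta_header <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#") & grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(sub("^#", "", lines), "=", fixed = TRUE)
  setNames(lapply(kv, function(x) x[2L]), vapply(kv, `[[`, "", 1L))
}

#' Read a parent-strain marker table
#'
#' Accepts either a VCF with one haploid sample column per parent strain
#' (biallelic records only) or the package's marker TSV. Multi-allelic
#' records and records with missing genotypes are dropped with a message
#' reporting the counts. A VCF record carrying the `MAT` INFO flag is taken
#' as the mating-type locus.
#'
#' @param path path to a `.vcf` or `.tsv` file.
#' @return a `marker_table`.
#' @export
read_markers <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    gt <- vcfR::extract.gt(v)
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                       dimnames = list(NULL, colnames(v@gt)[-1]))
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    miss <- apply(gt, 1L, function(g) any(is.na(g) | g == "."))
    drop <- multi | miss
    if (any(drop))
      message(sum(multi), " multi-allelic and ", sum(miss & !multi),
              " missing-genotype record(s) dropped")
    if (!any(!drop)) stop("no usable biallelic records in ", path)
    fix <- fix[!drop, , drop = FALSE]
    gt <- gt[!drop, , drop = FALSE]
    g <- apply(gt, 2L, function(x) as.integer(substr(x, 1L, 1L)))
    if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = dimnames(gt))
    info <- fix[, "INFO"]
    out <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      is_mat = !is.na(info) & grepl("(^|;)MAT(;|$)", info),
                      g, check.names = FALSE, stringsAsFactors = FALSE)
    strains <- colnames(gt)
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "#")
    stopifnot(all(c("chrom", "pos", "is_mat") %in% names(out)))
    out$is_mat <- as.logical(out$is_mat)
    strains <- setdiff(names(out), c("chrom", "pos", "is_mat"))
  }
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  attr(out, "strains") <- strains
  class(out) <- c("marker_table", "data.frame")
  validate_marker_table(out)
}

#' Write a marker table as a minimal VCF
#'
#' One haploid sample column per parent strain, `GT` 0 or 1; synthetic
#' REF/ALT bases (the analysis is allele-index based). The mating-type
#' locus is tagged with the `MAT` INFO flag.
#'
#' @param markers a `marker_table`.
#' @param path output path.
#' @export
write_marker_vcf <- function(markers, path) {
  strains <- attr(markers, "strains")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rrqtl",
    "##INFO=<ID=MAT,Number=0,Type=Flag,Description=\"Mating-type locus\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", strains), collapse = "\t"))
  g <- as.matrix(markers[strains])
  body <- paste(markers$chrom, markers$pos, ".", "A", "T", ".", "PASS",
                ifelse(markers$is_mat, "MAT", "."), "GT",
                apply(g, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a marker table as TSV
#' @param markers a `marker_table`.
#' @param path output path.
#' @export
write_marker_tsv <- function(markers, path) {
  write.table(as.data.frame(markers), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

pool_meta_keys <- c("cross", "parent_a", "parent_b", "mating_type",
                    "condition", "replicate")

#' Write pooled counts (or a frequency/contrast track) as TSV
#'
#' Pool metadata (cross, parents, mating type, condition, replicate) is
#' stored in `#key=value` comment lines so the file round-trips through
#' the matching reader.
#'
#' @param x a `pool_counts`, `freq_track` or `contrast_track`.
#' @param path output path.
#' @export
write_track_tsv <- function(x, path) {
  keys <- c(pool_meta_keys, "kind", "min_depth")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(x, keys), con)
  write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read pooled counts from TSV
#' @param path path written by [write_track_tsv()] (columns `chrom`, `pos`,
#'   `count_a`, `depth`).
#' @return a `pool_counts` object.
#' @export
read_pool_counts <- function(path) {
  meta <- read_meta_header(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pool_counts(df,
              cross = if (!is.null(meta$cross)) as.integer(meta$cross) else NA_integer_,
              parent_a = meta$parent_a %||% NA_character_,
              parent_b = meta$parent_b %||% NA_character_,
              mating_type = meta$mating_type %||% NA_character_,
              condition = meta$condition %||% NA_character_,
              replicate = if (!is.null(meta$replicate)) as.integer(meta$replicate) else 1L)
}

#' Read a frequency or contrast track from TSV
#' @param path path written by [write_track_tsv()].
#' @return a `freq_track` or `contrast_track` (decided by its columns).
#' @export
read_track_tsv <- function(path) {
  meta <- read_meta_header(path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  cls <- if ("diff" %in% names(df)) "contrast_track" else "freq_track"
  for (k in pool_meta_keys) {
    v <- meta[[k]]
    attr(df, k) <- if (is.null(v)) NA else
      if (k %in% c("cross", "replicate")) as.integer(v) else v
  }
  if (!is.null(meta$kind)) attr(df, "kind") <- meta$kind
  if (!is.null(meta$min_depth)) attr(df, "min_depth") <- as.numeric(meta$min_depth)
  class(df) <- c(cls, "data.frame")
  df
}

#' Write a LOD track as bedGraph
#'
#' Standard 4-column bedGraph (chrom, 0-based half-open start/end, LOD).
#'
#' @param track a `lod_track`.
#' @param path output path.
#' @export
write_lod_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta_header(track, c(pool_meta_keys, "bin_bp")),
               "track type=bedGraph name=LOD"), con)
  write.table(data.frame(track$chrom, track$start - 1L, track$end, track$lod),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a LOD track from bedGraph
#' @param path path written by [write_lod_bedgraph()].
#' @return a `lod_track`.
#' @export
read_lod_bedgraph <- function(path) {
  meta <- read_meta_header(path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & !startsWith(lines, "track")]
  df <- read.delim(text = body, header = FALSE,
                   col.names = c("chrom", "start0", "end0", "lod"),
                   stringsAsFactors = FALSE)
  r <- if (!is.null(meta$bin_bp)) as.integer(meta$bin_bp) else
    df$end0[1L] - df$start0[1L]
  out <- data.frame(chrom = df$chrom, start = df$start0 + 1L, end = df$end0,
                    pos = df$start0 + 1L + (r - 1) / 2, lod = df$lod,
                    stringsAsFactors = FALSE)
  for (k in pool_meta_keys) {
    v <- meta[[k]]
    attr(out, k) <- if (is.null(v)) NA else
      if (k %in% c("cross", "replicate")) as.integer(v) else v
  }
  attr(out, "bin_bp") <- r
  class(out) <- c("lod_track", "data.frame")
  out
}

#' Write QTL calls as a BED-like TSV
#' @param calls a `qtl_calls` data.frame.
#' @param path output path.
#' @export
write_qtl_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$lower - 1,
                   end = calls$upper, peak_pos = calls$peak_pos,
                   peak_lod = calls$peak_lod, cross = calls$cross,
                   condition = calls$condition,
                   mating_type = calls$mating_type,
                   replicated = calls$replicated,
                   direction = calls$direction)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read QTL calls written by [write_qtl_bed()]
#' @param path input path.
#' @return a `qtl_calls` data.frame.
#' @export
read_qtl_bed <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   col.names = strsplit(header, "\t")[[1L]],
                   stringsAsFactors = FALSE)
  out <- data.frame(chrom = df$chrom, peak_pos = df$peak_pos,
                    peak_lod = df$peak_lod, lower = df$start + 1,
                    upper = df$end, direction = df$direction,
                    cross = df$cross, condition = df$condition,
                    mating_type = df$mating_type, replicated = df$replicated,
                    stringsAsFactors = FALSE)
  new_qtl_calls(out)
}
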