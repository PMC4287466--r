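#' Construct a pool-counts table
#'
#' Per-marker pooled sequencing counts for one sequenced segregant pool:
#' reads supporting the designated parent-A allele (the first-listed parent
#' of the cross, which fixes the orientation of all downstream frequencies
#' and contrasts) out of the total depth.
#'
#' @param df data.frame with columns `chrom`, `pos`, `count_a`, `depth`.
#' @param cross,parent_a,parent_b,mating_type,condition,replicate pool
#'   metadata.
#' @return a `pool_counts` object.
#' @export
pool_counts <- function(df, cross = NA_integer_, parent_a = NA_character_,
                        parent_b = NA_character_, mating_type = NA_character_,
                        condition = NA_character_, replicate = 1L) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "pos", "count_a", "depth") %in% names(df)))
  if (any(df$count_a < 0 | df$depth < 0 | df$count_a > df$depth))
    stop("counts must satisfy 0 <= count_a <= depth")
  for (ch in unique(df$chrom)) {
    if (is.unsorted(df$pos[df$chrom == ch], strictly = TRUE))
      stop("positions must be strictly increasing within ", ch)
  }
  structure(df, cross = cross, parent_a = parent_a, parent_b = parent_b,
            mating_type = mating_type, condition = condition,
            replicate = replicate,
            class = c("pool_counts", "data.frame"))
}

# carry pool metadata from one track-like object to another
carry_meta <- function(to, from) {
  for (k in c("cross", "parent_a", "parent_b", "mating_type", "condition",
              "replicate")) {
    attr(to, k) <- attr(from, k)
  }
  to
}

#' Allele-frequency track from pooled counts
#'
#' The parent-A allele frequency is `count_a / depth` wherever the depth
#' reaches `min_depth`; lower-coverage markers are kept but set missing, so
#' downstream contrasts only use adequately covered sites.
#'
#' @param counts a [pool_counts()] table.
#' @param min_depth minimum depth for a frequency to be reported
#'   (default 10).
#' @return a `freq_track` data.frame: `chrom`, `pos`, `freq` (`NA` below
#'   `min_depth`), with the pool metadata carried over.
#' @export
compute_frequencies <- function(counts, min_depth = 10) {
  stopifnot(inherits(counts, "pool_counts"))
  freq <- ifelse(counts$depth >= min_depth, counts$count_a / counts$depth,
                 NA_real_)
  out <- data.frame(chrom = counts$chrom, pos = counts$pos, freq = freq,
                    stringsAsFactors = FALSE)
  out <- carry_meta(out, counts)
  attr(out, "min_depth") <- min_depth
  class(out) <- c("freq_track", "data.frame")
  out
}

# shared worker: per-marker difference x - y on the marker intersection
track_difference <- function(x, y, kind) {
  key_x <- paste(x$chrom, x$pos)
  key_y <- paste(y$chrom, y$pos)
  shared <- intersect(key_x, key_y)
  if (length(shared) == 0L) stop("tracks share no markers")
  ix <- match(shared, key_x)
  iy <- match(shared, key_y)
  d <- x$freq[ix] - y$freq[iy]
  ok <- !is.na(d)
  out <- data.frame(chrom = x$chrom[ix][ok], pos = x$pos[ix][ok],
                    diff = d[ok], stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(x$chrom)), out$pos), ]
  rownames(out) <- NULL
  out <- carry_meta(out, x)
  attr(out, "kind") <- kind
  class(out) <- c("contrast_track", "data.frame")
  out
}

#' Selection-minus-control allele-frequency contrast
#'
#' Subtracts the permissive-condition (control) allele frequencies from the
#' selected-condition frequencies marker by marker, cancelling frequency
#' skews caused by growth alone. Both tracks must come from the same cross
#' and mating type; markers missing in either track are dropped.
#'
#' @param selected,control `freq_track`s (from [compute_frequencies()]).
#' @return a `contrast_track` with `diff = selected - control` and kind
#'   `"selection_minus_control"`.
#' @export
contrast_frequencies <- function(selected, control) {
  stopifnot(inherits(selected, "freq_track"), inherits(control, "freq_track"))
  for (k in c("cross", "mating_type")) {
    a <- attr(selected, k); b <- attr(control, k)
    if (!is.na(a) && !is.na(b) && a != b)
      stop("selected and control tracks differ in ", k)
  }
  track_difference(selected, control, "selection_minus_control")
}

#' Mating-type allele-frequency contrast
#'
#' Subtracts MATalpha allele frequencies from the corresponding MATa
#' frequencies to expose loci whose effect depends on mating type.
#' Chromosome 3 is omitted from the output because it carries the MAT locus
#' itself, which is fully skewed by the sorting.
#'
#' @param track_a,track_alpha `freq_track`s of opposite mating types from
#'   the same cross and condition.
#' @param mat_chrom chromosome id carrying the MAT locus (default `"chr3"`).
#' @return a `contrast_track` with kind `"MATa_minus_MATalpha"`.
#' @export
mat_contrast <- function(track_a, track_alpha, mat_chrom = "chr3") {
  stopifnot(inherits(track_a, "freq_track"), inherits(track_alpha, "freq_track"))
  mta <- attr(track_a, "mating_type"); mtb <- attr(track_alpha, "mating_type")
  if (!is.na(mta) && !is.na(mtb) && mta == mtb)
    stop("both tracks have the same mating type")
  out <- track_difference(track_a, track_alpha, "MATa_minus_MATalpha")
  keep <- out$chrom != mat_chrom
  meta <- attributes(out)
  out <- out[keep, ]
  rownames(out) <- NULL
  for (k in setdiff(names(meta), c("row.names", "names"))) attr(out, k) <- meta[[k]]
  out
}

#' Moving-average smoothing of a frequency track
#'
#' Centered moving average over the markers lying within +/- `window_bp/2`
#' of each marker (per chromosome); missing frequencies are ignored in the
#' average. Window 0 returns the track unchanged. A presentation aid: the
#' LOD model consumes raw counts, never smoothed frequencies.
#'
#' @param track a `freq_track`.
#' @param window_bp window width in base pairs (>= 0).
#' @return a smoothed `freq_track`.
#' @export
smooth_track <- function(track, window_bp) {
  stopifnot(inherits(track, "freq_track"), window_bp >= 0)
  if (window_bp == 0) return(track)
  half <- window_bp / 2
  out <- track
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    pos <- track$pos[idx]
    x <- track$freq[idx]
    csum <- cumsum(ifelse(is.na(x), 0, x))
    cnt <- cumsum(!is.na(x))
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    n <- cnt[hi] - c(0, cnt)[lo]
    s <- csum[hi] - c(0, csum)[lo]
    out$freq[idx] <- ifelse(n > 0, s / n, NA_real_)
  }
  out
}
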