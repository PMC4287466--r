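# single-linkage clustering of intervals (within one chromosome): sweep
# sorted by lower bound, starting a new cluster when the next interval
# starts beyond everything seen so far
cluster_intervals <- function(lower, upper) {
  n <- length(lower)
  ord <- order(lower, upper)
  ids <- integer(n)
  cl <- 0L
  reach <- -Inf
  for (i in ord) {
    if (lower[i] > reach) cl <- cl + 1L
    ids[i] <- cl
    reach <- max(reach, upper[i])
  }
  ids
}

new_qtl_calls <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("qtl_calls", "data.frame")
  df
}

#' Call QTL peaks and 2-LOD support intervals from a LOD track
#'
#' Local maxima above the LOD threshold are reported as QTL. Each peak's
#' support interval extends outward to the first bins where the LOD falls
#' below `peak - drop` (or to the chromosome end). Peaks whose drop
#' intervals overlap are merged into a single call keeping the higher peak
#' (leftmost on ties) and the union of the intervals, so the shoulders of
#' one peak are not double-counted.
#'
#' @param track a `lod_track` from [contrast_lod()].
#' @param threshold minimum peak LOD (default 5).
#' @param drop LOD drop defining the support interval (default 2).
#' @param contrast optional `contrast_track` used to record the sign of the
#'   mean allele-frequency contrast within each interval.
#' @return a `qtl_calls` data.frame: `chrom`, `peak_pos`, `peak_lod`,
#'   `lower`, `upper` (bp, 1-based inclusive), `direction`, `cross`,
#'   `condition`, `mating_type`, `replicated` (`NA` until replication is
#'   assessed).
#' @export
call_qtl <- function(track, threshold = 5, drop = 2, contrast = NULL) {
  stopifnot(inherits(track, "lod_track"))
  if (any(!is.finite(track$lod))) stop("LOD track contains non-finite values")
  rows <- list()
  for (ch in unique(track$chrom)) {
    idx <- which(track$chrom == ch)
    v <- track$lod[idx]
    n <- length(v)
    is_peak <- v > threshold &
      v > c(-Inf, v[-n]) &          # strictly above the previous bin
      v >= c(v[-1L], -Inf)          # at least the next bin: leftmost on ties
    peaks <- which(is_peak)
    if (!length(peaks)) next
    calls <- lapply(peaks, function(i) {
      lim <- v[i] - drop
      jl <- i; while (jl > 1L && v[jl - 1L] >= lim) jl <- jl - 1L
      ju <- i; while (ju < n && v[ju + 1L] >= lim) ju <- ju + 1L
      c(peak = i, lod = v[i],
        lower = track$start[idx[jl]], upper = track$end[idx[ju]])
    })
    calls <- as.data.frame(do.call(rbind, calls))
    # merge overlapping drop intervals, keeping the higher (leftmost) peak
    repeat {
      cl <- cluster_intervals(calls$lower, calls$upper)
      if (max(cl) == nrow(calls)) break
      calls <- do.call(rbind, lapply(split(calls, cl), function(g) {
        best <- order(-g$lod, g$peak)[1L]
        data.frame(peak = g$peak[best], lod = g$lod[best],
                   lower = min(g$lower), upper = max(g$upper))
      }))
    }
    rows[[ch]] <- data.frame(chrom = ch,
                             peak_pos = track$pos[idx[calls$peak]],
                             peak_lod = calls$lod,
                             lower = calls$lower, upper = calls$upper,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), peak_pos = numeric(),
               peak_lod = numeric(), lower = numeric(), upper = numeric(),
               stringsAsFactors = FALSE)
  out$direction <- rep(NA_real_, nrow(out))
  if (!is.null(contrast) && nrow(out)) {
    for (i in seq_len(nrow(out))) {
      m <- contrast$chrom == out$chrom[i] & contrast$pos >= out$lower[i] &
        contrast$pos <= out$upper[i]
      if (any(m)) out$direction[i] <- sign(mean(contrast$diff[m], na.rm = TRUE))
    }
  }
  out$cross <- rep(attr(track, "cross") %||% NA_integer_, nrow(out))
  out$condition <- rep(attr(track, "condition") %||% NA_character_, nrow(out))
  out$mating_type <- rep(attr(track, "mating_type") %||% NA_character_,
                         nrow(out))
  out$replicated <- rep(NA, nrow(out))
  new_qtl_calls(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replication of QTL across the two mating-type selections
#'
#' QTL from the MATa and MATalpha selections of one cross and condition
#' are matched by interval overlap. Overlapping calls from the two
#' selections are merged into one replicated call whose interval bounds,
#' peak position and LOD are the means across the members; calls without a
#' partner in the other selection are returned flagged unreplicated. The
#' operation is symmetric in its two arguments and idempotent on identical
#' call sets.
#'
#' @param calls_a,calls_alpha `qtl_calls` from the two mating-type
#'   selections.
#' @return a `qtl_calls` data.frame with the `replicated` flag filled in.
#' @export
replicate_support <- function(calls_a, calls_alpha) {
  da <- as.data.frame(calls_a); da$.src <- rep("a", nrow(da))
  db <- as.data.frame(calls_alpha); db$.src <- rep("alpha", nrow(db))
  both <- rbind(da, db)
  if (nrow(both) == 0L) return(new_qtl_calls(both[setdiff(names(both), ".src")]))
  pieces <- list()
  for (ch in unique(both$chrom)) {
    g <- both[both$chrom == ch, ]
    cl <- cluster_intervals(g$lower, g$upper)
    for (id in unique(cl)) {
      mem <- g[cl == id, ]
      if (length(unique(mem$.src)) == 2L) {
        merged <- mem[1L, setdiff(names(mem), ".src")]
        merged$lower <- mean(mem$lower)
        merged$upper <- mean(mem$upper)
        merged$peak_pos <- mean(mem$peak_pos)
        merged$peak_lod <- mean(mem$peak_lod)
        merged$direction <- if (length(unique(sign(mem$direction))) == 1L)
          mem$direction[1L] else NA_real_
        merged$mating_type <- "both"
        merged$replicated <- TRUE
        pieces[[length(pieces) + 1L]] <- merged
      } else {
        mem$replicated <- FALSE
        pieces[[length(pieces) + 1L]] <- mem[setdiff(names(mem), ".src")]
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$chrom, unique(both$chrom)), out$lower), ]
  new_qtl_calls(out)
}

#' Direction agreement of unreplicated QTL between paired experiments
#'
#' For QTL detected in only one of two matched selections, checks whether
#' the sign of the mean allele-frequency contrast over the QTL interval
#' agrees between the two experiments, and assesses the observed agreement
#' fraction against a null built by permuting the marker-level contrast
#' values genome-wide in both tracks.
#'
#' @param calls unreplicated `qtl_calls`.
#' @param contrast_a,contrast_alpha the two experiments' `contrast_track`s.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional seed for the permutations.
#' @return list with `per_call` (data.frame: signs and agreement per call;
#'   `NA` where an interval contains no markers), `agreement` (observed
#'   fraction), and `p_value` (add-one-corrected empirical p, at least
#'   `1/(n_perm + 1)`).
#' @export
direction_agreement <- function(calls, contrast_a, contrast_alpha,
                                n_perm = 1000, seed = NULL) {
  stopifnot(inherits(contrast_a, "contrast_track"),
            inherits(contrast_alpha, "contrast_track"))
  region_idx <- function(track, i) {
    which(track$chrom == calls$chrom[i] & track$pos >= calls$lower[i] &
            track$pos <= calls$upper[i])
  }
  idx_a <- lapply(seq_len(nrow(calls)), region_idx, track = contrast_a)
  idx_b <- lapply(seq_len(nrow(calls)), region_idx, track = contrast_alpha)
  agree_frac <- function(xa, xb) {
    sa <- vapply(idx_a, function(j) if (length(j)) sign(mean(xa[j])) else NA_real_,
                 0)
    sb <- vapply(idx_b, function(j) if (length(j)) sign(mean(xb[j])) else NA_real_,
                 0)
    list(sa = sa, sb = sb, frac = mean((sa == sb)[!is.na(sa) & !is.na(sb)]))
  }
  obs <- agree_frac(contrast_a$diff, contrast_alpha$diff)
  p <- NA_real_
  if (n_perm > 0 && !is.na(obs$frac)) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(k) {
        fa <- sample(contrast_a$diff)
        fb <- sample(contrast_alpha$diff)
        agree_frac(fa, fb)$frac >= obs$frac
      }, logical(1)), na.rm = TRUE)
    })
    p <- (1 + exceed) / (n_perm + 1)
  }
  list(per_call = data.frame(chrom = calls$chrom, lower = calls$lower,
                             upper = calls$upper, sign_a = obs$sa,
                             sign_alpha = obs$sb, agree = obs$sa == obs$sb),
       agreement = obs$frac, p_value = p)
}

#' Combine QTL detected at different dosages of one stressor
#'
#' Calls sharing a cross and stressor but detected at different
#' concentrations are merged when their intervals overlap (transitively):
#' the merged interval bounds and peak position are means across dosages,
#' and the merged LOD is the minimum of the dosage peak LODs -- a
#' conservative summary of the region's support. Calls seen at a single
#' dosage pass through unchanged.
#'
#' @param calls `qtl_calls` from the dosages of one stressor (a `condition`
#'   column distinguishes dosages).
#' @return combined `qtl_calls`; merged rows have `condition` set to the
#'   dosage labels joined with `"+"`.
#' @export
combine_conditions <- function(calls) {
  df <- as.data.frame(calls)
  if (nrow(df) == 0L) return(new_qtl_calls(df))
  pieces <- list()
  for (ch in unique(df$chrom)) {
    g <- df[df$chrom == ch, ]
    cl <- cluster_intervals(g$lower, g$upper)
    for (id in unique(cl)) {
      mem <- g[cl == id, ]
      if (nrow(mem) > 1L) {
        merged <- mem[1L, ]
        merged$lower <- mean(mem$lower)
        merged$upper <- mean(mem$upper)
        merged$peak_pos <- mean(mem$peak_pos)
        merged$peak_lod <- min(mem$peak_lod)
        merged$condition <- paste(sort(unique(mem$condition)), collapse = "+")
        pieces[[length(pieces) + 1L]] <- merged
      } else {
        pieces[[length(pieces) + 1L]] <- mem
      }
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(match(out$chrom, unique(df$chrom)), out$lower), ]
  new_qtl_calls(out)
}

#' Group QTL across the round-robin crosses
#'
#' Single-linkage merging of overlapping QTL intervals across crosses into
#' QTL groups. Every cross -- whether or not it contributed a call --
#' contributes its replicate-averaged maximum LOD within the merged region,
#' giving a quantitative per-cross detection vector for each group; the
#' crosses-per-group histogram summarizes how widely each QTL replicates
#' across the design.
#'
#' @param calls `qtl_calls` from all crosses of one condition family (must
#'   carry a `cross` column).
#' @param lod_tracks named list (one element per cross id) of `lod_track`s
#'   or lists of replicate `lod_track`s; replicate maxima are averaged.
#' @return object of class `qtl_groups`: list with `groups` (data.frame:
#'   `group`, `chrom`, `lower`, `upper`, `n_crosses`, `crosses`,
#'   `conditions`), `lod` (groups x crosses matrix of replicate-averaged
#'   in-region maximum LOD; 0 where a cross's tracks have no bins there)
#'   and `histogram` (table of crosses per group).
#' @export
group_across_crosses <- function(calls, lod_tracks) {
  df <- as.data.frame(calls)
  stopifnot(nrow(df) > 0L, !is.null(names(lod_tracks)))
  tracks <- lapply(lod_tracks, function(x) {
    if (inherits(x, "lod_track")) list(x) else x
  })
  groups <- list()
  for (ch in unique(df$chrom)) {
    g <- df[df$chrom == ch, ]
    cl <- cluster_intervals(g$lower, g$upper)
    for (id in unique(cl)) {
      mem <- g[cl == id, ]
      groups[[length(groups) + 1L]] <- list(
        chrom = ch, lower = min(mem$lower), upper = max(mem$upper),
        crosses = sort(unique(mem$cross)),
        conditions = paste(sort(unique(mem$condition)), collapse = ","),
        members = mem)
    }
  }
  lod <- matrix(0, nrow = length(groups), ncol = length(tracks),
                dimnames = list(NULL, names(tracks)))
  for (gi in seq_along(groups)) {
    gr <- groups[[gi]]
    for (cx in names(tracks)) {
      vals <- vapply(tracks[[cx]], function(tr) {
        m <- tr$chrom == gr$chrom & tr$end >= gr$lower & tr$start <= gr$upper
        if (any(m)) max(tr$lod[m]) else 0
      }, 0)
      lod[gi, cx] <- mean(vals)
    }
  }
  summary_df <- data.frame(
    group = seq_along(groups),
    chrom = vapply(groups, `[[`, "", "chrom"),
    lower = vapply(groups, `[[`, 0, "lower"),
    upper = vapply(groups, `[[`, 0, "upper"),
    n_crosses = vapply(groups, function(g) length(g$crosses), 0L),
    crosses = vapply(groups, function(g) paste(g$crosses, collapse = ","), ""),
    conditions = vapply(groups, `[[`, "", "conditions"),
    stringsAsFactors = FALSE)
  structure(list(groups = summary_df, lod = lod,
                 members = lapply(groups, `[[`, "members"),
                 histogram = table(summary_df$n_crosses)),
            class = "qtl_groups")
}

#' @export
print.qtl_groups <- function(x, ...) {
  cat("QTL groups:", nrow(x$groups), "regions across",
      ncol(x$lod), "crosses\n")
  print(x$groups, row.names = FALSE)
  cat("crosses-per-group histogram:\n")
  print(x$histogram)
  invisible(x)
}
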