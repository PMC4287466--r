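#' Configuration of the binned latent-frequency LOD model
#'
#' The pool allele frequency along a chromosome is modeled as a hidden
#' Markov chain on a discrete frequency grid. Counts are summed into
#' contiguous bins of `bin_bp` base pairs; between adjacent bins the latent
#' frequency `p` moves to a value with mean `(1 - rho) p + rho (1 - p)` and
#' variance `rho (1 - rho) / N`, where `rho` is the Haldane recombination
#' fraction across one bin and `N` the number of segregants in the pool --
#' the one-generation random-walk of a finite pool recombining at the
#' genetic-map scale. Emissions are exact binomial: the bin's parent-A read
#' count given its depth and the latent frequency.
#'
#' The default grid places one point per possible pool allele count
#' (`pool_size + 1` points), so the grid resolution matches the per-bin
#' random-walk standard deviation `sqrt(rho (1 - rho) / N)`; a much coarser
#' grid cannot represent the sub-grid drift of the walk and freezes the
#' chain.
#'
#' @param pool_size number of segregants per pool (`N`, default 1000).
#' @param bin_bp bin width in base pairs (default 100).
#' @param grid_size number of equally spaced grid points on `[0, 1]`
#'   (default `pool_size + 1`; minimum 3).
#' @param bp_per_cM genetic-map scale (default 2200).
#' @param clip_negative clip negative LOD scores to zero (default `TRUE`).
#' @return object of class `lod_config`.
#' @export
lod_config <- function(pool_size = 1000, bin_bp = 100,
                       grid_size = pool_size + 1, bp_per_cM = 2200,
                       clip_negative = TRUE) {
  if (pool_size <= 0) stop("pool_size must be positive")
  if (bin_bp <= 0) stop("bin_bp must be positive")
  if (grid_size < 3) stop("grid_size must be at least 3")
  structure(list(pool_size = as.integer(pool_size),
                 bin_bp = as.integer(bin_bp),
                 grid_size = as.integer(grid_size),
                 model = recomb_model(bp_per_cM),
                 clip_negative = isTRUE(clip_negative)),
            class = "lod_config")
}

#' Sum pooled counts into contiguous genomic bins
#'
#' Bins are half-open windows `[start, start + bin_bp)` tiling each
#' chromosome from position 1; a marker at exactly `start + bin_bp` falls
#' in the next bin. Bins without markers are emitted with zero counts so
#' that the Markov chain steps across them.
#'
#' @param counts a [pool_counts()] table (positions sorted).
#' @param config a [lod_config()].
#' @param chrom_lengths optional named lengths used to extend the binning to
#'   chromosome ends; by default bins run to the last marker.
#' @return a `binned_counts` data.frame: `chrom`, `start`, `count_a`,
#'   `depth`, with attribute `bin_bp` and the pool metadata.
#' @export
bin_counts <- function(counts, config, chrom_lengths = NULL) {
  stopifnot(inherits(counts, "pool_counts"), inherits(config, "lod_config"))
  r <- config$bin_bp
  pieces <- lapply(unique(counts$chrom), function(ch) {
    sub <- counts[counts$chrom == ch, ]
    last <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(sub$pos)
    n_bins <- max(1L, ceiling(last / r))
    bin <- (sub$pos - 1L) %/% r + 1L  # 1-based bin index
    k <- numeric(n_bins)
    n <- numeric(n_bins)
    agg <- rowsum(cbind(sub$count_a, sub$depth), bin)
    filled <- as.integer(rownames(agg))
    k[filled] <- agg[, 1L]
    n[filled] <- agg[, 2L]
    data.frame(chrom = ch, start = (seq_len(n_bins) - 1L) * r + 1L,
               count_a = k, depth = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- carry_meta(out, counts)
  attr(out, "bin_bp") <- r
  class(out) <- c("binned_counts", "data.frame")
  out
}

# banded, row-renormalized discretization of the transition kernel:
# normal density evaluated at the grid points (truncated to [0,1])
build_transition_band <- function(config) {
  T_ <- config$grid_size
  grid <- seq(0, 1, length.out = T_)
  delta <- 1 / (T_ - 1)
  rho <- recombination_fraction(config$bin_bp, config$model)
  sigma <- sqrt(rho * (1 - rho) / config$pool_size)
  h <- as.integer(min(T_ - 1, max(1, ceiling((8.6 * sigma + rho) / delta) + 1)))
  offs <- seq(-h, h)
  band <- matrix(0, nrow = T_, ncol = 2L * h + 1L)
  mu <- (1 - rho) * grid + rho * (1 - grid)
  for (p in seq_len(T_)) {
    q <- p + offs
    ok <- q >= 1L & q <= T_
    w <- dnorm(grid[q[ok]], mean = mu[p], sd = sigma)
    if (!any(w > 0)) {  # degenerate kernel: all mass on the nearest point
      w <- as.numeric(seq_along(w) == which.min(abs(grid[q[ok]] - mu[p])))
    }
    band[p, ok] <- w / sum(w)
  }
  list(band = band, h = h, grid = grid, rho = rho, sigma = sigma)
}

# dense transition matrix (same kernel as the banded form); used by the
# exhaustive path-enumeration oracle and exposed for testing
transition_matrix <- function(config) {
  tb <- build_transition_band(config)
  T_ <- config$grid_size
  P <- matrix(0, T_, T_)
  for (p in seq_len(T_)) {
    q <- p + seq(-tb$h, tb$h)
    ok <- q >= 1L & q <= T_
    P[p, q[ok]] <- tb$band[p, ok]
  }
  P
}

#' Forward-backward pass of the latent-frequency model on one chromosome
#'
#' Runs the scaled forward-backward algorithm over the binned counts of a
#' single chromosome: uniform prior over the frequency grid, banded
#' truncated-normal transitions between adjacent bins, exact binomial
#' emissions (bins with zero depth contribute no emission). Returns the
#' per-bin posterior distribution of the pool allele frequency and the
#' log-likelihood of the whole track.
#'
#' @param binned a `binned_counts` table covering exactly one chromosome,
#'   with contiguous sorted bins.
#' @param config a [lod_config()].
#' @return list with `posterior` (grid x bins matrix, columns sum to 1),
#'   `loglik` (natural log), and `grid`.
#' @export
forward_backward <- function(binned, config) {
  stopifnot(inherits(binned, "binned_counts"), inherits(config, "lod_config"))
  if (length(unique(binned$chrom)) != 1L)
    stop("forward_backward runs on one chromosome at a time")
  if (is.unsorted(binned$start, strictly = TRUE))
    stop("bins must be sorted")
  if (any(diff(binned$start) != attr(binned, "bin_bp")))
    stop("bins must be contiguous")
  if (any(binned$count_a > binned$depth))
    stop("count_a exceeds depth")
  tb <- build_transition_band(config)
  T_ <- config$grid_size
  ne <- which(binned$depth > 0)
  emit_col <- integer(nrow(binned))
  emit_col[ne] <- seq_along(ne)
  emit <- if (length(ne)) {
    vapply(ne, function(i) dbinom(binned$count_a[i], binned$depth[i], tb$grid),
           numeric(T_))
  } else {
    matrix(0, T_, 0)
  }
  prior <- rep(1 / T_, T_)
  res <- fb_banded(emit, emit_col, tb$band, tb$h, prior)
  list(posterior = res$posterior, loglik = res$loglik, grid = tb$grid)
}

#' Contrast LOD scores between a selected and a control pool
#'
#' Runs [forward_backward()] independently on the two pools (chromosome by
#' chromosome) and scores, per bin, how strongly the data oppose equality
#' of the two latent allele frequencies: with per-bin posteriors
#' `post_sel`, `post_con` and a uniform prior `pi`, the posterior match is
#' `m_i = sum_p post_sel(i,p) post_con(i,p)` and the prior match is
#' `sum_p pi(p)^2 = 1/T`, giving the Savage-Dickey style score
#' `LOD(i) = log10((1/T) / m_i)`. Matched posteriors give negative scores
#' (clipped to 0 by default); divergent posteriors give large positive LOD.
#'
#' @param selected,control `binned_counts` with identical bin structure.
#' @param config a [lod_config()].
#' @return a `lod_track` data.frame: `chrom`, `start`, `end` (1-based,
#'   inclusive), `pos` (bin midpoint), `lod`; metadata carried from the
#'   selected pool.
#' @export
contrast_lod <- function(selected, control, config) {
  stopifnot(inherits(selected, "binned_counts"),
            inherits(control, "binned_counts"))
  if (nrow(selected) != nrow(control) ||
      !all(selected$chrom == control$chrom) ||
      !all(selected$start == control$start))
    stop("selected and control pools have different bin structures")
  T_ <- config$grid_size
  r <- attr(selected, "bin_bp")
  lod <- numeric(nrow(selected))
  for (ch in unique(selected$chrom)) {
    idx <- which(selected$chrom == ch)
    fs <- forward_backward(subset_binned(selected, idx), config)
    fc <- forward_backward(subset_binned(control, idx), config)
    m <- colSums(fs$posterior * fc$posterior)
    m <- pmax(m, .Machine$double.xmin)  # keep the score finite
    lod[idx] <- log10(1 / T_) - log10(m)
  }
  if (config$clip_negative) lod <- pmax(lod, 0)
  out <- data.frame(chrom = selected$chrom, start = selected$start,
                    end = selected$start + r - 1L,
                    pos = selected$start + (r - 1) / 2,
                    lod = lod, stringsAsFactors = FALSE)
  out <- carry_meta(out, selected)
  attr(out, "bin_bp") <- r
  class(out) <- c("lod_track", "data.frame")
  out
}

# subset a binned_counts table, preserving class and metadata
subset_binned <- function(binned, idx) {
  meta <- attributes(binned)
  out <- binned[idx, ]
  rownames(out) <- NULL
  for (k in setdiff(names(meta), c("row.names", "names"))) attr(out, k) <- meta[[k]]
  out
}
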