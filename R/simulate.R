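#' Simulate parent-strain marker genotypes
#'
#' Draws biallelic marker positions along each chromosome and assigns 0/1
#' alleles across the parent panel. A configurable fraction of variants is
#' private (exactly one strain carries the alternative allele); the
#' remainder receive a random polymorphic split. Monomorphic candidates are
#' never emitted. When the configuration has at least three chromosomes,
#' one marker at the midpoint of chromosome 3 is flagged as the MAT locus;
#' its allele is 1 for MATa strains and 0 for MATalpha strains (mating
#' types alternate along the strain list, matching the round-robin design).
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; the same seed reproduces the table.
#' @return a `marker_table`: data.frame with columns `chrom`, `pos`,
#'   `is_mat` and one 0/1 column per strain; attributes `strains` and
#'   `mating_type`.
#' @export
simulate_parent_genomes <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    N <- config$n_strains
    strains <- sprintf("strain%02d", seq_len(N))
    mt <- setNames(rep(c("a", "alpha"), length.out = N), strains)
    chroms <- names(config$chrom_lengths)
    out <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      m <- config$markers_per_chrom[ci]
      if (m == 0L) next
      pos <- sort(sample.int(config$chrom_lengths[ci], m))
      g <- matrix(0L, nrow = m, ncol = N, dimnames = list(NULL, strains))
      private <- runif(m) < config$private_frac
      n_priv <- sum(private)
      if (n_priv > 0L)
        g[cbind(which(private), sample.int(N, n_priv, replace = TRUE))] <- 1L
      n_shared <- m - n_priv
      if (n_shared > 0L) {
        gs <- matrix(rbinom(n_shared * N, 1L, 0.5), nrow = n_shared)
        mono <- rowSums(gs) %in% c(0L, N)
        while (any(mono)) {  # redraw monomorphic candidates
          gs[mono, ] <- rbinom(sum(mono) * N, 1L, 0.5)
          mono <- rowSums(gs) %in% c(0L, N)
        }
        g[!private, ] <- gs
      }
      out[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                              is_mat = FALSE, g, check.names = FALSE,
                              stringsAsFactors = FALSE)
    }
    markers <- do.call(rbind, out)
    if (is.null(markers) || nrow(markers) == 0L)
      stop("configuration produced zero markers")
    if (length(chroms) >= 3L) {
      # MAT locus at the chromosome 3 midpoint, alleles tracking mating type
      mat_pos <- as.integer(config$chrom_lengths[3L] %/% 2L)
      on3 <- markers$chrom == chroms[3L]
      while (mat_pos %in% markers$pos[on3]) mat_pos <- mat_pos + 1L
      mat_row <- data.frame(chrom = chroms[3L], pos = mat_pos, is_mat = TRUE,
                            matrix(as.integer(mt == "a"), nrow = 1,
                                   dimnames = list(NULL, strains)),
                            check.names = FALSE, stringsAsFactors = FALSE)
      markers <- rbind(markers, mat_row)
      markers <- markers[order(match(markers$chrom, chroms), markers$pos), ]
    }
    rownames(markers) <- NULL
    attr(markers, "strains") <- strains
    attr(markers, "mating_type") <- mt
    class(markers) <- c("marker_table", "data.frame")
    validate_marker_table(markers)
  })
}

#' Simulate recombinant haploid segregants of one cross
#'
#' Each segregant's parent-of-origin along a chromosome is a two-state
#' Markov chain: the origin at the first marker is uniform, and the origin
#' switches between adjacent markers with probability equal to the Haldane
#' recombination fraction of their physical gap. Chromosomes assort
#' independently (no crossover interference, matching the Haldane map).
#'
#' @param cross a row of a design (see [build_round_robin()]) given as a
#'   list with `parent_a`, `parent_b` (and optionally `cross`).
#' @param markers a `marker_table` containing both parents.
#' @param n number of segregants to draw.
#' @param model a [recomb_model()].
#' @param seed optional seed.
#' @return integer matrix `n x n_markers` of parent-of-origin codes
#'   (1 = parent A, 2 = parent B), with attributes `cross`, `parent_a`,
#'   `parent_b`.
#' @export
simulate_segregants <- function(cross, markers, n, model = recomb_model(),
                                seed = NULL) {
  strains <- attr(markers, "strains")
  if (!all(c(cross$parent_a, cross$parent_b) %in% strains))
    stop("cross parents not present in the marker table")
  with_seed(seed, {
    M <- nrow(markers)
    origins <- matrix(0L, nrow = n, ncol = M)
    for (ch in unique(markers$chrom)) {
      idx <- which(markers$chrom == ch)
      m <- length(idx)
      states <- matrix(0L, nrow = n, ncol = m)
      states[, 1L] <- rbinom(n, 1L, 0.5)
      if (m > 1L) {
        rho <- recombination_fraction(diff(markers$pos[idx]), model)
        sw <- vapply(rho, function(r) rbinom(n, 1L, r), integer(n))
        if (n == 1L) sw <- matrix(sw, nrow = 1L)
        # cumulative XOR of switch indicators gives the origin chain
        states <- (states[, 1L] + t(apply(cbind(0L, sw), 1L, cumsum))) %% 2L
      }
      origins[, idx] <- states
    }
    origins <- origins + 1L
    attr(origins, "cross") <- cross$cross
    attr(origins, "parent_a") <- cross$parent_a
    attr(origins, "parent_b") <- cross$parent_b
    origins
  })
}

#' Additive QTL effect for the viability-selection simulator
#'
#' @param chrom,pos marker coordinates of the causal locus (must match a
#'   marker in the table).
#' @param beta length-2 numeric: additive log-fitness of carrying allele 0
#'   and allele 1 at the locus.
#' @param condition optional condition label.
#' @return object of class `qtl_effect`.
#' @export
qtl_effect <- function(chrom, pos, beta, condition = NA_character_) {
  stopifnot(length(beta) == 2L, is.numeric(beta))
  structure(list(chrom = chrom, pos = as.integer(pos),
                 beta = as.numeric(beta), condition = condition),
            class = "qtl_effect")
}

# allele (0/1) carried by each segregant at marker row j
segregant_alleles_at <- function(origins, markers, j) {
  a <- markers[[attr(origins, "parent_a")]][j]
  b <- markers[[attr(origins, "parent_b")]][j]
  ifelse(origins[, j] == 1L, a, b)
}

#' Viability selection and mating-type sorting of a segregant pool
#'
#' FACS mating-type sorting is a hard filter: only segregants carrying the
#' requested MAT allele are retained. Growth selection is soft: each
#' segregant survives with weight `w = exp(sum_l beta_l(allele_l))` over
#' the additive QTL effects, and the pool is resampled (with replacement)
#' proportionally to `w`.
#'
#' @param segregants origin matrix from [simulate_segregants()].
#' @param markers the `marker_table` used to simulate them.
#' @param effects list of [qtl_effect()]s (empty list = no selection).
#' @param mat_filter `NULL`, `"a"` or `"alpha"`.
#' @param pool_size size of the resampled pool; defaults to the number of
#'   input segregants surviving the MAT filter.
#' @param seed optional seed.
#' @return origin matrix of the selected pool (attributes preserved).
#' @export
apply_selection <- function(segregants, markers, effects = list(),
                            mat_filter = NULL, pool_size = NULL, seed = NULL) {
  with_seed(seed, {
    keep <- segregants
    if (!is.null(mat_filter)) {
      mat_filter <- match.arg(mat_filter, c("a", "alpha"))
      j <- which(markers$is_mat)
      if (length(j) != 1L)
        stop("marker table has no MAT locus; cannot mating-type sort")
      allele <- segregant_alleles_at(keep, markers, j)
      sel <- allele == (if (mat_filter == "a") 1L else 0L)
      if (!any(sel)) stop("no segregants of the requested mating type")
      at <- attributes(keep)
      keep <- keep[sel, , drop = FALSE]
      attr(keep, "cross") <- at$cross
      attr(keep, "parent_a") <- at$parent_a
      attr(keep, "parent_b") <- at$parent_b
    }
    w <- rep(1, nrow(keep))
    for (ef in effects) {
      stopifnot(inherits(ef, "qtl_effect"))
      j <- which(markers$chrom == ef$chrom & markers$pos == ef$pos)
      if (length(j) != 1L)
        stop("effect locus ", ef$chrom, ":", ef$pos, " not in marker table")
      allele <- segregant_alleles_at(keep, markers, j)
      w <- w * exp(ef$beta[allele + 1L])
    }
    if (!any(w > 0)) stop("all selection weights are zero")
    if (is.null(pool_size)) pool_size <- nrow(keep)
    idx <- sample.int(nrow(keep), pool_size, replace = TRUE, prob = w)
    at <- attributes(keep)
    out <- keep[idx, , drop = FALSE]
    attr(out, "cross") <- at$cross
    attr(out, "parent_a") <- at$parent_a
    attr(out, "parent_b") <- at$parent_b
    attr(out, "mat_filter") <- mat_filter
    out
  })
}

#' True parent-A allele frequencies of a pool at its segregating markers
#'
#' Markers at which the two parents of the cross carry the same allele do
#' not segregate and are excluded (they carry no mapping information).
#'
#' @inheritParams apply_selection
#' @return data.frame `chrom`, `pos`, `freq` (frequency of the parent-A
#'   allele among pool members).
#' @export
pool_true_frequencies <- function(segregants, markers) {
  seg <- which(markers[[attr(segregants, "parent_a")]] !=
                 markers[[attr(segregants, "parent_b")]])
  data.frame(chrom = markers$chrom[seg], pos = markers$pos[seg],
             freq = colMeans(segregants[, seg, drop = FALSE] == 1L),
             stringsAsFactors = FALSE)
}

#' Pooled sequencing of a segregant pool
#'
#' Per segregating marker, sequencing depth is Poisson with mean
#' `depth * copy factor` (copy-number regions from the configuration
#' multiply the rate) and the number of reads supporting the parent-A
#' allele is binomial in the pool's true allele frequency. No read-level
#' error model beyond binomial sampling.
#'
#' @inheritParams apply_selection
#' @param config a [sim_config()] providing `depth` and `copy_number`.
#' @param condition,mating_type,replicate metadata stored on the result.
#' @param seed optional seed.
#' @return a `pool_counts` data.frame: `chrom`, `pos`, `count_a`, `depth`;
#'   attributes `cross`, `parent_a`, `parent_b`, `mating_type`, `condition`,
#'   `replicate`.
#' @export
sequence_pool <- function(segregants, markers, config,
                          condition = "YPD", mating_type = NA_character_,
                          replicate = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(segregants) == 0L) stop("empty pool")
  with_seed(seed, {
    tr <- pool_true_frequencies(segregants, markers)
    lambda <- rep(config$depth, nrow(tr))
    cn <- config$copy_number
    if (!is.null(cn)) {
      for (i in seq_len(nrow(cn))) {
        inside <- tr$chrom == cn$chrom[i] & tr$pos >= cn$start[i] &
          tr$pos <= cn$end[i]
        lambda[inside] <- lambda[inside] * cn$copies[i]
      }
    }
    depth <- rpois(nrow(tr), lambda)
    count_a <- rbinom(nrow(tr), depth, tr$freq)
    pool_counts(data.frame(chrom = tr$chrom, pos = tr$pos,
                           count_a = count_a, depth = depth,
                           stringsAsFactors = FALSE),
                cross = attr(segregants, "cross"),
                parent_a = attr(segregants, "parent_a"),
                parent_b = attr(segregants, "parent_b"),
                mating_type = mating_type, condition = condition,
                replicate = replicate)
  })
}
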