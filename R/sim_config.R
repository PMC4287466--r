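#' Simulation configuration for a round-robin X-QTL experiment
#'
#' Collects the knobs of the synthetic-data generator: the parent panel
#' size, the marker map, the segregant pool size, sequencing depth, and
#' optional copy-number regions that inflate local depth.
#'
#' Defaults describe a desk-scale version of a pooled-sequencing X-QTL
#' experiment: 12 parents, three chromosomes with yeast chromosome I-III
#' lengths, one biallelic marker per ~500 bp, pools of 1000 segregants and
#' 50x mean depth per marker.
#'
#' @param n_strains number of parent strains (>= 2).
#' @param chrom_lengths numeric vector of chromosome lengths in bp; names
#'   are taken as chromosome ids, otherwise `chr1`, `chr2`, ... are used.
#'   When a third chromosome is present it carries the mating-type (MAT)
#'   locus at its midpoint.
#' @param markers_per_chrom integer vector (recycled) of marker counts per
#'   chromosome.
#' @param pool_size number of segregants per sequenced pool (the `N` the
#'   LOD model assumes; default 1000).
#' @param depth mean sequencing depth per marker (Poisson rate).
#' @param private_frac fraction of variants private to a single strain; the
#'   rest receive a random polymorphic allele split across the panel.
#' @param copy_number optional data.frame with columns `chrom`, `start`,
#'   `end`, `copies`: markers inside such a region have their Poisson depth
#'   multiplied by `copies` (depth multiplier only; no extra alleles).
#' @param bp_per_cM genetic map scale passed to [recomb_model()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 12,
                       chrom_lengths = c(chr1 = 230218, chr2 = 813184, chr3 = 316620),
                       markers_per_chrom = pmax(10L, ceiling(chrom_lengths / 500)),
                       pool_size = 1000,
                       depth = 50,
                       private_frac = 0.5,
                       copy_number = NULL,
                       bp_per_cM = 2200) {
  if (n_strains < 2L) stop("need at least 2 strains")
  if (length(chrom_lengths) < 1L || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  markers_per_chrom <- rep_len(as.integer(markers_per_chrom),
                               length(chrom_lengths))
  if (sum(markers_per_chrom) == 0L) stop("configuration has zero markers")
  if (any(markers_per_chrom > chrom_lengths))
    stop("more markers than base pairs on a chromosome")
  if (pool_size <= 0) stop("pool_size must be positive")
  if (depth <= 0) stop("depth must be positive")
  if (private_frac < 0 || private_frac > 1)
    stop("private_frac must be in [0, 1]")
  if (!is.null(copy_number)) {
    stopifnot(is.data.frame(copy_number),
              all(c("chrom", "start", "end", "copies") %in% names(copy_number)),
              all(copy_number$copies > 0))
  }
  structure(list(n_strains = as.integer(n_strains),
                 chrom_lengths = chrom_lengths,
                 markers_per_chrom = markers_per_chrom,
                 pool_size = as.integer(pool_size),
                 depth = depth,
                 private_frac = private_frac,
                 copy_number = copy_number,
                 model = recomb_model(bp_per_cM)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("X-QTL simulation config:", x$n_strains, "strains;",
      length(x$chrom_lengths), "chromosomes (",
      paste0(names(x$chrom_lengths), "=", x$chrom_lengths, collapse = ", "),
      ");", sum(x$markers_per_chrom), "markers;",
      "pool", x$pool_size, "; depth", x$depth, "x\n")
  invisible(x)
}

# internal validator shared by the simulator and the marker readers
validate_marker_table <- function(markers) {
  strains <- attr(markers, "strains")
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "is_mat") %in% names(markers)),
            !is.null(strains), all(strains %in% names(markers)))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing within ", ch)
  }
  g <- as.matrix(markers[strains])
  if (!all(g %in% c(0L, 1L))) stop("alleles must be coded 0/1")
  mono <- rowSums(g) %in% c(0L, ncol(g))
  if (any(mono)) stop("marker table contains monomorphic records")
  n_mat <- sum(markers$is_mat)
  if (n_mat > 1L) stop("more than one MAT locus flagged")
  if (n_mat == 1L && markers$chrom[markers$is_mat] != "chr3")
    stop("the MAT locus must lie on chromosome 3")
  invisible(markers)
}
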