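#' Stress-to-permissive growth normalization
#'
#' Growth under a stress condition is expressed relative to growth under
#' the permissive condition of the same strain: the ratio of the mean
#' stress measurement to the mean permissive measurement (technical
#' replicate pins are averaged before the ratio is formed). Invariant to a
#' common multiplicative calibration of both measurements.
#'
#' @param stress,permissive numeric vectors of replicate growth
#'   measurements (non-negative, arbitrary units) for one strain.
#' @return the unitless ratio, or `NA` (with a warning) if the permissive
#'   mean is zero.
#' @export
normalize_growth <- function(stress, permissive) {
  stopifnot(length(stress) >= 1L, length(permissive) >= 1L,
            all(stress >= 0, na.rm = TRUE), all(permissive >= 0, na.rm = TRUE))
  mp <- mean(permissive, na.rm = TRUE)
  if (!is.finite(mp) || mp == 0) {
    warning("permissive growth mean is zero; normalized growth undefined")
    return(NA_real_)
  }
  mean(stress, na.rm = TRUE) / mp
}

#' Midparent (directional epistasis) test
#'
#' Compares the mean phenotype of a cross's segregants to the midparent
#' value, the average of the two parents' means. Under purely additive
#' genetics the segregant mean equals the midparent value; a significant
#' deviation indicates directional non-additivity among the causal loci.
#' The statistic is `t = (mean_seg - midparent) / SE` with
#' `SE^2 = s2_seg/n_seg + (s2_1/n_1 + s2_2/n_2)/4`, referred to a t
#' distribution with Welch-Satterthwaite degrees of freedom.
#'
#' @param segregants numeric vector of segregant phenotypes (n >= 2).
#' @param parent1,parent2 numeric vectors of parental replicate phenotypes
#'   (each n >= 2).
#' @return object of class `htest` with the statistic, degrees of freedom,
#'   two-sided p-value, and the segregant-mean and midparent estimates.
#' @export
midparent_test <- function(segregants, parent1, parent2) {
  if (length(segregants) < 2L || length(parent1) < 2L || length(parent2) < 2L)
    stop("need at least 2 replicates per group")
  n <- c(length(segregants), length(parent1), length(parent2))
  mid <- (mean(parent1) + mean(parent2)) / 2
  delta <- mean(segregants) - mid
  comps <- c(var(segregants) / n[1L],
             var(parent1) / (4 * n[2L]),
             var(parent2) / (4 * n[3L]))
  se2 <- sum(comps)
  if (se2 == 0) {
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    df <- sum(n) - 3
  } else {
    stat <- delta / sqrt(se2)
    df <- se2^2 / sum(comps^2 / (n - 1L))
  }
  p <- if (is.infinite(stat)) 0 else 2 * pt(-abs(stat), df)
  structure(list(statistic = c(t = stat), parameter = c(df = df),
                 p.value = p,
                 estimate = c(`segregant mean` = mean(segregants),
                              midparent = mid),
                 method = "Midparent t test (Welch-combined SE)",
                 data.name = "segregants vs. parents",
                 alternative = "two.sided"),
            class = "htest")
}

#' Coverage-ratio copy-number estimate
#'
#' Ratio of the median read depth over a region (e.g. a gene's variant
#' coding sequence) to the median depth of its chromosome, read as the
#' number of copies of the region in a haploid genome. Estimates are not
#' rounded to integers.
#'
#' @param region_depth per-position (or per-window) depths over the region.
#' @param chrom_depth per-position depths over the reference chromosome.
#' @return unitless copy-number estimate.
#' @export
copy_number <- function(region_depth, chrom_depth) {
  if (length(region_depth) == 0L || length(chrom_depth) == 0L)
    stop("coverage tracks must be non-empty")
  if (any(region_depth < 0) || any(chrom_depth < 0))
    stop("depths must be non-negative")
  md <- median(chrom_depth)
  if (md == 0) stop("chromosome median coverage is zero")
  median(region_depth) / md
}
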