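#' Variant segregation matrix over the crosses of a design
#'
#' For every variant in a QTL region, records in which crosses it
#' segregates: entry (variant, cross) is 1 when the cross's two parents
#' carry different alleles. A variant private to one strain segregates in
#' exactly the two crosses containing that strain; more broadly, any
#' polymorphic variant segregates in an even number (>= 2) of crosses of a
#' round-robin design.
#'
#' @param markers a `marker_table` covering the region's variants.
#' @param design a [build_round_robin()] design whose strains appear in the
#'   marker table.
#' @param region list or data.frame row with `chrom`, `lower`, `upper`
#'   (bp, inclusive) delimiting the QTL region.
#' @return 0/1 integer matrix, variants (rownames `chrom:pos`) x crosses.
#' @export
segregation_matrix <- function(markers, design, region) {
  stopifnot(inherits(design, "cross_design"))
  strains <- attr(markers, "strains")
  if (!all(design$strains %in% strains))
    stop("design strains missing from the marker table")
  keep <- markers$chrom == region$chrom & markers$pos >= region$lower &
    markers$pos <= region$upper
  if (!any(keep)) stop("no variants in the region")
  sub <- markers[keep, , drop = FALSE]
  ga <- as.matrix(sub[design$crosses$parent_a])
  gb <- as.matrix(sub[design$crosses$parent_b])
  seg <- (ga != gb) * 1L
  dimnames(seg) <- list(paste0(sub$chrom, ":", sub$pos),
                        design$crosses$cross)
  seg
}

#' Association between a segregation pattern and the per-cross LOD pattern
#'
#' The squared Pearson correlation between a variant's 0/1 segregation
#' indicator across crosses and the per-cross maximum LOD of the QTL
#' region. A causal variant should segregate exactly in the crosses where
#' the QTL appears, maximizing the score. Zero-variance patterns (variants
#' segregating everywhere or nowhere, or a flat LOD profile) carry no
#' association information and score 0 by convention.
#'
#' @param seg_row 0/1 indicator vector over crosses.
#' @param lod_vector per-cross (replicate-averaged) maximum LOD, same
#'   length and cross order.
#' @return squared correlation in `[0, 1]`.
#' @export
association_score <- function(seg_row, lod_vector) {
  if (length(seg_row) != length(lod_vector))
    stop("segregation and LOD vectors differ in length")
  if (var(seg_row) == 0 || var(lod_vector) == 0) return(0)
  cor(as.numeric(seg_row), as.numeric(lod_vector))^2
}

#' Score and permutation-test all region variants against the LOD pattern
#'
#' Computes [association_score()] for every variant of a segregation
#' matrix and an empirical p-value per variant from permutations of the
#' cross labels of the LOD vector (add-one corrected, so p is at least
#' `1/(n_perm + 1)`). Variants with `p <= alpha` are flagged significant
#' and the per-region fold reduction (variants considered over variants
#' significant) is attached.
#'
#' @param seg_matrix matrix from [segregation_matrix()].
#' @param lod_vector per-cross maximum LOD vector.
#' @param alpha significance level (default 0.01).
#' @param n_perm number of label permutations (default 10000).
#' @param seed optional seed.
#' @return data.frame (class `association_result`) sorted by decreasing
#'   `r2`: `variant`, `r2`, `p`, `significant`; attribute `fold_reduction`.
#' @export
significant_variants <- function(seg_matrix, lod_vector, alpha = 0.01,
                                 n_perm = 10000, seed = NULL) {
  stopifnot(is.matrix(seg_matrix), nrow(seg_matrix) >= 1L,
            ncol(seg_matrix) == length(lod_vector))
  r2 <- apply(seg_matrix, 1L, association_score, lod_vector = lod_vector)
  exceed <- rep(0L, nrow(seg_matrix))
  with_seed(seed, {
    for (k in seq_len(n_perm)) {
      perm <- sample(lod_vector)
      r2p <- apply(seg_matrix, 1L, association_score, lod_vector = perm)
      exceed <- exceed + (r2p >= r2)
    }
  })
  p <- (1 + exceed) / (n_perm + 1)
  out <- data.frame(variant = rownames(seg_matrix), r2 = r2, p = p,
                    significant = p <= alpha, stringsAsFactors = FALSE)
  out <- out[order(-out$r2), ]
  rownames(out) <- NULL
  n_sig <- sum(out$significant)
  attr(out, "fold_reduction") <- if (n_sig > 0) nrow(out) / n_sig else NA_real_
  class(out) <- c("association_result", "data.frame")
  out
}
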