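#' Build a round-robin cross design
#'
#' Arranges the parent strains on a cycle and crosses each strain to its two
#' neighbors, so that K strains give K crosses and every allele enters the
#' experiment in at least two crosses. Mating types alternate along the
#' cycle (a, alpha, a, ...), which is consistent for an even number of
#' strains; with an odd number the final adjacent pair shares a mating type
#' and a warning is issued.
#'
#' @param strains character vector of distinct parent strain ids, in cycle
#'   order (the order is part of the design).
#' @return an object of class `cross_design`: a list with elements
#'   `strains`, `crosses` (data.frame with columns `cross`, `parent_a`,
#'   `parent_b`; parent A is always the first-listed parent and fixes the
#'   allele-frequency orientation of the cross) and `mating_type` (named
#'   vector, `"a"` or `"alpha"` per strain).
#' @examples
#' rr <- build_round_robin(paste0("strain", 1:12))
#' table(unlist(rr$crosses[c("parent_a", "parent_b")]))
#' @export
build_round_robin <- function(strains) {
  strains <- as.character(strains)
  if (anyDuplicated(strains) > 0L) stop("strain ids must be distinct")
  K <- length(strains)
  if (K < 3L) stop("a round-robin design needs at least 3 strains")
  crosses <- data.frame(
    cross = seq_len(K),
    parent_a = strains,
    parent_b = strains[c(seq_len(K)[-1L], 1L)],
    stringsAsFactors = FALSE
  )
  mt <- setNames(rep(c("a", "alpha"), length.out = K), strains)
  if (K %% 2L == 1L) {
    warning("odd number of strains: mating types cannot alternate around the full cycle")
  }
  structure(list(strains = strains, crosses = crosses, mating_type = mt),
            class = "cross_design")
}

#' @export
print.cross_design <- function(x, ...) {
  cat("Round-robin cross design:", length(x$strains), "strains,",
      nrow(x$crosses), "crosses\n")
  print(x$crosses, row.names = FALSE)
  invisible(x)
}

#' Crosses in which a variant segregates
#'
#' A variant segregates in a cross when the cross's two parents carry
#' different alleles. On a cycle, the number of segregating crosses equals
#' the number of allele changes encountered walking around the cycle, which
#' is even and at least 2 for any polymorphic variant.
#'
#' @param alleles 0/1 vector of parental alleles, either named by strain or
#'   in the design's strain order.
#' @param design a [build_round_robin()] design.
#' @return integer vector of cross indices in which the variant segregates.
#' @export
segregating_crosses <- function(alleles, design) {
  stopifnot(inherits(design, "cross_design"))
  if (!is.null(names(alleles))) {
    missing <- setdiff(design$strains, names(alleles))
    if (length(missing)) stop("alleles missing for strains: ",
                              paste(missing, collapse = ", "))
    alleles <- alleles[design$strains]
  } else if (length(alleles) != length(design$strains)) {
    stop("allele vector length does not match the number of strains")
  }
  a <- alleles[match(design$crosses$parent_a, design$strains)]
  b <- alleles[match(design$crosses$parent_b, design$strains)]
  which(a != b)
}

# cross k of a design as a small list used by the simulators
cross_info <- function(design, k) {
  stopifnot(inherits(design, "cross_design"))
  row <- design$crosses[design$crosses$cross == k, ]
  if (nrow(row) != 1L) stop("no cross ", k, " in design")
  list(cross = row$cross, parent_a = row$parent_a, parent_b = row$parent_b)
}
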