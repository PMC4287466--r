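#' Recombination model (Haldane map on a fixed bp-per-cM scale)
#'
#' The genetic map is summarized by a single genome-wide scale: the number
#' of base pairs per centimorgan (default 2200 bp/cM, the standard scale for
#' the S. cerevisiae genome). Crossovers are assumed to occur without
#' interference, so physical distance converts to recombination fraction via
#' the Haldane map function. The same model drives both the meiosis
#' simulator and the transition kernel of the LOD model.
#'
#' @param bp_per_cM base pairs per centimorgan; must be positive.
#' @return object of class `recomb_model`.
#' @export
recomb_model <- function(bp_per_cM = 2200) {
  if (!is.numeric(bp_per_cM) || length(bp_per_cM) != 1L || bp_per_cM <= 0)
    stop("bp_per_cM must be a single positive number")
  structure(list(bp_per_cM = as.numeric(bp_per_cM), map_function = "haldane"),
            class = "recomb_model")
}

#' Recombination fraction between two positions
#'
#' Haldane map function: `rho = 0.5 * (1 - exp(-2 d))` with `d` the distance
#' in Morgans (`distance_bp / (100 * bp_per_cM)`). Monotone in distance,
#' zero at zero distance, approaching 1/2 for unlinked positions.
#'
#' @param distance_bp non-negative physical distance(s) in base pairs.
#' @param model a [recomb_model()].
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recombination_fraction(2200)   # one centimorgan
#' @export
recombination_fraction <- function(distance_bp, model = recomb_model()) {
  stopifnot(inherits(model, "recomb_model"))
  if (any(is.na(distance_bp)) || any(distance_bp < 0))
    stop("distances must be non-negative")
  d <- distance_bp / (100 * model$bp_per_cM)
  0.5 * (1 - exp(-2 * d))
}
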