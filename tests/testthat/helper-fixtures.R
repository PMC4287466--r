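# shared fixtures and independent oracles, built in code at test time

# binned counts with class/attributes, bins contiguous from position 1
make_binned <- function(count_a, depth, bin_bp = 100, chrom = "chr1",
                        cross = 1L, mating_type = "a", condition = "stress") {
  stopifnot(length(count_a) == length(depth))
  df <- data.frame(chrom = chrom,
                   start = (seq_along(count_a) - 1L) * bin_bp + 1L,
                   count_a = count_a, depth = depth,
                   stringsAsFactors = FALSE)
  attr(df, "bin_bp") <- as.integer(bin_bp)
  attr(df, "cross") <- cross
  attr(df, "mating_type") <- mating_type
  attr(df, "condition") <- condition
  class(df) <- c("binned_counts", "data.frame")
  df
}

make_counts <- function(chrom, pos, count_a, depth, ...) {
  pool_counts(data.frame(chrom = chrom, pos = pos, count_a = count_a,
                         depth = depth, stringsAsFactors = FALSE), ...)
}

make_freq <- function(chrom, pos, freq, cross = 1L, mating_type = "a",
                      condition = "stress") {
  df <- data.frame(chrom = chrom, pos = pos, freq = freq,
                   stringsAsFactors = FALSE)
  attr(df, "cross") <- cross
  attr(df, "mating_type") <- mating_type
  attr(df, "condition") <- condition
  class(df) <- c("freq_track", "data.frame")
  df
}

make_contrast <- function(chrom, pos, diff, ...) {
  df <- data.frame(chrom = chrom, pos = pos, diff = diff,
                   stringsAsFactors = FALSE)
  class(df) <- c("contrast_track", "data.frame")
  df
}

# LOD track with the package's bin geometry
make_lod_track <- function(lod, bin_bp = 100, chrom = "chr1", cross = 1L,
                           mating_type = "a", condition = "stress") {
  start <- (seq_along(lod) - 1L) * bin_bp + 1L
  df <- data.frame(chrom = chrom, start = start, end = start + bin_bp - 1L,
                   pos = start + (bin_bp - 1) / 2, lod = lod,
                   stringsAsFactors = FALSE)
  attr(df, "bin_bp") <- as.integer(bin_bp)
  attr(df, "cross") <- cross
  attr(df, "mating_type") <- mating_type
  attr(df, "condition") <- condition
  class(df) <- c("lod_track", "data.frame")
  df
}

# independent oracle: exhaustive path enumeration of the chain likelihood
brute_force_loglik <- function(binned, config) {
  T_ <- config$grid_size
  grid <- seq(0, 1, length.out = T_)
  P <- rrqtl:::transition_matrix(config)
  B <- nrow(binned)
  paths <- as.matrix(expand.grid(rep(list(seq_len(T_)), B)))
  total <- 0
  for (row in seq_len(nrow(paths))) {
    s <- paths[row, ]
    pr <- 1 / T_
    for (i in seq_len(B)) {
      if (i > 1L) pr <- pr * P[s[i - 1L], s[i]]
      if (binned$depth[i] > 0)
        pr <- pr * dbinom(binned$count_a[i], binned$depth[i], grid[s[i]])
    }
    total <- total + pr
  }
  log(total)
}

# a small multi-chromosome marker table + design used across tests
small_sim <- function(seed = 42, n_strains = 4) {
  cfg <- sim_config(n_strains = n_strains,
                    chrom_lengths = c(chr1 = 60000, chr2 = 40000, chr3 = 50000),
                    markers_per_chrom = c(120L, 80L, 100L),
                    pool_size = 200, depth = 50)
  markers <- simulate_parent_genomes(cfg, seed = seed)
  list(cfg = cfg, markers = markers,
       design = build_round_robin(attr(markers, "strains")))
}

# one-chromosome two-parent experiment used by the calibration/power tests:
# a pool of segregants, an optional planted viability locus, and sequenced
# selected/control pools
one_chrom_experiment <- function(seed, length_bp = 1e6, n_markers = 2000,
                                 pool_size = 1000, depth = 50,
                                 effect_beta = NULL, effect_at = 0.5) {
  cfg <- sim_config(n_strains = 2,
                    chrom_lengths = c(chr1 = length_bp),
                    markers_per_chrom = n_markers,
                    pool_size = pool_size, depth = depth)
  markers <- simulate_parent_genomes(cfg, seed = derive_seed(seed, "genomes"))
  cross <- list(cross = 1L, parent_a = "strain01", parent_b = "strain02")
  pop <- simulate_segregants(cross, markers, n = pool_size,
                             seed = derive_seed(seed, "meiosis"))
  out <- list(cfg = cfg, markers = markers, cross = cross, pop = pop)
  if (!is.null(effect_beta)) {
    j <- which.min(abs(markers$pos - effect_at * length_bp))
    out$locus_pos <- markers$pos[j]
    ef <- qtl_effect("chr1", markers$pos[j], beta = c(0, effect_beta))
    out$selected <- apply_selection(pop, markers, effects = list(ef),
                                    seed = derive_seed(seed, "select"))
  }
  out
}
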