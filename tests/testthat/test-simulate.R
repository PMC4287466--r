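test_that("parent genome simulation is deterministic and polymorphic", {
  s <- small_sim(seed = 1)
  s2 <- small_sim(seed = 1)
  expect_identical(as.data.frame(s$markers), as.data.frame(s2$markers))
  g <- as.matrix(s$markers[attr(s$markers, "strains")])
  expect_false(any(rowSums(g) %in% c(0L, ncol(g))))
  for (ch in unique(s$markers$chrom)) {
    expect_false(is.unsorted(s$markers$pos[s$markers$chrom == ch],
                             strictly = TRUE))
  }
  expect_equal(sum(s$markers$is_mat), 1L)
  expect_equal(s$markers$chrom[s$markers$is_mat], "chr3")
  expect_error(sim_config(n_strains = 4, markers_per_chrom = 0L),
               "zero markers")
})

test_that("fully private tables segregate in exactly 2 crosses per variant", {
  cfg <- sim_config(n_strains = 12,
                    chrom_lengths = c(chr1 = 50000, chr2 = 50000, chr3 = 50000),
                    markers_per_chrom = 60L, pool_size = 100, depth = 30,
                    private_frac = 1)
  mk <- simulate_parent_genomes(cfg, seed = 3)
  design <- build_round_robin(attr(mk, "strains"))
  strains <- attr(mk, "strains")
  for (i in which(!mk$is_mat)) {
    seg <- segregating_crosses(unlist(mk[i, strains]), design)
    expect_equal(length(seg), 2L)
  }
})

test_that("segregant origins follow the recombination model", {
  s <- small_sim(seed = 5)
  cross <- rrqtl:::cross_info(s$design, 1)
  # rho -> 0: whole chromosomes from one parent
  tight <- recomb_model(bp_per_cM = 1e12)
  seg <- simulate_segregants(cross, s$markers, n = 20, model = tight, seed = 8)
  for (ch in unique(s$markers$chrom)) {
    idx <- which(s$markers$chrom == ch)
    expect_true(all(apply(seg[, idx, drop = FALSE], 1,
                          function(x) length(unique(x)) == 1L)))
  }
  # mean parent-A share close to 1/2 (binomial-scale tolerance)
  seg <- simulate_segregants(cross, s$markers, n = 10000, seed = 9)
  share <- rowMeans(seg == 1L)
  se <- sd(share) / sqrt(length(share))
  expect_lt(abs(mean(share) - 0.5), 3 * se + 1e-6)
  expect_error(simulate_segregants(list(cross = 1, parent_a = "nope",
                                        parent_b = "strain01"),
                                   s$markers, n = 1),
               "not present")
})

test_that("selection shifts a single-locus frequency to its closed form", {
  s <- small_sim(seed = 11)
  cross <- rrqtl:::cross_info(s$design, 1)
  mk <- s$markers
  # pick a marker segregating in cross 1, away from chromosome ends
  segm <- which(mk[[cross$parent_a]] != mk[[cross$parent_b]] & !mk$is_mat)
  j <- segm[which.min(abs(mk$pos[segm] - 30000))]
  pop <- simulate_segregants(cross, mk, n = 20000, seed = 12)
  beta <- log(3)
  allele_a <- mk[[cross$parent_a]][j]
  ef <- qtl_effect(mk$chrom[j], mk$pos[j],
                   beta = if (allele_a == 1) c(0, beta) else c(beta, 0))
  sel <- apply_selection(pop, mk, effects = list(ef), seed = 13)
  p0 <- mean(pop[, j] == 1L)
  expected <- p0 * exp(beta) / (p0 * exp(beta) + (1 - p0))
  observed <- mean(sel[, j] == 1L)
  expect_lt(abs(observed - expected), 0.015)  # Monte-Carlo tolerance, n=20000

  # no selection leaves frequencies unchanged in expectation
  null_sel <- apply_selection(pop, mk, effects = list(), seed = 14)
  expect_lt(max(abs(colMeans(null_sel == 1L) - colMeans(pop == 1L))), 0.03)
})

test_that("mating-type sorting fixes the MAT-locus allele", {
  s <- small_sim(seed = 21)
  cross <- rrqtl:::cross_info(s$design, 2)
  pop <- simulate_segregants(cross, s$markers, n = 500, seed = 22)
  mata <- apply_selection(pop, s$markers, mat_filter = "a", seed = 23)
  j <- which(s$markers$is_mat)
  alleles <- rrqtl:::segregant_alleles_at(mata, s$markers, j)
  expect_true(all(alleles == 1L))
  matalpha <- apply_selection(pop, s$markers, mat_filter = "alpha", seed = 24)
  expect_true(all(rrqtl:::segregant_alleles_at(matalpha, s$markers, j) == 0L))
})

test_that("pooled sequencing has Poisson depth and copy-number scaling", {
  cfg <- sim_config(n_strains = 2, chrom_lengths = c(chr1 = 2e5),
                    markers_per_chrom = 400L, pool_size = 300, depth = 50,
                    copy_number = data.frame(chrom = "chr1", start = 150000,
                                             end = 200000, copies = 4))
  mk <- simulate_parent_genomes(cfg, seed = 31)
  cross <- list(cross = 1L, parent_a = "strain01", parent_b = "strain02")
  pop <- simulate_segregants(cross, mk, n = 300, seed = 32)
  ct <- sequence_pool(pop, mk, cfg, seed = 33)
  bg <- ct$depth[ct$pos < 150000]
  fg <- ct$depth[ct$pos >= 150000]
  se <- sqrt(50 / length(bg))
  expect_lt(abs(mean(bg) - 50), 3 * se)
  expect_gt(length(fg), 50)
  expect_lt(abs(mean(fg) / mean(bg) - 4), 0.4)
  # very deep sequencing recovers the true pool frequencies
  cfg_deep <- sim_config(n_strains = 2, chrom_lengths = c(chr1 = 2e5),
                         markers_per_chrom = 400L, pool_size = 300,
                         depth = 20000)
  deep <- sequence_pool(pop, mk, cfg_deep, seed = 34)
  truth <- pool_true_frequencies(pop, mk)
  expect_lt(max(abs(deep$count_a / deep$depth - truth$freq)), 0.02)
})

test_that("frequency noise shrinks with pool size and depth under no selection", {
  settings <- list(c(pool = 50, depth = 10), c(pool = 200, depth = 30),
                   c(pool = 1000, depth = 100))
  dev <- vapply(seq_along(settings), function(i) {
    st <- settings[[i]]
    cfg <- sim_config(n_strains = 2, chrom_lengths = c(chr1 = 1e5),
                      markers_per_chrom = 200L, pool_size = st["pool"],
                      depth = st["depth"])
    mk <- simulate_parent_genomes(cfg, seed = 41)
    cross <- list(cross = 1L, parent_a = "strain01", parent_b = "strain02")
    pop <- simulate_segregants(cross, mk, n = st[["pool"]],
                               seed = derive_seed(42, i))
    ct <- sequence_pool(pop, mk, cfg, seed = derive_seed(43, i))
    f <- compute_frequencies(ct, min_depth = 1)
    mean(abs(f$freq - 0.5), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(dev) < 0))
})
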