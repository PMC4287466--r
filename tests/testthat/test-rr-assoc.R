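# small helper: a marker table for a region built directly from a genotype
# matrix (variants x strains)
region_markers <- function(g, chrom = "chr15", start = 100000, by = 500) {
  strains <- colnames(g)
  df <- data.frame(chrom = chrom, pos = start + (seq_len(nrow(g)) - 1L) * by,
                   is_mat = FALSE, g, check.names = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "strains") <- strains
  class(df) <- c("marker_table", "data.frame")
  df
}

test_that("segregation matrices flag crosses whose parents differ", {
  design <- build_round_robin(paste0("s", 1:12))
  g <- rbind(private = c(1, rep(0, 11)),          # private to s1
             constant = rep(1, 12) * 0,           # placeholder, fixed below
             alternating = rep(c(1, 0), 6))
  g["constant", ] <- c(rep(1, 6), rep(0, 6))       # 6/6 split, two blocks
  colnames(g) <- design$strains
  mk <- region_markers(g)
  seg <- segregation_matrix(mk, design,
                            list(chrom = "chr15", lower = 1, upper = 2e5))
  expect_equal(unname(which(seg[1L, ] == 1)), c(1L, 12L))  # private to s1
  expect_equal(sum(seg[2L, ]), 2L)                 # block split: 2 boundaries
  expect_true(all(seg[3L, ] == 1L))                # 6/6 alternating: all 12
  expect_error(segregation_matrix(mk, design,
                                  list(chrom = "chr15", lower = 1, upper = 2)),
               "no variants")
})

test_that("association scores are squared Pearson correlations with a zero-variance rule", {
  expect_equal(association_score(c(1, 1, rep(0, 10)), c(10, 10, rep(0, 10))), 1)
  # with unequal peak heights the matching pattern still attains the maximum
  # over every polymorphic 0/1 pattern (exhaustively enumerated)
  lod <- c(10, 12, rep(0, 10))
  match_r2 <- association_score(c(1, 1, rep(0, 10)), lod)
  all_r2 <- vapply(1:(2^12 - 2), function(code) {
    association_score(as.integer(intToBits(code))[1:12], lod)
  }, 0)
  expect_equal(match_r2, max(all_r2))
  expect_equal(association_score(rep(1, 12), lod), 0)
  expect_equal(association_score(c(1, 0, 1, 0), c(3, 1, 4, 2)), 0.8)
  expect_error(association_score(c(1, 0), c(1, 2, 3)), "length")
  # invariance: joint permutation of crosses, affine rescaling of the LOD
  set.seed(301)
  for (i in 1:20) {
    seg <- rbinom(12, 1, 0.5)
    lodv <- rexp(12)
    r2 <- association_score(seg, lodv)
    perm <- sample(12)
    expect_equal(association_score(seg[perm], lodv[perm]), r2)
    expect_equal(association_score(seg, 3.7 * lodv + 2), r2)
    expect_gte(r2, 0); expect_lte(r2, 1)
  }
})

test_that("a private variant driving two neighboring crosses tops the region", {
  set.seed(302)
  design <- build_round_robin(paste0("s", 1:12))
  K <- 12
  target <- 5                      # the CLIB219-like parent
  private_pattern <- as.integer(seq_len(K) %in% c(target))
  n_total <- 64; n_private <- 4
  g <- matrix(0L, nrow = n_total, ncol = K,
              dimnames = list(NULL, design$strains))
  for (i in seq_len(n_private)) g[i, target] <- 1L
  i <- n_private + 1L
  while (i <= n_total) {
    cand <- rbinom(K, 1, 0.3)
    if (sum(cand) %in% c(0, K)) next
    if (identical(as.integer(cand), private_pattern)) next
    g[i, ] <- cand
    i <- i + 1L
  }
  mk <- region_markers(g)
  seg <- segregation_matrix(mk, design,
                            list(chrom = "chr15", lower = 1, upper = 1e6))
  # LOD high exactly in the two crosses carrying the target parent
  lodv <- runif(K, 0, 1.5)
  lodv[segregating_crosses(private_pattern, design)] <- c(41, 38)
  res <- significant_variants(seg, lodv, n_perm = 2000, seed = 303)
  top <- max(res$r2)
  priv_names <- paste0("chr15:", mk$pos[1:n_private])
  expect_true(all(res$r2[match(priv_names, res$variant)] == top))
  expect_true(all(res$p >= 1 / 2001 & res$p <= 1))
  # all-zero LOD vector: nothing is significant
  res0 <- significant_variants(seg, rep(0, K), n_perm = 200, seed = 304)
  expect_false(any(res0$significant))
  expect_true(all(res0$r2 == 0))
})

test_that("causal variants rank at the top across simulated groups", {
  set.seed(305)
  design <- build_round_robin(paste0("s", 1:12))
  hits <- 0L
  n_groups <- 50
  for (gi in seq_len(n_groups)) {
    repeat {
      causal <- rbinom(12, 1, 0.4)
      if (!sum(causal) %in% c(0, 12)) break
    }
    g <- matrix(0L, 20, 12, dimnames = list(NULL, design$strains))
    g[1, ] <- causal
    for (i in 2:20) {
      repeat {
        cand <- rbinom(12, 1, 0.4)
        if (!sum(cand) %in% c(0, 12) && !identical(cand, causal)) break
      }
      g[i, ] <- cand
    }
    mk <- region_markers(g)
    seg <- segregation_matrix(mk, design,
                              list(chrom = "chr15", lower = 1, upper = 1e6))
    lodv <- 12 * seg[1, ] + rnorm(12, 0, 1.2)   # additive signal, mild noise
    r2 <- apply(seg, 1, association_score, lod_vector = lodv)
    if (r2[1] >= max(r2)) hits <- hits + 1L
  }
  expect_gte(hits / n_groups, 0.95)
})
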