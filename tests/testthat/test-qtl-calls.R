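test_that("peaks above threshold get 2-LOD drop intervals", {
  # flat track below threshold: nothing
  expect_equal(nrow(call_qtl(make_lod_track(rep(4.9, 50)))), 0L)

  # symmetric triangular peak (max 10, slope 1/bin): interval = bins >= 8
  tri <- c(rep(0, 10), 1:9, 10, 9:1, rep(0, 10))
  calls <- call_qtl(make_lod_track(tri))
  expect_equal(nrow(calls), 1L)
  peak_bin <- which.max(tri)
  expect_equal(calls$peak_lod, 10)
  expect_equal(calls$lower, (peak_bin - 2 - 1) * 100 + 1)
  expect_equal(calls$upper, (peak_bin + 2) * 100)

  # brute-force oracle: interval = maximal run of bins with lod >= peak - drop
  set.seed(201)
  for (rep in 1:10) {
    lod <- pmax(0, cumsum(rnorm(80, 0, 2)))
    tr <- make_lod_track(lod)
    calls <- call_qtl(tr, threshold = 5, drop = 2)
    for (i in seq_len(nrow(calls))) {
      pk <- which(tr$pos == calls$peak_pos[i])
      lim <- calls$peak_lod[i] - 2
      lo <- pk; while (lo > 1 && lod[lo - 1] >= lim) lo <- lo - 1
      hi <- pk; while (hi < 80 && lod[hi + 1] >= lim) hi <- hi + 1
      expect_lte(calls$lower[i], tr$start[lo])
      expect_gte(calls$upper[i], tr$end[hi])
      expect_true(calls$lower[i] <= calls$peak_pos[i] &
                    calls$peak_pos[i] <= calls$upper[i])
    }
  }
})

test_that("overlapping drop intervals merge to the higher peak", {
  lod <- c(rep(0, 5), 6, 7, 8, 9, 8.5, 8, 7.5, 7, 6.5, rep(0, 5))
  calls <- call_qtl(make_lod_track(lod))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$peak_lod, 9)
  # two peaks, LOD 9 and 7, with overlapping drop intervals: one call at 9
  lod2 <- c(rep(0, 3), 8, 9, 8, 7.5, 7, 7.5, rep(0, 3))
  calls2 <- call_qtl(make_lod_track(lod2))
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$peak_lod, 9)
})

test_that("lowering the drop never widens an interval", {
  set.seed(202)
  for (rep in 1:10) {
    lod <- pmax(0, 8 * exp(-abs(seq(-40, 39)) / 10) + rnorm(80, 0, 0.3))
    tr <- make_lod_track(lod)
    c2 <- call_qtl(tr, drop = 2)
    c1 <- call_qtl(tr, drop = 1)
    if (nrow(c2) == 1L && nrow(c1) == 1L) {
      expect_gte(c1$lower, c2$lower)
      expect_lte(c1$upper, c2$upper)
    }
  }
})

test_that("replication across mating types averages interval bounds", {
  a <- call_qtl(make_lod_track(c(rep(0, 10), 2, 6, 12, 6, 2, rep(0, 10)),
                               mating_type = "a"))
  a$lower <- 100000; a$upper <- 140000
  b <- a
  b$lower <- 110000; b$upper <- 150000
  b$mating_type <- "alpha"
  m <- replicate_support(a, b)
  expect_equal(m$lower, 105000)
  expect_equal(m$upper, 145000)
  expect_true(m$replicated)
  expect_identical(m$mating_type, "both")
  # symmetry and idempotence
  m_rev <- replicate_support(b, a)
  expect_equal(m$lower, m_rev$lower)
  expect_equal(m$peak_lod, m_rev$peak_lod)
  self <- replicate_support(a, a)
  expect_equal(self$lower, a$lower)
  expect_equal(self$upper, a$upper)
  expect_equal(self$peak_lod, a$peak_lod)
  # disjoint intervals: both flagged unreplicated
  far <- a; far$lower <- 500000; far$upper <- 540000
  u <- replicate_support(a, far)
  expect_equal(nrow(u), 2L)
  expect_true(all(!u$replicated))
})

test_that("direction agreement compares region-mean contrast signs", {
  calls <- new_calls <- call_qtl(make_lod_track(c(rep(0, 4), 6, 7, 6, rep(0, 4))))
  pos <- seq(50, 1100, by = 50)
  ca <- make_contrast("chr1", pos, rep(0.3, length(pos)))
  res <- direction_agreement(calls, ca, ca, n_perm = 50, seed = 1)
  expect_equal(res$agreement, 1)
  expect_true(res$p_value >= 1 / 51 && res$p_value <= 1)

  # independent random contrasts agree about half the time
  set.seed(203)
  many <- do.call(rbind, lapply(seq(1, 40000, by = 2000), function(lo) {
    data.frame(chrom = "chr1", peak_pos = lo + 500, peak_lod = 6,
               lower = lo, upper = lo + 1999, direction = NA, cross = 1L,
               condition = "x", mating_type = "a", replicated = FALSE)
  }))
  class(many) <- c("qtl_calls", "data.frame")
  pos2 <- seq(1, 42000, by = 100)
  fracs <- vapply(1:30, function(i) {
    ca <- make_contrast("chr1", pos2, rnorm(length(pos2)))
    cb <- make_contrast("chr1", pos2, rnorm(length(pos2)))
    direction_agreement(many, ca, cb, n_perm = 0)$agreement
  }, 0)
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("dosage combination is conservative and transitive", {
  base <- as.data.frame(call_qtl(make_lod_track(c(rep(0, 4), 13, rep(0, 4)))))
  lo <- base; lo$lower <- 100; lo$upper <- 300; lo$peak_lod <- 12
  lo$condition <- "0.5M"
  hi <- base; hi$lower <- 250; hi$upper <- 500; hi$peak_lod <- 8
  hi$condition <- "1M"
  both <- rbind(lo, hi)
  class(both) <- c("qtl_calls", "data.frame")
  comb <- combine_conditions(both)
  expect_equal(nrow(comb), 1L)
  expect_equal(comb$peak_lod, 8)        # minimum across dosages
  expect_equal(comb$lower, 175)
  expect_identical(comb$condition, "0.5M+1M")

  # single-dosage region passes through
  solo <- hi; solo$lower <- 5000; solo$upper <- 5400
  res <- combine_conditions({x <- rbind(lo, hi, solo)
                             class(x) <- c("qtl_calls", "data.frame"); x})
  expect_equal(nrow(res), 2L)

  # chain a-b, b-c merges into a single call (transitive closure)
  a <- base; a$lower <- 100; a$upper <- 300; a$condition <- "d1"
  b <- base; b$lower <- 250; b$upper <- 600; b$condition <- "d2"
  cc <- base; cc$lower <- 550; cc$upper <- 800; cc$condition <- "d3"
  chain <- rbind(a, b, cc)
  class(chain) <- c("qtl_calls", "data.frame")
  expect_equal(nrow(combine_conditions(chain)), 1L)
})

test_that("cross-grouping records per-cross in-region max LOD", {
  lod1 <- c(rep(0, 10), 3, 8, 14, 8, 3, rep(0, 10))
  lod2 <- c(rep(0, 11), 4, 9, 4, rep(0, 11))
  tr1 <- make_lod_track(lod1, cross = 7L)
  tr2 <- make_lod_track(lod2, cross = 8L)
  tr3 <- make_lod_track(rep(0.5, 25), cross = 9L)
  c1 <- call_qtl(tr1); c1$replicated <- TRUE
  c2 <- call_qtl(tr2); c2$replicated <- TRUE
  calls <- rbind(c1, c2)
  class(calls) <- c("qtl_calls", "data.frame")
  groups <- group_across_crosses(calls, list(`7` = tr1, `8` = tr2, `9` = tr3))
  expect_equal(nrow(groups$groups), 1L)
  expect_equal(groups$groups$n_crosses, 2L)
  expect_identical(groups$groups$crosses, "7,8")
  # per-cross max-LOD vector matches a direct scan of each track
  gr <- groups$groups
  for (tr in list(tr1, tr2, tr3)) {
    cx <- as.character(attr(tr, "cross"))
    sel <- tr$end >= gr$lower & tr$start <= gr$upper
    expect_equal(unname(groups$lod[1, cx]), max(tr$lod[sel]))
  }
  expect_equal(unname(groups$histogram["2"]), 1L)
  # non-overlapping calls each form their own group
  c3 <- call_qtl(make_lod_track(c(rep(0, 40), 6, rep(0, 5)), cross = 9L))
  calls2 <- rbind(c1, c3)
  class(calls2) <- c("qtl_calls", "data.frame")
  g2 <- group_across_crosses(calls2, list(`7` = tr1, `9` = tr3))
  expect_equal(nrow(g2$groups), 2L)
  expect_true(all(g2$groups$n_crosses == 1L))
})
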