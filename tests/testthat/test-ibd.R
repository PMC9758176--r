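test_that("identical genotype vectors yield one full-panel segment", {
  set.seed(1)
  g <- rand_geno(500, 0.4)
  pos <- sort(sample(1:1e6, 500))
  gm <- make_pair_gm(g, g, pos)
  seg <- pairwise_ibd_segments(gm, c("S1", "S2"), streak_params(0, 10, 0))
  expect_equal(nrow(seg), 1)
  first_inf <- pos[which(!is.na(g))[1]]
  expect_equal(seg$start, min(pos[!is.na(g)]))
  expect_equal(seg$end, max(pos[!is.na(g)]))
  expect_equal(seg$n_mismatches, 0)
})

test_that("streak detection matches the brute-force oracle over a parameter grid", {
  grid <- expand.grid(k = c(0, 1, 3), min_markers = c(1, 5), min_span = c(0, 50000))
  for (seed in 1:3) {
    set.seed(seed)
    n <- 150
    g1 <- rand_geno(n, 0.5, missing_rate = 0.05)
    g2 <- rand_geno(n, 0.5, missing_rate = 0.05)
    pos <- sort(sample(1:1.5e6, n))
    gm <- make_pair_gm(g1, g2, pos)
    for (r in seq_len(nrow(grid))) {
      p <- streak_params(grid$k[r], grid$min_markers[r], grid$min_span[r])
      got <- pairwise_ibd_segments(gm, c("S1", "S2"), p)
      want <- oracle_segments(g1, g2, pos, grid$k[r], grid$min_markers[r],
                              grid$min_span[r])
      expect_equal(got[, c("start", "end", "n_markers", "n_mismatches")], want,
                   info = sprintf("seed %d, k=%d mm=%d ms=%d", seed, grid$k[r],
                                  grid$min_markers[r], grid$min_span[r]))
    }
  }
})

test_that("segment detection is symmetric in the sample pair", {
  set.seed(5)
  gm <- make_pair_gm(rand_geno(200, 0.5), rand_geno(200, 0.5))
  p <- streak_params(1, 5, 0)
  a <- pairwise_ibd_segments(gm, c("S1", "S2"), p)
  b <- pairwise_ibd_segments(gm, c("S2", "S1"), p)
  expect_equal(a[, c("start", "end", "n_markers", "n_mismatches")],
               b[, c("start", "end", "n_markers", "n_mismatches")])
})

test_that("missing genotypes neither terminate a streak nor count as markers", {
  g1 <- rep(1L, 50); g2 <- rep(1L, 50)
  g1[20:25] <- NA
  g2[30] <- NA
  gm <- make_pair_gm(g1, g2)
  seg <- pairwise_ibd_segments(gm, c("S1", "S2"), streak_params(0, 1, 0))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_markers, 50 - 6 - 1)
  # a streak never starts or ends on a missing site
  g1[c(1, 50)] <- NA
  gm2 <- make_pair_gm(g1, g2)
  seg2 <- pairwise_ibd_segments(gm2, c("S1", "S2"), streak_params(0, 1, 0))
  expect_equal(seg2$start, 2000L)
  expect_equal(seg2$end, 49000L)
})

test_that("chance streaks between unrelated samples are controlled by the marker minimum", {
  hits <- vapply(1:50, function(seed) {
    set.seed(seed + 100)
    gm <- make_pair_gm(rand_geno(1000, 0.5), rand_geno(1000, 0.5))
    nrow(pairwise_ibd_segments(gm, c("S1", "S2"), streak_params(0, 60, 0)))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("span in kb is rounded half-up at the 10 kb level", {
  expect_equal(segment_span_kb(36118198, 37898880), 1780L)
  expect_equal(segment_span_kb(36137298, 36818382), 680L)
  expect_equal(segment_span_kb(100, 100), 0L)
  expect_equal(segment_span_kb(0, 15000), 20L)   # 15 kb rounds up
  expect_error(segment_span_kb(200, 100), class = "founderhap_invalid_input")
})

test_that("unknown samples are rejected", {
  gm <- make_pair_gm(rep(0L, 10), rep(0L, 10))
  expect_error(pairwise_ibd_segments(gm, c("S1", "nope")),
               class = "founderhap_invalid_input")
  expect_error(multiway_shared_segments(gm, "S1"),
               class = "founderhap_invalid_input")
})

test_that("multiway sharing reduces to pairwise for two samples and respects the quartet topology", {
  p <- streak_params(0, 50, 1e5)
  q <- simulate_founder_quartet(9)
  pw <- pairwise_ibd_segments(q$gm, c("P1", "P2"), p)
  mw <- multiway_shared_segments(q$gm, c("P1", "P2"), p)
  expect_equal(mw[, c("start", "end", "n_markers", "n_mismatches")],
               pw[, c("start", "end", "n_markers", "n_mismatches")])

  a <- multiway_shared_segments(q$gm, q$truth$pairs$alpha, p)
  b <- multiway_shared_segments(q$gm, q$truth$pairs$beta, p)
  expect_equal(c(a$start, a$end), q$truth$span_alpha)
  expect_equal(c(b$start, b$end), q$truth$span_beta)
  all4 <- multiway_shared_segments(q$gm, c("P1", "P2", "P3", "H1"), p)
  expect_equal(nrow(all4), 0)
})

test_that("planted spans are recovered exactly without genotyping error", {
  for (seed in c(2, 17, 23)) {
    sim <- simulate_ibd_pair(seed, span = c(36118198, 37898880))
    seg <- pairwise_ibd_segments(sim$gm, c("S1", "S2"), streak_params(0, 50, 1e5))
    expect_equal(nrow(seg), 1)
    expect_equal(c(seg$start, seg$end), sim$truth$span)
  }
})

test_that("planted spans survive genotyping error within tolerance", {
  n_ok <- sum(vapply(1:20, function(seed) {
    sim <- simulate_ibd_pair(seed, region = c(35e6, 38e6), span = c(35.8e6, 36.8e6),
                             spacing = 4000, error_rate = 0.002)
    seg <- pairwise_ibd_segments(sim$gm, c("S1", "S2"), streak_params(3, 50, 1e5))
    if (nrow(seg) == 0) return(FALSE)
    best <- seg[which.max(seg$n_markers), ]
    abs(best$span_bp - diff(sim$truth$span)) / diff(sim$truth$span) < 0.05
  }, logical(1)))
  expect_gte(n_ok, 19)
})

test_that("BED export uses 0-based half-open coordinates", {
  gm <- make_pair_gm(rep(1L, 30), rep(1L, 30))
  seg <- pairwise_ibd_segments(gm, c("S1", "S2"), streak_params(0, 5, 0))
  bed_path <- withr::local_tempfile(fileext = ".bed")
  write_bed(seg, bed_path)
  bed <- read.delim(bed_path, header = FALSE)
  expect_equal(bed$V2, seg$start - 1L)
  expect_equal(bed$V3, seg$end)
  expect_equal(bed$V5, seg$n_markers)
})
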