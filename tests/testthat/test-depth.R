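test_that("depth normalisation produces copy ratios around the median", {
  dp <- data.frame(contig = "chrS", bin_start = c(0, 10, 20),
                   bin_end = c(10, 20, 30), mean_depth = c(30, 45, 30))
  class(dp) <- c("cgr_depth", "data.frame")
  nd <- normalize_depth(dp)
  expect_equal(nd$ratio, c(1, 1.5, 1))
  dp$mean_depth <- 0
  expect_error(normalize_depth(dp), "median")
})

test_that("flat and stepped profiles segment to the right integer CN", {
  flat <- data.frame(contig = "chrS", bin_start = seq(0, 90, 10),
                     bin_end = seq(10, 100, 10), mean_depth = 30)
  class(flat) <- c("cgr_depth", "data.frame")
  cs <- segment_cn(normalize_depth(flat))
  expect_equal(nrow(cs), 1)
  expect_equal(cs$cn, 2)

  # median normalisation needs the diploid state to dominate the genome
  hemi <- data.frame(contig = "chrS", bin_start = seq(0, 110, 10),
                     bin_end = seq(10, 120, 10),
                     mean_depth = c(rep(30, 8), rep(15, 4)))
  class(hemi) <- c("cgr_depth", "data.frame")
  cs2 <- segment_cn(normalize_depth(hemi))
  expect_equal(cs2$cn, c(2, 1))
})

test_that("runs shorter than min_bins are absorbed into neighbours", {
  d <- data.frame(contig = "chrS", bin_start = seq(0, 110, 10),
                  bin_end = seq(10, 120, 10),
                  mean_depth = c(rep(30, 5), 60, rep(30, 6)))
  class(d) <- c("cgr_depth", "data.frame")
  cs <- segment_cn(normalize_depth(d), min_bins = 3)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$cn, 2)
})

test_that("noise-free simulated profiles recover the CN vector exactly", {
  seg <- data.frame(start = c(0, 100000, 200000, 300000),
                    end = c(100000, 200000, 300000, 400000),
                    cn = c(2, 3, 1, 2))
  dp <- simulate_depth(seg, coverage = 30, bin = 10000, seed = 1)
  dp$mean_depth <- 30 * dp$mean_depth / dp$mean_depth  # exact, noise-free
  mids <- (dp$bin_start + dp$bin_end) / 2
  cn_truth <- vapply(mids, function(x)
    seg$cn[seg$start <= x & seg$end > x], numeric(1))
  dp$mean_depth <- 15 * cn_truth
  cs <- segment_cn(normalize_depth(dp))
  expect_equal(cs$cn, seg$cn)
  expect_equal(cs$start, seg$start)
})

test_that("Poisson noise at 30x keeps boundary error within one bin", {
  seg <- data.frame(start = c(0, 100000, 200000, 300000),
                    end = c(100000, 200000, 300000, 400000),
                    cn = c(2, 3, 1, 2))
  ok <- 0
  for (s in 1:40) {
    dp <- simulate_depth(seg, coverage = 30, bin = 10000, seed = s)
    cs <- segment_cn(normalize_depth(dp))
    if (identical(cs$cn, seg$cn) &&
        all(abs(cs$start - seg$start) <= 10000)) ok <- ok + 1
  }
  expect_gte(ok, 38)
})
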