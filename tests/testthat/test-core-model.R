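test_that("interval construction enforces invariants and lengths", {
  gi <- genomic_interval("chr21", 0, 10)
  expect_equal(interval_length(gi), 10)
  expect_error(genomic_interval("chr21", 5, 5), "empty")
  expect_error(genomic_interval("chr21", -1, 5), ">= 0")
})

test_that("1-based inclusive and half-open conversions round-trip", {
  for (se in list(c(1, 1), c(100, 200), c(23765839, 24915464))) {
    cc <- coords_from_1based(se[1], se[2])
    back <- coords_to_1based(cc$start, cc$end)
    expect_equal(c(back$start, back$end), se)
    expect_equal(cc$end - cc$start, se[2] - se[1] + 1)
  }
})

test_that("segment lengths match table arithmetic", {
  seg <- cgr_case("RD_P505")$segments
  expect_equal(segment_length(seg[seg$label == "D", ]), 1032304)
  expect_equal(segment_length(seg[seg$label == "L", ]), 3882480)
})

test_that("total_length sums dosage classes and handles empty selections", {
  p505 <- cgr_case("RD_P505")$segments
  expect_equal(total_length(p505, "DUP"), 10339425)
  expect_equal(mb(total_length(p505, "DUP")), 10.3)
  p01 <- cgr_case("RD_P01")$segments
  expect_equal(total_length(p01, "DEL"), 13443065)
  expect_equal(mb(total_length(p01, "DEL")), 13.4)
  expect_warning(z <- total_length(p01, "TELDEL"), "total is 0")
  expect_equal(z, 0)
})

test_that("reference adjacency uses half-open abutment", {
  a <- genomic_interval("chr21", 0, 10)
  expect_true(reference_adjacent(a, genomic_interval("chr21", 10, 20)))
  expect_false(reference_adjacent(a, genomic_interval("chr21", 11, 20)))
  expect_false(reference_adjacent(a, genomic_interval("chr22", 10, 20)))
  # abutting Table rows (1-based inclusive) become adjacent after conversion
  b <- coords_from_1based(532439, 2754000)
  c <- coords_from_1based(2754001, 3885184)
  expect_true(reference_adjacent(
    genomic_interval("chr21", b$start, b$end),
    genomic_interval("chr21", c$start, c$end)))
})

test_that("within each bundled case, segments of one dosage class never overlap", {
  for (cid in cgr_case_ids()) {
    seg <- cgr_case(cid)$segments
    for (d in unique(seg$dosage)) {
      s <- seg[seg$dosage == d, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1)
        expect_true(all(s$start[-1] >= s$end[-nrow(s)]),
                    info = paste(cid, d))
    }
  }
})

test_that("segment tables reject duplicate labels and unknown dosage", {
  expect_error(segments("c", c("A", "A"), "chr21", c(0, 10), c(5, 20), "DEL"),
               "duplicate")
  expect_error(segments("c", "A", "chr21", 0, 5, "GAIN"), "unknown dosage")
})

test_that("walk validation rejects reused or unbacked novel adjacencies", {
  w <- derivative_walk(data.frame(contig = "chrT",
                                  start = c(0, 5000, 2000),
                                  end = c(1000, 6000, 3000),
                                  inverted = FALSE, gap = FALSE))
  jn <- walk_junctions(w)
  expect_silent(validate_walk(w, jn))
  expect_error(validate_walk(w, jn[1, ]), "not backed")
  # duplicated use of one adjacency
  w2 <- derivative_walk(data.frame(contig = "chrT",
                                   start = c(0, 5000, 0, 5000),
                                   end = c(1000, 6000, 1000, 6000),
                                   inverted = FALSE, gap = FALSE))
  expect_error(validate_walk(w2, walk_junctions(w)), "more than once")
})
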