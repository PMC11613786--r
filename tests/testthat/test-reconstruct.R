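chr21_len <- 45090682

toy_tandem_graph <- function() {
  seg <- segments("toy", c("A", "B", "C"), "chrT",
                  c(0, 1000, 2000), c(1000, 2000, 3000),
                  c("NML", "DUP", "NML"))
  jn <- junctions("td", "chrT", 2000, "L", "chrT", 1001, "R")
  build_graph(seg, jn, cn = c(2, 3, 2), contig_length = 3000)
}

test_that("a tandem duplication graph assembles to A,B,B,C", {
  ws <- assemble_walk(toy_tandem_graph())
  expect_length(ws$walks, 1)
  expect_false(ws$ambiguous)
  w <- ws$walks[[1]]
  expect_false(w$circular)
  n <- normalize_walk(w)
  # normalised: [0,2000) + [1000,3000): the B copy appears twice
  expect_equal(nrow(walk_junctions(w)), 1)
  gi <- walk_to_graph_inputs(w, 3000)
  expect_equal(gi$cn, c(2, 3, 2))
})

test_that("junction endpoints off segment boundaries fail with nearest boundaries", {
  seg <- segments("toy", c("A", "B"), "chrT", c(0, 1000), c(1000, 2000),
                  c("NML", "NML"))
  jn <- junctions("x", "chrT", 999, "L", "chrT", 1500, "R")
  expect_error(build_graph(seg, jn, cn = c(2, 2), contig_length = 2000),
               "nearest boundaries")
  # with tolerance the endpoint snaps
  g <- build_graph(seg, junctions("x", "chrT", 999, "L", "chrT", 1001, "R"),
                   cn = c(2, 2), contig_length = 2000, tolerance = 1)
  expect_equal(g$junctions$pos1, 1000)
})

test_that("breakpoint counting follows the 2-per-SV convention with dedup", {
  expect_equal(count_breakpoints(cgr_case("RD_P01")$segments), 26)
  one_del <- segments("x", "A", "chrT", 100, 200, "DEL")
  expect_equal(count_breakpoints(one_del), 2)
  expect_equal(count_breakpoints(one_del[0, ]), 0)
  # abutting rows share a boundary: the bundled ring case has 8, not 12
  expect_equal(count_breakpoints(cgr_case("RD_P26")$segments), 8)
})

test_that("template switches count the walk's novel adjacencies", {
  ident <- derivative_walk(data.frame(contig = "chrT", start = 0, end = 1000,
                                      inverted = FALSE, gap = FALSE))
  expect_equal(count_template_switches(ident), 0)
  expect_equal(count_template_switches(
    cgr_case("RD_P505")$metadata$nomenclature_walk), 9)
  expect_gte(count_template_switches(
    cgr_case("RD_P01")$metadata$nomenclature_walk), 13)
})

test_that("ring detection reports circularity and lost terminal segments", {
  b <- cgr_case("RD_P26")
  w <- b$metadata$nomenclature_walk
  r <- detect_ring(w, b$segments)
  expect_true(r$ring)
  expect_setequal(r$lost_p, c("Tel", "B", "D"))
  expect_setequal(r$lost_q, c("F", "H"))
  lin <- derivative_walk(data.frame(contig = "chrT", start = 0, end = 1000,
                                    inverted = FALSE, gap = FALSE))
  expect_false(detect_ring(lin)$ring)
})

test_that("the ring case fixture assembles into the circular derivative", {
  b <- cgr_case("RD_P26")
  gi <- walk_to_graph_inputs(b$metadata$nomenclature_walk, chr21_len)
  g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                   contig_length = chr21_len)
  ws <- assemble_walk(g)
  expect_length(ws$walks, 1)
  w <- ws$walks[[1]]
  expect_true(w$circular)
  expect_true(walk_equal(w, b$metadata$nomenclature_walk))
  # segment G appears inverted, adjacent to p-arm sequence
  gseg <- b$segments[b$segments$label == "G", ]
  st <- normalize_walk(w)$steps
  gi_idx <- which(st$start == gseg$start & st$end == gseg$end & st$inverted)
  expect_length(gi_idx, 1)
  nb <- st[c(if (gi_idx > 1) gi_idx - 1 else nrow(st),
             if (gi_idx < nrow(st)) gi_idx + 1 else 1), ]
  expect_true(any(nb$start < 11.1e6))
})

test_that("the dup-only case assembles with the D,J,F-inverted cassette", {
  b <- cgr_case("RD_P505")
  truth <- b$metadata$nomenclature_walk
  gi <- walk_to_graph_inputs(truth, chr21_len)
  g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                   contig_length = chr21_len)
  ws <- assemble_walk(g)
  expect_true(any(vapply(ws$walks, walk_equal, TRUE, b = truth)))
  # the truth walk stitches D, J and inverted F consecutively
  nm <- normalize_walk(truth)$steps
  seg <- b$segments
  idx_of <- function(lab) {
    s <- seg[seg$label == lab, ]
    which(nm$start == s$start & nm$end == s$end)
  }
  d <- idx_of("D"); j <- idx_of("J"); f <- idx_of("F")
  expect_equal(j, d + 1)
  expect_equal(f, j + 1)
  expect_true(nm$inverted[f])
  expect_false(nm$inverted[d] || nm$inverted[j])
})

test_that("inconsistent evidence yields a structured explanation", {
  seg <- segments("toy", c("A", "B"), "chrT", c(0, 1000), c(1000, 2000),
                  c("NML", "DEL"))
  # junction pointing into the deleted segment: nothing can traverse it
  jn <- junctions("bad", "chrT", 1000, "L", "chrT", 1001, "R")
  g <- build_graph(seg, jn, cn = c(2, 1), contig_length = 2000)
  ws <- assemble_walk(g)
  expect_length(ws$walks, 0)
  expect_match(ws$reason, "inconsistent evidence")
})

test_that("assembly equals brute-force enumeration on random small graphs", {
  set.seed(7)
  n_ok <- 0
  for (i in 1:40) {
    w <- random_walk_case(L = 50000, ring = i %% 5 == 0, max_middle = 3)
    if (sum(w$steps$end - w$steps$start, na.rm = TRUE) > 200000) next
    gi <- walk_to_graph_inputs(w, 50000)
    if (nrow(gi$junctions) > 4 || sum(gi$cn - 1) > 7) next
    g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                     contig_length = 50000)
    ws <- assemble_walk(g)
    got <- sort(vapply(ws$walks, canonical_walk, character(1)))
    expected <- oracle_enumerate_walks(g)
    expect_equal(got, expected, info = paste("case", i))
    expect_true(canonical_walk(w) %in% got, info = paste("case", i))
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 20)
})

test_that("every returned walk conserves copy numbers and uses edges once", {
  set.seed(11)
  for (i in 1:15) {
    w <- random_walk_case(L = 50000, ring = i %% 4 == 0, max_middle = 3)
    gi <- walk_to_graph_inputs(w, 50000)
    g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                     contig_length = 50000)
    ws <- assemble_walk(g, max_walks = 50)
    for (sol in ws$walks) {
      gi2 <- walk_to_graph_inputs(sol, 50000)
      expect_equal(gi2$cn, gi$cn, info = paste("case", i))
      expect_silent(validate_walk(sol, gi$junctions))
    }
  }
})

test_that("simulated truth walks are recovered through the graph round trip", {
  set.seed(3)
  hits <- 0; total <- 0
  for (i in 1:60) {
    w <- random_walk_case(L = 80000, ring = i %% 6 == 0, max_middle = 3)
    gi <- walk_to_graph_inputs(w, 80000)
    g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                     contig_length = 80000)
    ws <- assemble_walk(g, max_walks = 2000)
    total <- total + 1
    if (any(vapply(ws$walks, walk_equal, TRUE, b = w))) hits <- hits + 1
  }
  expect_equal(hits, total)
})
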