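test_that("toy references are reproducible and bounded", {
  r1 <- make_reference(50000, seed = 1)
  r2 <- make_reference(50000, seed = 1)
  expect_identical(as.character(r1), as.character(r2))
  expect_error(make_reference(100, seed = 1), "too short")
})

test_that("planted repeat pairs share a detectable alignment", {
  r <- make_reference(50000, seed = 3, repeat_pairs = 1)
  # the planted 300-nt block occurs twice: self-alignment beyond the
  # trivial diagonal
  s <- as.character(r[[1]])
  found <- FALSE
  for (i in seq(1, 49900, by = 100)) {
    block <- substr(s, i, i + 99)
    hits <- gregexpr(block, s, fixed = TRUE)[[1]]
    if (length(hits) > 1) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("the identity walk reproduces the reference", {
  ref <- make_reference(20000, seed = 2, contig = "chrS")
  w <- derivative_walk(data.frame(contig = "chrS", start = 0, end = 20000,
                                  inverted = FALSE, gap = FALSE))
  sim <- simulate_derivative(ref, w)
  expect_identical(as.character(sim$derivative[[1]]),
                   as.character(sim$reference[[1]]))
})

test_that("a tandem duplication adds exactly the duplicated length", {
  ref <- make_reference(20000, seed = 2, contig = "chrS")
  w <- derivative_walk(data.frame(contig = "chrS",
                                  start = c(0, 1000, 2000),
                                  end = c(2000, 2000, 20000),
                                  inverted = FALSE, gap = FALSE))
  sim <- simulate_derivative(ref, w)
  expect_equal(Biostrings::width(sim$derivative), 21000)
})

test_that("junction parameter validation catches infeasible requests", {
  ref <- make_reference(20000, seed = 2, contig = "chrS")
  w <- derivative_walk(data.frame(contig = "chrS",
                                  start = c(0, 12000), end = c(5000, 20000),
                                  inverted = FALSE, gap = FALSE))
  expect_error(simulate_derivative(ref, w, data.frame(m = 200, ins_len = 0)),
               "infeasible")
  expect_error(simulate_derivative(ref, w, data.frame(m = 5, ins_len = 5)),
               "mutually exclusive")
  expect_error(simulate_derivative(ref, w, data.frame(m = c(0, 0))), "rows")
})

test_that("trio simulation is deterministic and respects the quality floor", {
  seg <- segments("t", c("A", "B"), "chrT", c(0, 50000), c(20000, 80000),
                  c("DUP", "NML"))
  t1 <- simulate_trio_snvs(seg, "PATERNAL", 100, seed = 9)
  t2 <- simulate_trio_snvs(seg, "PATERNAL", 100, seed = 9)
  expect_identical(t1, t2)
  # noise-free deletion: the remaining allele is fully the unaffected one
  del <- segments("t", "A", "chrT", 0, 50000, "DEL")
  td <- simulate_trio_snvs(del, "PATERNAL", 100, seed = 1, low_qual_frac = 0)
  s <- trio_sites(td$child, td$father, td$mother)
  att <- mapply(cgrwalk:::attribute_site, s$informative, s$gt_child)
  expect_true(all(att == "maternal"))
})

test_that("depth simulation is reproducible and scales with copy number", {
  seg <- data.frame(start = c(0, 100000), end = c(100000, 200000),
                    cn = c(2, 4))
  d1 <- simulate_depth(seg, coverage = 30, seed = 4)
  d2 <- simulate_depth(seg, coverage = 30, seed = 4)
  expect_identical(d1, d2)
  m2 <- mean(d1$mean_depth[d1$bin_start < 100000])
  m4 <- mean(d1$mean_depth[d1$bin_start >= 100000])
  expect_lt(abs(m2 - 30), 3)
  expect_lt(abs(m4 - 60), 4)
})

test_that("scenario artefacts are written and re-readable with matching truth", {
  dir <- tempfile("ring21")
  sc <- cgr_scenario("ring21", seed = 5, out_dir = dir)
  expect_true(all(file.exists(unlist(sc$files))))

  back <- read_junctions_bedpe(sc$files$bedpe)
  expect_equal(nrow(back), nrow(sc$sim$junctions))
  expect_equal(back$orientation, sc$sim$junctions$orientation)
  expect_equal(back$seq, sc$sim$junctions$seq)

  vj <- read_vcf_bnd(sc$files$breakends)
  key <- function(j) sort(paste(j$pos1, j$side1, j$pos2, j$side2))
  expect_equal(key(vj), key(back))

  seg <- read_segment_table(sc$files$segments, "ring21", contig = "chrS")
  expect_equal(nrow(seg), nrow(sc$case_segments))

  dp <- read_depth_tsv(sc$files$depth)
  expect_equal(nrow(dp), nrow(sc$depth))

  ref <- read_fasta(sc$files$reference)
  expect_identical(as.character(ref), as.character(sc$sim$reference))
})

test_that("the 13-SV scenario emits one unpaired breakend on purpose", {
  dir <- tempfile("mixed")
  sc <- cgr_scenario("mixed_delsdups13", seed = 6, out_dir = dir)
  expect_warning(vj <- read_vcf_bnd(sc$files$breakends), "unpaired")
  expect_equal(nrow(vj), nrow(sc$sim$junctions) - 1)
  # the truth BEDPE stays complete
  expect_equal(nrow(read_junctions_bedpe(sc$files$bedpe)),
               nrow(sc$sim$junctions))
})
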