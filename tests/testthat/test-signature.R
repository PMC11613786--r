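test_that("microhomology counts shared junction-flanking bases on both sides", {
  # worked example: flank_b's first 3 bases continue identically in the
  # reference past the first breakpoint
  m <- microhomology(flank_a = "GATCCA", flank_b = "CCAGTT",
                     ref_beyond_a = "CCACGG", ref_beyond_b = "TTTTTT")
  expect_equal(as.integer(m), 3)
  expect_equal(attr(m, "k_right"), 3)
  expect_equal(attr(m, "k_left"), 0)
  expect_equal(as.integer(
    microhomology("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT")), 0)
  # 79 identical terminal bases on both sides
  rep79 <- paste(rep("ACGT", 20), collapse = "")
  rep79 <- substr(rep79, 1, 79)
  m79 <- microhomology(flank_a = paste0("TTTTT", rep79),
                       flank_b = "GGGGGGGGGG",
                       ref_beyond_a = "CAGGGGGGGG",
                       ref_beyond_b = paste0("AAAAA", rep79))
  expect_equal(as.integer(m79), 79)
})

test_that("N runs at the junction truncate the comparison and are flagged", {
  m <- microhomology("GATCCA", "CCNGTT", "CCNGTT", "TTTTTT")
  expect_equal(as.integer(m), 2)
  expect_true(attr(m, "n_truncated"))
  expect_error(microhomology("GATXCA", "CC", "CC", "TT"), "ACGTN")
})

test_that("microhomology equals the brute-force breakpoint-placement oracle", {
  set.seed(101)
  for (i in 1:300) {
    cs <- random_junction_case(m = sample(0:79, 1))
    got <- as.integer(microhomology(cs$flank_a, cs$flank_b,
                                    cs$ref_beyond_a, cs$ref_beyond_b))
    oracle <- oracle_microhomology(cs$flank_a, cs$flank_b,
                                   cs$ref_beyond_a, cs$ref_beyond_b)
    expect_equal(got, oracle, info = paste("case", i))
    expect_equal(got, cs$m, info = paste("case", i))
  }
})

test_that("planted microhomology is recovered exactly for every m in 0..79", {
  ref <- make_reference(20000, seed = 5, contig = "chrS")
  for (m in c(0:10, seq(12, 78, by = 6), 79)) {
    w <- derivative_walk(data.frame(contig = "chrS",
                                    start = c(0, 12000), end = c(5000, 20000),
                                    inverted = FALSE, gap = FALSE))
    sim <- simulate_derivative(ref, w, data.frame(m = m, ins_len = 0,
                                                  ins_templated = FALSE))
    sig <- junction_signatures(sim$junctions, sim$reference)
    expect_equal(sig$microhomology_len, m, info = paste("m =", m))
    expect_equal(sig$insertion_len, 0L)
    expect_equal(sig$blunt, m == 0)
  }
})

test_that("insertions are extracted and classified by templated origin", {
  ref <- make_reference(20000, seed = 9, contig = "chrS")
  w <- derivative_walk(data.frame(contig = "chrS",
                                  start = c(0, 12000), end = c(5000, 20000),
                                  inverted = FALSE, gap = FALSE))
  sim_nt <- simulate_derivative(ref, w, data.frame(m = 0, ins_len = 4,
                                                   ins_templated = FALSE))
  sig_nt <- junction_signatures(sim_nt$junctions, sim_nt$reference)
  expect_equal(sig_nt$insertion_len, 4L)
  expect_equal(sig_nt$insertion_origin, "NONTEMPLATED")
  expect_equal(sig_nt$microhomology_len, 0L)
  expect_false(sig_nt$blunt)

  sim_t <- simulate_derivative(ref, w, data.frame(m = 0, ins_len = 40,
                                                  ins_templated = TRUE))
  sig_t <- junction_signatures(sim_t$junctions, sim_t$reference)
  expect_equal(sig_t$insertion_len, 40L)
  expect_equal(sig_t$insertion_origin, "TEMPLATED")

  sim_0 <- simulate_derivative(ref, w)
  sig_0 <- junction_signatures(sim_0$junctions, sim_0$reference)
  expect_equal(sig_0$insertion_origin, "NONE")
  expect_true(sig_0$blunt)
})

test_that("a junction sequence that misses a flank anchor is rejected", {
  expect_error(classify_insertion(rand_dna(60), rand_dna(150), rand_dna(150)),
               "does not span")
})

test_that("random far-away inserts are almost never called templated", {
  set.seed(77)
  ref <- make_reference(30000, seed = 77, contig = "chrS")
  w <- derivative_walk(data.frame(contig = "chrS",
                                  start = c(0, 20000), end = c(8000, 30000),
                                  inverted = FALSE, gap = FALSE))
  sim <- simulate_derivative(ref, w)
  fl <- cgrwalk:::junction_flanks("chrS", 8000, "L", "chrS", 20001, "R",
                                  sim$reference)
  wins <- list(cgrwalk:::window_around(sim$reference, "chrS", 8000, 2000),
               cgrwalk:::window_around(sim$reference, "chrS", 20001, 2000))
  fp <- 0; trials <- 400
  for (i in seq_len(trials)) {
    ins <- rand_dna(sample(10:60, 1))
    js <- paste0(substr(fl$flank_a, 100, 150), ins,
                 substr(fl$flank_b, 1, 50))
    r <- classify_insertion(js, fl$flank_a, fl$flank_b, search_windows = wins)
    if (r$origin == "TEMPLATED") fp <- fp + 1
  }
  expect_lt(fp / trials, 0.01)
})

test_that("mechanism heuristics fire on the intended patterns", {
  # replicative: many gains, microhomology-rich junctions
  sc_like <- data.frame(junction_id = paste0("j", 1:7),
                        microhomology_len = c(1, 3, 7, 21, 40, 79, 0),
                        insertion_len = c(0, 0, 0, 0, 0, 0, 4),
                        insertion_origin = c(rep("NONE", 6), "NONTEMPLATED"),
                        blunt = FALSE, stringsAsFactors = FALSE)
  dup_walk <- cgr_case("RD_P505")$metadata$nomenclature_walk
  mc <- call_mechanism(sc_like, dup_walk)
  expect_equal(mc$call, "CHROMOANASYNTHESIS")
  expect_true(length(mc$evidence) >= 2)

  ring_walk <- cgr_case("RD_P26")$metadata$nomenclature_walk
  ring_sig <- data.frame(junction_id = paste0("j", 1:4),
                         microhomology_len = c(5, 0, 2, 0),
                         insertion_len = c(0, 20, 0, 0),
                         insertion_origin = c("NONE", "TEMPLATED", "NONE",
                                              "NONE"),
                         blunt = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(call_mechanism(ring_sig, ring_walk)$call, "ALU_MEDIATED_RING")

  one_del <- derivative_walk(data.frame(contig = "chrT",
                                        start = c(0, 5000),
                                        end = c(1000, 10000),
                                        inverted = FALSE, gap = FALSE))
  blunt_sig <- data.frame(junction_id = "j1", microhomology_len = 0L,
                          insertion_len = 0L, insertion_origin = "NONE",
                          blunt = TRUE)
  expect_equal(call_mechanism(blunt_sig, one_del)$call, "SIMPLE_NHEJ_LIKE")
})
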