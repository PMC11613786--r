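test_that("a segments-plus-junctions case reports totals without phasing", {
  rep <- run_case(cgr_case("RD_P505"))
  expect_equal(rep$case_id, "RD_P505")
  expect_equal(rep$segments$DUP$n, 6)
  expect_equal(mb(rep$segments$DUP$total_nt), 10.3)
  expect_equal(rep$walk$junctions, 9)
  expect_null(rep$phasing)
  expect_false(rep$walk$ring)
  expect_true("reconstruct" %in% rep$stages_run)
})

test_that("an empty bundle is an error", {
  seg0 <- cgr_case("RD_P505")$segments[0, ]
  expect_error(run_case(case_bundle("empty", seg0)), "empty bundle")
  expect_error(run_case(list()), "cgr_bundle")
})

test_that("report JSON is byte-identical across runs", {
  rep <- run_case(cgr_case("RD_P26"))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_report(rep, f1)
  write_report(run_case(cgr_case("RD_P26")), f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_equal(parsed$walk$junctions, 4)
  expect_true(parsed$walk$ring)
})

test_that("a full scenario report includes phasing and copy number", {
  dir <- tempfile("sc")
  sc <- cgr_scenario("ring21", seed = 8, out_dir = dir)
  expr <- walk_to_seq(sc$truth_walk, sc$contig_length)
  bundle <- case_bundle("ring21_sim", sc$phasing_segments,
                        sc$sim$junctions, karyotype_string = expr,
                        metadata = list(nomenclature_walk = sc$truth_walk,
                                        contig_length = sc$contig_length))
  rep <- run_case(bundle, fasta = sc$sim$reference,
                  trio = list(child = sc$files$child,
                              father = sc$files$father,
                              mother = sc$files$mother),
                  depth = sc$depth)
  expect_true(rep$walk$ring)
  expect_equal(rep$phasing$origin_call, "MATERNAL")
  expect_equal(rep$signatures$n_resolved, 4)
  expect_equal(rep$mechanism$call, "ALU_MEDIATED_RING")
  expect_true(any(rep$copy_number$cn == 1))
  expect_setequal(rep$stages_run, c("segments", "reconstruct", "signature",
                                    "phasing", "copy_number"))
})

test_that("derivative plots are written as non-empty files", {
  f <- tempfile(fileext = ".png")
  plot_derivative(cgr_case("RD_P26")$metadata$nomenclature_walk, f,
                  contig_length = 45090682)
  expect_true(file.exists(f))
  expect_gt(file.size(f), 1000)
  f2 <- tempfile(fileext = ".png")
  ident <- derivative_walk(data.frame(contig = "chrT", start = 0, end = 1000,
                                      inverted = FALSE, gap = FALSE))
  plot_derivative(ident, f2)
  expect_gt(file.size(f2), 1000)
})
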