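chr21_len <- 45090682

case_string <- function(case_id) {
  ks <- read.delim(system.file("extdata", "karyotypes.tsv",
                               package = "cgrwalk"))
  ks$karyotype[ks$case_id == case_id]
}

test_that("the identity expression parses to a single untouched walk", {
  e <- parse_seq("NC_060945.1:g.[pter_qter]", contig_length = 1000)
  expect_length(e$ast$items, 1)
  w <- seq_to_walk(e, 1000)
  expect_equal(nrow(w$steps), 1)
  expect_false(w$circular)
  expect_equal(count_novel_adjacencies(w), 0)
})

test_that("the ring case string parses to two pter/qter-anchored edits", {
  e <- parse_seq(case_string("RD_P26"), contig_length = chr21_len)
  expect_length(e$ast$items, 2)
  expect_equal(vapply(e$ast$items, `[[`, "", "kind"),
               c("delins", "delins"))
  expect_equal(e$ast$seps, "::")
  expect_length(e$diagnostics, 0)
  w <- seq_to_walk(e)
  expect_true(w$circular)
  expect_equal(count_novel_adjacencies(w), 4)
})

test_that("the 13-SV case string parses with 11 replacement elements, one unknown", {
  e <- parse_seq(case_string("RD_P01"), contig_length = chr21_len)
  expect_length(e$ast$items, 2)
  repl2 <- e$ast$items[[2]]$repl
  expect_length(repl2, 11)
  kinds <- vapply(repl2, function(x) {
    if (x$kind == "range" && !is.null(x$end) && x$end$kind == "unknown")
      "open_range" else x$kind
  }, "")
  expect_equal(sum(kinds == "open_range"), 1)
  w <- seq_to_walk(e)
  expect_equal(count_novel_adjacencies(w), 15)
  expect_equal(sum(w$steps$gap), 1)
})

test_that("lenient mode repairs the two printed defects of the dup-only case", {
  e <- parse_seq(case_string("RD_P505"), contig_length = chr21_len)
  expect_length(e$diagnostics, 2)
  expect_match(e$diagnostics[1], "':'")
  expect_match(e$diagnostics[2], "surplus digit")
  w <- seq_to_walk(e)
  expect_equal(count_novel_adjacencies(w), 9)
  expect_error(parse_seq(case_string("RD_P505"), contig_length = chr21_len,
                         lenient = FALSE), "':'|exceeds")
})

test_that("unbalanced brackets are a hard error with an offset", {
  expect_error(parse_seq("g.[100_200delins[300_400", contig_length = 1000),
               "offset")
})

test_that("a toy delins resolves to flank-insert-flank with two junctions", {
  e <- parse_seq("g.[100_200delins[400_500inv]]", contig_length = 1000)
  w <- seq_to_walk(e)
  expect_equal(nrow(w$steps), 3)
  expect_equal(count_novel_adjacencies(w), 2)
  expect_equal(w$steps$inverted, c(FALSE, TRUE, FALSE))
  expect_equal(w$steps$start + 1, c(1, 400, 201))
  expect_equal(w$steps$end, c(99, 500, 1000))
})

test_that("uncertain positions resolve to interval midpoints", {
  e <- parse_seq("g.[pter_(100_200)delins[500_600]]", contig_length = 1000)
  w <- seq_to_walk(e)
  # deleted target ends at the midpoint 150; the flank resumes at 151
  expect_equal(w$steps$start + 1, c(500, 151))
})

test_that("emission is the inverse of parsing on random walks", {
  set.seed(42)
  for (i in 1:60) {
    w <- random_walk_case(L = 100000, ring = i %% 4 == 0)
    s <- walk_to_seq(w, 100000)
    w2 <- seq_to_walk(parse_seq(s, contig_length = 100000), 100000,
                      contig = "chrT")
    expect_true(walk_equal(w, w2), info = paste("case", i, s))
  }
})

test_that("identity and gap walks emit canonical strings", {
  w <- derivative_walk(data.frame(contig = "chrT", start = 0, end = 1000,
                                  inverted = FALSE, gap = FALSE))
  expect_equal(walk_to_seq(w, 1000), "g.[pter_qter]")
  wg <- derivative_walk(data.frame(contig = "chrT",
                                   start = c(0, 5000, NA, 8000),
                                   end = c(1000, 6000, NA, 10000),
                                   inverted = FALSE,
                                   gap = c(FALSE, FALSE, TRUE, FALSE)))
  expect_match(walk_to_seq(wg, 10000), "?", fixed = TRUE)
})

test_that("the emitted ring string is structurally equivalent to the printed one", {
  b <- cgr_case("RD_P26")
  w <- b$metadata$nomenclature_walk
  s <- walk_to_seq(w, chr21_len, accession = "NC_060945.1")
  e1 <- parse_seq(s, contig_length = chr21_len)
  e2 <- parse_seq(case_string("RD_P26"), contig_length = chr21_len)
  expect_true(ast_equivalent(e1, e2, contig_length = chr21_len))
})

test_that("nomenclature and graph reconstruction agree on junction counts", {
  for (cid in c("RD_P26", "RD_P01")) {
    b <- cgr_case(cid)
    w <- b$metadata$nomenclature_walk
    expect_equal(count_novel_adjacencies(w), nrow(b$junctions), info = cid)
  }
  # and for the ring case the assembled walk carries the same count
  b <- cgr_case("RD_P26")
  gi <- walk_to_graph_inputs(b$metadata$nomenclature_walk, chr21_len)
  g <- build_graph(gi$segments, gi$junctions, cn = gi$cn,
                   contig_length = chr21_len)
  ws <- assemble_walk(g)
  expect_equal(count_novel_adjacencies(ws$walks[[1]]), 4)
})
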