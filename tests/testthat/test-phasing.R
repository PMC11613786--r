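test_that("informative-site attribution follows Mendelian trio logic", {
  expect_equal(cgrwalk:::attribute_site("paternal", "0/1"), "paternal")
  expect_equal(cgrwalk:::attribute_site("maternal", "0/1"), "maternal")
  # hemizygous child: the carried allele's parent
  expect_equal(cgrwalk:::attribute_site("paternal", "1/1"), "paternal")
  expect_equal(cgrwalk:::attribute_site("paternal", "0/0"), "maternal")
  expect_true(is.na(cgrwalk:::attribute_site("uninformative", "0/1")))
})

test_that("hemizygous deletion segments tally the remaining allele's parent", {
  seg <- segments("t", c("A", "B"), "chrT", c(0, 50000), c(20000, 80000),
                  c("DEL", "NML"))
  tr <- simulate_trio_snvs(seg, "PATERNAL", sites_per_segment = 100, seed = 2,
                           low_qual_frac = 0)
  s <- trio_sites(tr$child, tr$father, tr$mother)
  fr <- segment_allele_fractions(s, seg)
  # paternal-origin deletion: every remaining allele is maternal
  expect_equal(fr$maternal_fraction[fr$label == "A"], 1)
  expect_gt(fr$n_informative[fr$label == "B"], 0)
  expect_lt(abs(fr$paternal_fraction[fr$label == "B"] - 0.5), 0.2)
})

test_that("diploid fractions converge to one half", {
  seg <- segments("t", "N", "chrT", 0, 200000, "NML")
  set.seed(4)
  fracs <- replicate(20, {
    tr <- simulate_trio_snvs(seg, "PATERNAL", sites_per_segment = 200,
                             low_qual_frac = 0)
    s <- trio_sites(tr$child, tr$father, tr$mother)
    segment_allele_fractions(s, seg)$paternal_fraction
  })
  se <- sqrt(0.25 / 200)
  expect_true(all(abs(fracs - 0.5) <= 3 * se + 1e-9))
})

test_that("segments without informative sites are excluded from the test", {
  seg <- segments("t", c("A", "B"), "chrT", c(0, 50000), c(20000, 80000),
                  c("DUP", "NML"))
  sites <- data.frame(chrom = "chrT", pos = c(60000, 60001), qual = 50,
                      gt_child = "0/1", gt_father = c("1/1", "0/0"),
                      gt_mother = c("0/0", "1/1"),
                      informative = c("paternal", "maternal"))
  fr <- segment_allele_fractions(sites, seg)
  expect_true(is.na(fr$paternal_fraction[fr$label == "A"]))
  ph <- phase_case(sites, seg)
  expect_equal(ph$origin_call, "INCONCLUSIVE")
  expect_match(ph$test$note, "fewer than 2")
})

test_that("the Welch test degenerates sensibly on identical groups", {
  r <- origin_test(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(call_origin(0.5, 0.5, r$p), "INCONCLUSIVE")
  expect_equal(call_origin(0.7, 0.5, 0.5), "INCONCLUSIVE")
  expect_equal(call_origin(0.7, 0.5, 0.01), "PATERNAL")
  expect_equal(call_origin(0.3, 0.5, 0.01), "MATERNAL")
})

test_that("paternal duplications and maternal deletions phase correctly", {
  # six rearranged segments against six diploid controls, the scale of
  # the duplication-only case
  starts <- seq(0, by = 30000, length.out = 12)
  dup_seg <- segments("t", LETTERS[1:12], "chrT", starts, starts + 20000,
                      rep(c("DUP", "NML"), 6))
  del_seg <- dup_seg
  del_seg$dosage <- rep(c("DEL", "NML"), 6)
  n_pat <- 0; n_mat <- 0
  for (s in 1:20) {
    trd <- simulate_trio_snvs(dup_seg, "PATERNAL", 200, seed = s)
    ph <- phase_case(trio_sites(trd$child, trd$father, trd$mother), dup_seg)
    if (ph$origin_call == "PATERNAL" && ph$test$p < 0.05) n_pat <- n_pat + 1
    trm <- simulate_trio_snvs(del_seg, "MATERNAL", 200, seed = 500 + s)
    phm <- phase_case(trio_sites(trm$child, trm$father, trm$mother), del_seg)
    if (phm$origin_call == "MATERNAL") n_mat <- n_mat + 1
  }
  expect_gte(n_pat, 19)
  expect_gte(n_mat, 19)
})
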