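# Random derivative-walk generator used by the round-trip and
# property-style tests. Coordinates are drawn on a 1 kb grid of a toy
# contig so breakends stay well separated.

random_walk_case <- function(L = 100000, ring = FALSE, max_middle = 4) {
  grid <- seq(2000, L - 2000, by = 1000)
  pick1 <- function(x) if (length(x) == 1) x else sample(x, 1)
  rand_iv <- function() {
    a <- pick1(grid[-length(grid)])
    b <- pick1(grid[grid > a])
    c(a, b)
  }
  # a stable linear derivative keeps at least one telomere (a derivative
  # missing both would close into a ring under the emission convention)
  has_pter <- !ring && runif(1) < 0.7
  has_qter <- !ring && runif(1) < 0.7
  if (!ring && !has_pter && !has_qter) has_qter <- TRUE
  steps <- list()
  if (has_pter) {
    c1 <- sample(grid, 1)
    steps[[1]] <- data.frame(contig = "chrT", start = 0, end = c1,
                             inverted = FALSE, gap = FALSE)
  }
  n_mid <- sample.int(max_middle, 1)
  for (k in seq_len(n_mid)) {
    iv <- rand_iv()
    steps[[length(steps) + 1L]] <-
      data.frame(contig = "chrT", start = iv[1], end = iv[2],
                 inverted = runif(1) < 0.5, gap = FALSE)
  }
  if (has_qter) {
    c2 <- sample(grid, 1)
    steps[[length(steps) + 1L]] <-
      data.frame(contig = "chrT", start = c2, end = L,
                 inverted = FALSE, gap = FALSE)
  }
  st <- do.call(rbind, steps)
  if (ring && all(st$inverted)) st$inverted[1] <- FALSE
  w <- derivative_walk(st, circular = ring)
  normalize_walk(w)
}

# write a trio of minimal VCFs for a simulated trio and read them back
trio_sites_via_files <- function(trio, dir = tempfile("trio")) {
  dir.create(dir, showWarnings = FALSE)
  write_snv_vcf(trio$child, file.path(dir, "c.vcf"), "CHILD")
  write_snv_vcf(trio$father, file.path(dir, "f.vcf"), "FATHER")
  write_snv_vcf(trio$mother, file.path(dir, "m.vcf"), "MOTHER")
  read_phased_snvs(file.path(dir, "c.vcf"), file.path(dir, "f.vcf"),
                   file.path(dir, "m.vcf"))
}
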