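# Independent oracles and random-case generators shared by the suite.

# Brute-force microhomology oracle: enumerate every breakpoint placement
# around the nominal junction and count the consistent ones. A split
# shifted by d (d > 0: into ref_beyond_a; d < 0: into flank_a) is
# consistent iff the derivative junction sequence is still explained by
# (copy A up to split, copy B from split).
oracle_microhomology <- function(flank_a, flank_b, ref_beyond_a, ref_beyond_b) {
  ok <- function(d) {
    if (d > 0) {
      if (d > nchar(ref_beyond_a) || d > nchar(flank_b)) return(FALSE)
      substr(flank_b, 1, d) == substr(ref_beyond_a, 1, d)
    } else if (d < 0) {
      k <- -d
      if (k > nchar(flank_a) || k > nchar(ref_beyond_b)) return(FALSE)
      substr(flank_a, nchar(flank_a) - k + 1, nchar(flank_a)) ==
        substr(ref_beyond_b, nchar(ref_beyond_b) - k + 1, nchar(ref_beyond_b))
    } else TRUE
  }
  # consistent placements form a contiguous run around 0
  lo <- 0
  while (ok(lo - 1)) lo <- lo - 1
  hi <- 0
  while (ok(hi + 1)) hi <- hi + 1
  hi - lo
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Construct a random junction with a known-by-construction microhomology
# m: both reference copies share exactly m bases at the join.
random_junction_case <- function(m, w = 150) {
  flank_a <- rand_dna(w)
  flank_b <- rand_dna(w)
  ref_beyond_a <- rand_dna(w)
  ref_beyond_b <- rand_dna(w)
  split <- sample(0:m, 1)  # place the nominal breakpoint inside the run
  # shared run S of length m lies across the junction: the last `split`
  # bases of flank_a and first (m - split) bases of flank_b; both copies
  # carry it
  if (split > 0) {
    s_left <- substr(flank_a, w - split + 1, w)
    substr(ref_beyond_b, w - split + 1, w) <- s_left
  }
  if (m - split > 0) {
    s_right <- substr(flank_b, 1, m - split)
    substr(ref_beyond_a, 1, m - split) <- s_right
  }
  # force mismatches just outside the run (`avoid` is the single base the
  # position must differ from)
  force_diff <- function(s, i, avoid) {
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), avoid)[1]
    s
  }
  if (w - split >= 1)
    ref_beyond_b <- force_diff(ref_beyond_b, w - split,
                               substr(flank_a, w - split, w - split))
  if (m - split + 1 <= w)
    ref_beyond_a <- force_diff(ref_beyond_a, m - split + 1,
                               substr(flank_b, m - split + 1, m - split + 1))
  list(flank_a = flank_a, flank_b = flank_b,
       ref_beyond_a = ref_beyond_a, ref_beyond_b = ref_beyond_b, m = m)
}

# Brute-force derivative-walk enumeration for small graphs: every
# ordering of the copy multiset with every orientation, checked against
# the join rules; acceptance mirrors the assembler's telomere/ring
# conditions. Returns the set of canonical serialisations.
oracle_enumerate_walks <- function(graph) {
  at <- graph$segments
  visits <- at$cn - 1
  ej <- graph$junctions
  L <- graph$contig_length
  results <- character()

  exit_be <- function(seg, inv) {
    if (!inv) c(at$end[seg], "L") else c(at$start[seg] + 1, "R")
  }
  entry_be <- function(seg, inv) {
    if (!inv) c(at$start[seg] + 1, "R") else c(at$end[seg], "L")
  }
  edge_match <- function(e, be1, be2) {
    (ej$pos1[e] == as.numeric(be1[1]) && ej$side1[e] == be1[2] &&
       ej$pos2[e] == as.numeric(be2[1]) && ej$side2[e] == be2[2]) ||
      (ej$pos2[e] == as.numeric(be1[1]) && ej$side2[e] == be1[2] &&
         ej$pos1[e] == as.numeric(be2[1]) && ej$side1[e] == be2[2])
  }
  ref_join <- function(be1, be2) {
    (be1[2] == "L" && be2[2] == "R" &&
       as.numeric(be1[1]) + 1 == as.numeric(be2[1])) ||
      (be1[2] == "R" && be2[2] == "L" &&
         as.numeric(be1[1]) - 1 == as.numeric(be2[1]))
  }
  mk <- function(path, circular) {
    segs <- vapply(path, `[[`, 0, 1)
    invs <- vapply(path, function(p) as.logical(p[[2]]), TRUE)
    derivative_walk(data.frame(contig = graph$contig, start = at$start[segs],
                               end = at$end[segs], inverted = invs,
                               gap = FALSE), circular = circular)
  }
  recurse <- function(path, visits, used) {
    n <- length(path)
    if (n > 0 && all(visits == 0)) {
      last <- path[[n]]
      cur <- exit_be(last[[1]], as.logical(last[[2]]))
      first <- path[[1]]
      started_pter <- first[[1]] == 1 && !as.logical(first[[2]])
      at_qter <- as.numeric(cur[1]) == L && cur[2] == "L"
      if (all(used) && (started_pter || at_qter))
        results <<- c(results, canonical_walk(mk(path, FALSE)))
      ent0 <- entry_be(first[[1]], as.logical(first[[2]]))
      if (ref_join(cur, ent0) && all(used))
        results <<- c(results, canonical_walk(mk(path, TRUE)))
      if (!all(used) && sum(!used) == 1) {
        e <- which(!used)
        if (edge_match(e, cur, ent0))
          results <<- c(results, canonical_walk(mk(path, TRUE)))
      }
    }
    for (s in which(visits > 0)) {
      for (inv in c(FALSE, TRUE)) {
        if (n > 0) {
          last <- path[[n]]
          cur <- exit_be(last[[1]], as.logical(last[[2]]))
          ent <- entry_be(s, inv)
          if (ref_join(cur, ent)) {
            v2 <- visits; v2[s] <- v2[s] - 1
            recurse(c(path, list(list(s, inv))), v2, used)
          }
          for (e in which(!used)) {
            if (edge_match(e, cur, ent)) {
              v2 <- visits; v2[s] <- v2[s] - 1
              u2 <- used; u2[e] <- TRUE
              recurse(c(path, list(list(s, inv))), v2, u2)
            }
          }
        } else {
          v2 <- visits; v2[s] <- v2[s] - 1
          recurse(list(list(s, inv)), v2, used)
        }
      }
    }
  }
  recurse(list(), visits, rep(FALSE, nrow(ej)))
  sort(unique(results))
}
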