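# Junction microarchitecture: microhomology, blunt joins, nontemplated
# and templated insertions, and case-level mechanism heuristics.
#
# Microhomology is the run of bases flanking a junction that is identical
# in both reference copies: within it the true breakpoint cannot be
# placed. With flank_a the derivative sequence ending at bp1, flank_b the
# derivative sequence starting at bp2, ref_beyond_a the reference
# continuation past bp1 and ref_beyond_b the reference sequence
# immediately preceding bp2 (all in derivative orientation), the
# microhomology length is k_left + k_right where
#   k_right = longest prefix of flank_b matching ref_beyond_a,
#   k_left  = longest suffix of flank_a matching the suffix of ref_beyond_b.

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv | av == "N" | bv == "N")
  if (!length(d)) n else d[1] - 1L
}

rev_chars <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")

common_suffix_len <- function(a, b) common_prefix_len(rev_chars(a), rev_chars(b))

#' Microhomology length at a junction
#'
#' All four sequences are uppercase ACGTN in derivative orientation.
#' Runs of `N` at the junction stop the comparison (the result is then
#' computed on the non-N part and flagged via the `"n_truncated"`
#' attribute).
#'
#' @param flank_a Derivative sequence ending at the first breakpoint.
#' @param flank_b Derivative sequence starting at the second breakpoint.
#' @param ref_beyond_a Reference continuation past the first breakpoint
#'   (what would have followed `flank_a` without the rearrangement).
#' @param ref_beyond_b Reference sequence immediately preceding the
#'   second breakpoint.
#' @return Integer microhomology length (`k_left + k_right`, with both
#'   components as attributes).
#' @export
microhomology <- function(flank_a, flank_b, ref_beyond_a, ref_beyond_b) {
  seqs <- toupper(c(flank_a, flank_b, ref_beyond_a, ref_beyond_b))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequences must be ACGTN", call. = FALSE)
  k_right <- common_prefix_len(seqs[2], seqs[3])
  k_left <- common_suffix_len(seqs[1], seqs[4])
  n_trunc <- any(vapply(seqs, function(s) grepl("N", s), TRUE))
  structure(k_left + k_right, k_left = k_left, k_right = k_right,
            n_truncated = n_trunc)
}

# Extract the four junction-context sequences from the reference for a
# canonical junction row (breakend = pos 1-based + retained side).
junction_flanks <- function(contig1, pos1, side1, contig2, pos2, side2,
                            ref, window = 150) {
  seq_of <- function(contig, from, to, revcomp = FALSE) {
    len <- Biostrings::width(ref[contig])
    from <- max(1, from); to <- min(len, to)
    if (from > to) return("")
    s <- as.character(Biostrings::subseq(ref[[contig]], from, to))
    if (revcomp)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  if (side1 == "L") {
    flank_a <- seq_of(contig1, pos1 - window + 1, pos1)
    ref_beyond_a <- seq_of(contig1, pos1 + 1, pos1 + window)
  } else {
    flank_a <- seq_of(contig1, pos1, pos1 + window - 1, revcomp = TRUE)
    ref_beyond_a <- seq_of(contig1, pos1 - window, pos1 - 1, revcomp = TRUE)
  }
  if (side2 == "R") {
    flank_b <- seq_of(contig2, pos2, pos2 + window - 1)
    ref_beyond_b <- seq_of(contig2, pos2 - window, pos2 - 1)
  } else {
    flank_b <- seq_of(contig2, pos2 - window + 1, pos2, revcomp = TRUE)
    ref_beyond_b <- seq_of(contig2, pos2 + 1, pos2 + window, revcomp = TRUE)
  }
  list(flank_a = flank_a, flank_b = flank_b,
       ref_beyond_a = ref_beyond_a, ref_beyond_b = ref_beyond_b)
}

#' Classify junction-inserted bases
#'
#' `junction_seq` must span the join: it starts with a suffix of
#' `flank_a` and ends with a prefix of `flank_b` (each anchor at least
#' `min_anchor` bases). The bases between the anchors are the insertion.
#' An insertion with a local alignment of at least `min_match` bases at
#' `min_identity` identity inside either search window (both strands) is
#' TEMPLATED (with locus offset and identity); otherwise NONTEMPLATED;
#' no inserted bases gives NONE.
#'
#' @param junction_seq Observed junction-spanning sequence.
#' @param flank_a,flank_b Reference flanks in derivative orientation.
#' @param search_windows Character/`DNAString` list of reference windows
#'   (e.g. +/- 2 kb around both breakpoints).
#' @param min_anchor Minimum flank anchor match (default 10 nt).
#' @param min_match Minimum templated-alignment length (default 10 nt).
#' @param min_identity Minimum templated-alignment identity (default 0.9).
#' @return List: `insertion_seq`, `insertion_len`, `origin` (one of
#'   `"NONE"`, `"NONTEMPLATED"`, `"TEMPLATED"`), `templated_window`,
#'   `templated_identity`, `templated_inverted`, `simple_repeat`.
#' @export
classify_insertion <- function(junction_seq, flank_a, flank_b,
                               search_windows = list(),
                               min_anchor = 10, min_match = 10,
                               min_identity = 0.9) {
  js <- toupper(junction_seq)
  fa <- toupper(flank_a); fb <- toupper(flank_b)
  # longest prefix of junction_seq equal to a suffix of flank_a, and
  # longest suffix equal to a prefix of flank_b: the anchors
  a_len <- 0L
  for (k in seq_len(min(nchar(js), nchar(fa)))) {
    if (substr(js, 1, k) == substr(fa, nchar(fa) - k + 1, nchar(fa)))
      a_len <- k
  }
  b_len <- 0L
  for (k in seq_len(min(nchar(js), nchar(fb)))) {
    if (substr(js, nchar(js) - k + 1, nchar(js)) == substr(fb, 1, k))
      b_len <- k
  }
  if (a_len < min_anchor || b_len < min_anchor)
    stop("junction sequence does not span the join", call. = FALSE)
  ins_from <- a_len + 1L
  ins_to <- nchar(js) - b_len
  if (ins_from > ins_to)
    return(list(insertion_seq = "", insertion_len = 0L, origin = "NONE",
                templated_window = NA_integer_,
                templated_identity = NA_real_, templated_inverted = FALSE,
                simple_repeat = FALSE))
  ins <- substr(js, ins_from, ins_to)

  origin <- "NONTEMPLATED"
  t_win <- NA_integer_; t_ident <- NA_real_; t_inv <- FALSE
  if (nchar(ins) >= min_match && length(search_windows)) {
    pat <- Biostrings::DNAString(ins)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
    for (wi in seq_along(search_windows)) {
      w <- Biostrings::DNAString(as.character(search_windows[[wi]]))
      for (strand in 1:2) {
        subj <- if (strand == 1) w else Biostrings::reverseComplement(w)
        al <- Biostrings::pairwiseAlignment(pat, subj, type = "local",
                                            substitutionMatrix = mat,
                                            gapOpening = 4, gapExtension = 2)
        n_al <- Biostrings::nchar(Biostrings::pattern(al))
        if (n_al >= min_match) {
          ident <- Biostrings::nmatch(al) / n_al
          if (ident >= min_identity && n_al >= min_match &&
              Biostrings::nmatch(al) >= min_identity * nchar(ins)) {
            origin <- "TEMPLATED"; t_win <- wi
            t_ident <- round(100 * ident, 1); t_inv <- strand == 2
          }
        }
        if (origin == "TEMPLATED") break
      }
      if (origin == "TEMPLATED") break
    }
  }
  base_tab <- table(strsplit(ins, "")[[1]])
  simple <- nchar(ins) >= 4 && (max(base_tab) / nchar(ins) >= 0.8 ||
                                  is_str_repeat(ins))
  list(insertion_seq = ins, insertion_len = nchar(ins), origin = origin,
       templated_window = t_win, templated_identity = t_ident,
       templated_inverted = t_inv, simple_repeat = simple)
}

# di/trinucleotide short tandem repeat check
is_str_repeat <- function(x) {
  n <- nchar(x)
  for (u in 2:3) {
    if (n >= 2 * u) {
      unit <- substr(x, 1, u)
      rep_full <- paste(rep(unit, ceiling(n / u)), collapse = "")
      if (substr(rep_full, 1, n) == x) return(TRUE)
    }
  }
  FALSE
}

#' Signature of every junction in a set
#'
#' Computes per-junction microhomology from the reference flanks, and,
#' where a junction-spanning sequence is available, insertion
#' classification. Insertions take precedence: at a junction with
#' inserted bases the microhomology is reported as 0 (the categories are
#' mutually exclusive per junction). A junction with neither
#' microhomology nor insertion is blunt. Flank-versus-flank similarity
#' (identity > 80% over 50 nt) is additionally reported as
#' `flank_similarity`.
#'
#' @param junc A `cgr_junctions` table.
#' @param ref Named `DNAStringSet` reference.
#' @param window Flank window for microhomology (default 150 nt).
#' @param search_window Half-width of the templated-insert search window
#'   (default 2000 nt).
#' @param ... Passed to [classify_insertion()].
#' @return A data.frame of class `cgr_signatures`: one row per resolved
#'   junction with `microhomology_len`, `insertion_len`, `insertion_seq`,
#'   `insertion_origin`, `blunt`, `flank_similarity`,
#'   `templated_inverted`, `simple_repeat`.
#' @export
junction_signatures <- function(junc, ref, window = 150,
                                search_window = 2000, ...) {
  res <- junc[junc$resolved1 & junc$resolved2, , drop = FALSE]
  rows <- lapply(seq_len(nrow(res)), function(i) {
    fl <- junction_flanks(res$contig1[i], res$pos1[i], res$side1[i],
                          res$contig2[i], res$pos2[i], res$side2[i],
                          ref, window = window)
    wins <- list(
      window_around(ref, res$contig1[i], res$pos1[i], search_window),
      window_around(ref, res$contig2[i], res$pos2[i], search_window))
    ins <- list(insertion_seq = "", insertion_len = 0L, origin = "NONE",
                templated_inverted = FALSE, simple_repeat = FALSE,
                templated_identity = NA_real_)
    if (!is.na(res$seq[i])) {
      # a junction-spanning sequence may be given on either strand: the
      # canonical breakend order can be the reverse-complement reading
      ins <- tryCatch(
        classify_insertion(res$seq[i], fl$flank_a, fl$flank_b,
                           search_windows = wins, ...),
        error = function(e) {
          rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(res$seq[i])))
          classify_insertion(rc, fl$flank_a, fl$flank_b,
                             search_windows = wins, ...)
        })
    }
    mh <- if (ins$insertion_len > 0) 0L
    else as.integer(microhomology(fl$flank_a, fl$flank_b,
                                  fl$ref_beyond_a, fl$ref_beyond_b))
    sim <- flank_similarity(fl$flank_a, fl$flank_b)
    data.frame(junction_id = res$id[i], microhomology_len = mh,
               insertion_len = ins$insertion_len,
               insertion_seq = ins$insertion_seq,
               insertion_origin = if (ins$insertion_len > 0) ins$origin
               else "NONE",
               templated_identity = ins$templated_identity,
               templated_inverted = isTRUE(ins$templated_inverted),
               simple_repeat = isTRUE(ins$simple_repeat),
               blunt = mh == 0 && ins$insertion_len == 0,
               flank_similarity = sim, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(junction_id = character(), microhomology_len = integer(),
               insertion_len = integer(), insertion_seq = character(),
               insertion_origin = character(), templated_identity = numeric(),
               templated_inverted = logical(), simple_repeat = logical(),
               blunt = logical(), flank_similarity = numeric())
  class(out) <- c("cgr_signatures", "data.frame")
  out
}

window_around <- function(ref, contig, pos, half) {
  len <- Biostrings::width(ref[contig])
  from <- max(1, pos - half); to <- min(len, pos + half)
  as.character(Biostrings::subseq(ref[[contig]], from, to))
}

# identity of flank_a (reversed into a comparable orientation) vs flank_b
# over the terminal 50 nt; a reporting category for junctions whose two
# sides share sequence.
flank_similarity <- function(flank_a, flank_b, span = 50) {
  a <- substr(flank_a, max(1, nchar(flank_a) - span + 1), nchar(flank_a))
  b <- substr(flank_b, 1, span)
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(NA_real_)
  av <- strsplit(substr(a, nchar(a) - n + 1, nchar(a)), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  round(100 * mean(av == bv), 1)
}

#' Rule-based mechanism call for a case
#'
#' CHROMOANASYNTHESIS: at least `min_gains` copy-number gains and at
#' least half of the resolved junctions with 1-100 nt microhomology or a
#' templated insert (the replicative template-switch signature).
#' ALU_MEDIATED_RING: a circular walk with terminal losses (named for
#' the proposed repeat-mediated ring mechanism; the rule keys on
#' topology, not repeat content). SIMPLE_NHEJ_LIKE: at most 2 junctions,
#' all blunt or with microhomology of at most 2 nt. Otherwise
#' UNCLASSIFIED.
#'
#' @param signatures A `cgr_signatures` table.
#' @param walk The case's `cgr_walk`.
#' @param min_gains Gains threshold for the replicative call (default 3).
#' @return List with `call` and `evidence` (character vector of fired
#'   rules).
#' @export
call_mechanism <- function(signatures, walk, min_gains = 3) {
  st <- walk$steps[!walk$steps$gap, , drop = FALSE]
  # count distinct gained regions: atoms covered by >= 2 step copies
  gains <- 0L
  if (nrow(st)) {
    cuts <- sort(unique(c(st$start, st$end)))
    if (length(cuts) > 1) {
      a0 <- cuts[-length(cuts)]; a1 <- cuts[-1]
      cov <- vapply(seq_along(a0), function(i)
        sum(st$start <= a0[i] & st$end >= a1[i]), numeric(1))
      gains <- sum(rle(cov >= 2)$values)
    }
  }
  n_j <- nrow(signatures)
  mh_or_templated <- signatures$microhomology_len >= 1 &
    signatures$microhomology_len <= 100
  mh_or_templated <- mh_or_templated | signatures$insertion_origin == "TEMPLATED"
  frac <- if (n_j) mean(mh_or_templated) else 0

  evidence <- character()
  call <- "UNCLASSIFIED"
  if (gains >= min_gains && n_j > 0 && frac >= 0.5) {
    call <- "CHROMOANASYNTHESIS"
    evidence <- c(evidence,
                  sprintf("%d copy-number gains (>= %d)", gains, min_gains),
                  sprintf("%.0f%% of resolved junctions with microhomology or templated insert (>= 50%%)",
                          100 * frac))
  } else if (isTRUE(walk$circular)) {
    call <- "ALU_MEDIATED_RING"
    evidence <- c(evidence, "circular derivative (ring)",
                  "terminal segments lost")
  } else if (n_j <= 2 && n_j > 0 &&
             all(signatures$blunt | signatures$microhomology_len <= 2)) {
    call <- "SIMPLE_NHEJ_LIKE"
    evidence <- c(evidence,
                  sprintf("%d junction(s), blunt or microhomology <= 2 nt", n_j))
  }
  list(call = call, evidence = evidence)
}
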