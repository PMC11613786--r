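# Synthetic-data generator: everything the pipeline consumes, with known
# truth. Derivative chromosomes are spliced from a toy reference along a
# truth walk; junction microarchitecture is planted by mutating the
# reference flanks *before* splicing, so that microhomology bases are
# genuinely shared by both reference copies and the brute-force detector
# oracle stays honest. All functions are deterministic given their seed.

BASES <- c("A", "C", "G", "T")

#' Generate a random toy reference
#'
#' Uniform-random ACGT sequence; optionally plants pairs of direct
#' repeats (identical blocks at two loci) for homology/templated-insert
#' tests.
#'
#' @param length Reference length in nt (at least 10 kb).
#' @param seed Integer seed (reproducible output).
#' @param contig Contig name.
#' @param repeat_pairs Number of planted 300-nt direct repeat pairs.
#' @return A named `DNAStringSet` of length 1.
#' @export
make_reference <- function(length, seed = 1, contig = "chrS",
                           repeat_pairs = 0) {
  if (length < 10000) stop("reference too short (< 10 kb)", call. = FALSE)
  set.seed(seed)
  s <- sample(BASES, length, replace = TRUE)
  if (repeat_pairs > 0) {
    for (k in seq_len(repeat_pairs)) {
      src <- sample.int(length - 300, 1)
      dst <- sample.int(length - 300, 1)
      s[dst:(dst + 299)] <- s[src:(src + 299)]
    }
  }
  x <- Biostrings::DNAStringSet(paste(s, collapse = ""))
  names(x) <- contig
  x
}

comp_base <- function(b) unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])

# derivative-view base accessors around a breakend ---------------------------
# beyond_a index i = i-th reference base past an exit breakend, in
# derivative orientation; flank_b index i = i-th base of the entry flank.

ref_pos_beyond_exit <- function(pos, side, i) if (side == "L") pos + i else pos - i
ref_pos_flank_entry <- function(pos, side, i) if (side == "R") pos + i - 1 else pos - i + 1
ref_pos_before_entry <- function(pos, side) if (side == "R") pos - 1 else pos + 1

#' Simulate a derivative chromosome from a truth walk
#'
#' Splices the reference along `walk`; at each novel adjacency the
#' reference flanks are first mutated to realise the requested
#' microhomology (`m` shared terminal bases, with forced mismatches at
#' `m + 1` so the planted value is exact) or the requested insertion.
#'
#' @param ref Named `DNAStringSet` (single contig).
#' @param walk A `cgr_walk` without gap steps (on that contig).
#' @param junction_params data.frame with one row per novel adjacency of
#'   the walk (in join order): columns `m` (microhomology nt),
#'   `ins_len` (inserted nt, exclusive with `m > 0`), `ins_templated`
#'   (logical; templated inserts are copied from 300 nt past the first
#'   breakend). Missing -> all blunt.
#' @param flank_window Junction-spanning sequence half-width (default 150).
#' @return A `cgr_sim` list: `reference` (mutated), `derivative`,
#'   `walk`, `junctions` (with junction-spanning sequences),
#'   `junction_params`, `graph_inputs` (segments/cn/junctions for
#'   [build_graph()]), `inserts` (per-junction inserted sequence).
#' @export
simulate_derivative <- function(ref, walk, junction_params = NULL,
                                flank_window = 150) {
  contig <- names(ref)[1]
  L <- Biostrings::width(ref)[1]
  if (any(walk$steps$gap))
    stop("truth walks must be fully resolved", call. = FALSE)
  joins <- walk_joins(walk)
  joins <- joins[!joins$reference, , drop = FALSE]
  nj <- nrow(joins)
  if (is.null(junction_params))
    junction_params <- data.frame(m = integer(nj), ins_len = integer(nj),
                                  ins_templated = logical(nj))
  if (is.null(junction_params$ins_len)) junction_params$ins_len <- 0L
  if (is.null(junction_params$ins_templated)) junction_params$ins_templated <- FALSE
  if (nrow(junction_params) != nj)
    stop(sprintf("junction_params has %d rows but the walk has %d novel adjacencies",
                 nrow(junction_params), nj), call. = FALSE)
  if (any(junction_params$m > 0 & junction_params$ins_len > 0))
    stop("microhomology and insertion are mutually exclusive per junction",
         call. = FALSE)
  if (any(junction_params$m > flank_window - 2))
    stop("infeasible microhomology: m exceeds the flank window", call. = FALSE)

  seqv <- strsplit(as.character(ref[[1]]), "")[[1]]
  written <- new.env(parent = emptyenv())

  put <- function(pos, value, flexible_not = NULL) {
    # value: exact base to write; flexible_not: write any base != these
    if (pos < 1 || pos > L) return(invisible())
    key <- as.character(pos)
    if (!is.null(value)) {
      prev <- written[[key]]
      if (!is.null(prev) && prev != value)
        stop("junction contexts overlap: conflicting write at position ", pos,
             call. = FALSE)
      seqv[pos] <<- value
      written[[key]] <- value
    } else {
      prev <- written[[key]]
      if (!is.null(prev)) {
        if (prev %in% flexible_not)
          stop("junction contexts overlap: conflicting write at position ", pos,
               call. = FALSE)
        return(invisible())
      }
      if (seqv[pos] %in% flexible_not) {
        pick <- setdiff(BASES, flexible_not)[1]
        seqv[pos] <<- pick
        written[[key]] <- pick
      }
    }
    invisible()
  }

  exit_bes <- lapply(joins$from, function(i) step_exit_breakend(walk$steps[i, ]))
  entry_bes <- lapply(joins$to, function(i) step_entry_breakend(walk$steps[i, ]))
  inserts <- character(nj)

  for (k in seq_len(nj)) {
    a <- exit_bes[[k]]; b <- entry_bes[[k]]
    m <- junction_params$m[k]
    ilen <- junction_params$ins_len[k]
    # derivative-view base at entry flank index i (reads current seqv)
    entry_base <- function(i) {
      p <- ref_pos_flank_entry(b$pos, b$side, i)
      if (b$side == "R") seqv[p] else comp_base(seqv[p])
    }
    exit_flank_base_last <- if (a$side == "L") unname(seqv[a$pos]) else
      unname(comp_base(seqv[a$pos]))
    set_beyond_exit <- function(i, dbase) {
      p <- ref_pos_beyond_exit(a$pos, a$side, i)
      put(p, unname(if (a$side == "L") dbase else comp_base(dbase)))
    }
    exit_flank_base <- function(i) {  # i-th base before the junction
      p <- if (a$side == "L") a$pos - i + 1 else a$pos + i - 1
      if (a$side == "L") unname(seqv[p]) else unname(comp_base(seqv[p]))
    }
    set_before_entry_i <- function(i, dbase) {
      p <- if (b$side == "R") b$pos - i else b$pos + i
      put(p, unname(if (b$side == "R") dbase else comp_base(dbase)))
    }
    exit_room <- if (a$side == "L") L - a$pos else a$pos - 1
    if (ilen == 0) {
      # realise m exactly: copy the entry flank into the exit's reference
      # continuation (or, when the exit breakend sits at a contig end,
      # copy the exit flank into the reference preceding the entry), then
      # force mismatches one base past the run on both sides. Insertion
      # junctions skip all of this (their microhomology is 0 by the
      # category-exclusivity convention) so their contexts never clobber
      # a neighbouring junction's planted homology.
      if (exit_room >= m + 1) {
        if (m > 0) {
          for (i in seq_len(m)) set_beyond_exit(i, entry_base(i))
          mm <- setdiff(BASES, entry_base(m + 1))[1]
          set_beyond_exit(m + 1, mm)
        } else {
          mm <- setdiff(BASES, entry_base(1))[1]
          set_beyond_exit(1, mm)
        }
        pb <- ref_pos_before_entry(b$pos, b$side)
        forbid <- if (b$side == "R") exit_flank_base_last else
          unname(comp_base(exit_flank_base_last))
        put(pb, NULL, flexible_not = forbid)
      } else {
        # exit flank ends at a telomere: plant the homology upstream of
        # the entry instead (the shared bases sit before bp2)
        if (m > 0) {
          for (i in seq_len(m)) set_before_entry_i(i, exit_flank_base(i))
          mm2 <- setdiff(BASES, exit_flank_base(m + 1))[1]
          set_before_entry_i(m + 1, mm2)
        } else {
          mm2 <- setdiff(BASES, exit_flank_base(1))[1]
          set_before_entry_i(1, mm2)
        }
      }
    }

    if (ilen > 0) {
      if (junction_params$ins_templated[k]) {
        # copy from 300 nt past the first breakend (inside the default
        # 2 kb search window)
        src <- vapply(seq_len(ilen), function(i) {
          p <- ref_pos_beyond_exit(a$pos, a$side, 300 + i)
          if (a$side == "L") seqv[p] else comp_base(seqv[p])
        }, character(1))
        inserts[k] <- paste(src, collapse = "")
      } else {
        inserts[k] <- paste(sample(BASES, ilen, replace = TRUE), collapse = "")
      }
    }
  }

  mutated <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(mutated) <- contig

  step_seq <- function(i) {
    st <- walk$steps[i, ]
    s <- paste(seqv[(st$start + 1):st$end], collapse = "")
    if (st$inverted)
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }
  pieces <- vapply(seq_len(nrow(walk$steps)), step_seq, character(1))
  # interleave inserts at their joins (join k sits after step joins$from[k])
  ins_after <- rep("", nrow(walk$steps))
  for (k in seq_len(nj)) {
    if (joins$to[k] != 1 || !walk$circular) ins_after[joins$from[k]] <- inserts[k]
  }
  deriv <- paste(paste0(pieces, ins_after), collapse = "")
  if (walk$circular && nj > 0) {
    closing <- which(joins$to == 1 & joins$from == nrow(walk$steps))
    if (length(closing)) deriv <- paste0(deriv, inserts[closing])
  }
  derivative <- Biostrings::DNAStringSet(deriv)
  names(derivative) <- paste0(contig, "_der")

  junc <- walk_junctions(walk)
  # junction-spanning sequences: flank tail + insert + flank head
  w <- flank_window
  jseq <- vapply(seq_len(nj), function(k) {
    fa <- pieces[joins$from[k]]
    fb <- pieces[joins$to[k]]
    paste0(substr(fa, max(1, nchar(fa) - w + 1), nchar(fa)), inserts[k],
           substr(fb, 1, min(w, nchar(fb))))
  }, character(1))
  junc$seq <- jseq  # walk_junctions rows follow join order

  structure(list(reference = mutated, derivative = derivative, walk = walk,
                 junctions = junc, junction_params = junction_params,
                 inserts = inserts,
                 graph_inputs = walk_to_graph_inputs(
                   walk, Biostrings::width(mutated)[1])),
            class = "cgr_sim")
}

#' Simulate trio SNV genotypes with a chosen parental origin
#'
#' Emits informative-site genotypes consistent with the rearrangement's
#' origin: deleted segments transmit only the unaffected homolog's
#' allele; duplicated segments over-represent the carrier parent among
#' phased informative sites at the 2/3 dosage of the duplicated
#' haplotype; diploid segments are balanced. A fraction of sites is
#' emitted below the quality floor to exercise filtering.
#'
#' @param seg A `cgr_segments` table (internal coordinates).
#' @param origin `"PATERNAL"` or `"MATERNAL"` (ignored for diploid rows).
#' @param sites_per_segment Informative sites per segment (default 200).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param low_qual_frac Fraction of additional low-quality (QUAL <= 40)
#'   sites (default 0.1).
#' @return List of data.frames `child`, `father`, `mother` (VCF site
#'   tables for [write_snv_vcf()]) and `truth` (per-site attribution).
#' @export
simulate_trio_snvs <- function(seg, origin = "PATERNAL",
                               sites_per_segment = 200, seed = NULL,
                               low_qual_frac = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  origin <- match.arg(origin, c("PATERNAL", "MATERNAL"))
  rows <- list()
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i]
    n <- min(sites_per_segment, floor(0.8 * len))
    n_low <- min(ceiling(n * low_qual_frac), len - n)
    pos <- sort(seg$start[i] + sample.int(len, n + n_low))
    qual <- c(sample(45:99, n, replace = TRUE),
              sample(20:40, n_low, replace = TRUE))
    dos <- seg$dosage[i]
    p_father_homalt <- if (dos == "DUP") {
      if (origin == "PATERNAL") 2 / 3 else 1 / 3
    } else 0.5
    father_homalt <- stats::runif(n + n_low) < p_father_homalt
    gt_f <- ifelse(father_homalt, "1/1", "0/0")
    gt_m <- ifelse(father_homalt, "0/0", "1/1")
    gt_c <- if (dos %in% c("DEL", "TELDEL")) {
      remaining <- if (origin == "PATERNAL") "maternal" else "paternal"
      rem_homalt <- (remaining == "paternal") == father_homalt
      ifelse(rem_homalt, "1/1", "0/0")
    } else rep("0/1", n + n_low)
    rows[[i]] <- data.frame(chrom = seg$contig[i], pos = pos, ref = "A",
                            alt = "G", qual = qual, gt_father = gt_f,
                            gt_mother = gt_m, gt_child = gt_c,
                            label = seg$label[i], stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  mk <- function(gt_col) data.frame(chrom = all$chrom, pos = all$pos,
                                    ref = all$ref, alt = all$alt,
                                    qual = all$qual, gt = all[[gt_col]],
                                    stringsAsFactors = FALSE)
  list(child = mk("gt_child"), father = mk("gt_father"),
       mother = mk("gt_mother"), truth = all)
}

#' Simulate a binned read-depth profile from a copy-number vector
#'
#' Per-bin read counts are Poisson with rate
#' `coverage/2 * cn * bin / read_length`; mean depth is reads scaled
#' back by `read_length / bin`.
#'
#' @param cn_segments data.frame with `start`, `end` (0-based half-open)
#'   and `cn`; must tile the profiled region.
#' @param coverage Haploid-pair coverage at CN 2 (default 30).
#' @param bin Bin width in nt (default 10000).
#' @param read_length Notional read length (default 150).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param contig Contig name.
#' @return A `cgr_depth` data.frame.
#' @export
simulate_depth <- function(cn_segments, coverage = 30, bin = 10000,
                           read_length = 150, seed = NULL, contig = "chrS") {
  if (!is.null(seed)) set.seed(seed)
  L <- max(cn_segments$end)
  starts <- seq(0, L - 1, by = bin)
  ends <- pmin(starts + bin, L)
  mids <- (starts + ends) / 2
  cn <- vapply(mids, function(x) {
    i <- which(cn_segments$start <= x & cn_segments$end > x)[1]
    if (is.na(i)) 2 else cn_segments$cn[i]
  }, numeric(1))
  lambda <- coverage / 2 * cn * (ends - starts) / read_length
  reads <- stats::rpois(length(lambda), lambda)
  df <- data.frame(contig = contig, bin_start = starts, bin_end = ends,
                   mean_depth = reads * read_length / (ends - starts))
  class(df) <- c("cgr_depth", "data.frame")
  df
}

# ------------------------------------------------------------- scenarios --

scale_walk <- function(walk, scale = 100) {
  st <- walk$steps
  st$start <- floor(st$start / scale)
  st$end <- floor(st$end / scale)
  derivative_walk(st, circular = walk$circular)
}

scale_segments <- function(seg, scale = 100) {
  seg$start <- floor(seg$start / scale)
  seg$end <- floor(seg$end / scale)
  validate_segments(seg)
}

# fill inter-segment gaps with diploid control segments (for phasing)
fill_control_segments <- function(seg, contig_length) {
  o <- order(seg$start)
  seg <- seg[o, , drop = FALSE]
  gaps <- list(); cursor <- 0; k <- 0
  for (i in seq_len(nrow(seg))) {
    if (seg$start[i] - cursor > 1000) {
      k <- k + 1
      gaps[[k]] <- data.frame(case_id = seg$case_id[1],
                              label = paste0("ctrl", k), contig = seg$contig[1],
                              start = cursor, end = seg$start[i],
                              dosage = "NML", method = NA_character_)
    }
    cursor <- max(cursor, seg$end[i])
  }
  if (contig_length - cursor > 1000) {
    k <- k + 1
    gaps[[k]] <- data.frame(case_id = seg$case_id[1], label = paste0("ctrl", k),
                            contig = seg$contig[1], start = cursor,
                            end = contig_length, dosage = "NML",
                            method = NA_character_)
  }
  validate_segments(rbind(as.data.frame(seg), do.call(rbind, gaps)))
}

scenario_names <- function() c("chromoanasynthesis_dup6", "ring21",
                               "mixed_delsdups13")

#' Build a named simulation scenario
#'
#' The three scenarios mirror the statistical structure of the bundled
#' cases at 1/100 genomic scale (toy reference of ~451 kb):
#' `"chromoanasynthesis_dup6"` (6 duplications, 9 junctions, 6 with
#' microhomology 1-79 nt, one 4-nt nontemplated insertion, paternal
#' origin), `"ring21"` (ring with two terminal-deletion arms and a
#' relocated inversion, one templated insert, maternal-origin
#' deletions), `"mixed_delsdups13"` (13 dosage-altering SVs, 15
#' junctions: ten 1-7 nt microhomologies, two 4/9-nt nontemplated and
#' three 26-94 nt templated insertions, paternal origin; its breakend
#' VCF additionally carries one unpaired record emulating an unresolved
#' partner).
#'
#' @param name One of `scenario_names()`.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, all on-disk artefacts
#'   (FASTA, truth BEDPE, segment TSV, trio VCFs, BND VCF, depth TSV)
#'   are written there.
#' @return A list: `name`, `sim` (a `cgr_sim`), `truth_walk`,
#'   `case_segments` (scaled dosage rows), `phasing_segments`, `origin`,
#'   `trio`, `depth`, `contig_length`, `files` (paths, when written).
#' @export
cgr_scenario <- function(name, seed = 1, out_dir = NULL) {
  name <- match.arg(name, scenario_names())
  set.seed(seed)
  L <- floor(CHR21_LENGTH / 100)
  ref <- make_reference(L, seed = sample.int(1e6, 1), contig = "chrS")

  case_id <- switch(name, chromoanasynthesis_dup6 = "RD_P505",
                    ring21 = "RD_P26", mixed_delsdups13 = "RD_P01")
  bundle <- cgr_case(case_id)
  walk <- bundle$metadata$nomenclature_walk
  if (name == "mixed_delsdups13") {
    # the case's unresolved element is given a concrete 0.1 Mb extent so
    # the truth walk is fully specified
    st <- walk$steps
    g <- which(st$gap)
    st$end[g] <- st$start[g] + 1e5
    st$gap[g] <- FALSE
    walk <- derivative_walk(st, circular = walk$circular)
  }
  walk <- scale_walk(walk, 100)
  walk$steps$contig <- "chrS"

  nj <- count_novel_adjacencies(walk)
  params <- switch(
    name,
    chromoanasynthesis_dup6 = data.frame(
      m = c(1, 3, 7, 21, 40, 79, 0, 0, 0),
      ins_len = c(0, 0, 0, 0, 0, 0, 4, 0, 0),
      ins_templated = FALSE),
    ring21 = data.frame(
      m = c(5, 0, 2, 0),
      ins_len = c(0, 20, 0, 0),
      ins_templated = c(FALSE, TRUE, FALSE, FALSE)),
    mixed_delsdups13 = data.frame(
      m = c(1, 2, 3, 0, 4, 5, 6, 0, 7, 1, 0, 2, 3, 4, 5),
      ins_len = c(0, 0, 0, 26, 0, 0, 0, 4, 0, 0, 60, 0, 0, 0, 0),
      ins_templated = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                        FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                        FALSE)))
  stopifnot(nrow(params) == nj)
  sim <- simulate_derivative(ref, walk, params)

  case_segments <- scale_segments(bundle$segments, 100)
  case_segments$contig <- "chrS"
  phasing_segments <- fill_control_segments(case_segments, L)
  origin <- switch(name, chromoanasynthesis_dup6 = "PATERNAL",
                   ring21 = "MATERNAL", mixed_delsdups13 = "PATERNAL")
  trio <- simulate_trio_snvs(phasing_segments, origin = origin,
                             sites_per_segment = 200)
  gi <- sim$graph_inputs
  depth <- simulate_depth(data.frame(start = gi$segments$start,
                                     end = gi$segments$end,
                                     cn = gi$cn),
                          coverage = 30, bin = 10000, contig = "chrS")

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(sim$reference, p("reference.fa"))
    write_fasta(sim$derivative, p("derivative.fa"))
    write_junctions_bedpe(sim$junctions, p("truth.bedpe"))
    write_segment_table(case_segments, p("segments.tsv"))
    jf <- Biostrings::DNAStringSet(sim$junctions$seq)
    names(jf) <- sim$junctions$id
    write_fasta(jf, p("junction_seqs.fa"))
    write_vcf_bnd(sim$junctions, p("breakends.vcf"),
                  contig_lengths = stats::setNames(L, "chrS"))
    if (name == "mixed_delsdups13" && nrow(sim$junctions) > 3) {
      # emulate one unresolved partner: remove one mate record so the
      # remaining breakend is unpaired
      lines <- readLines(p("breakends.vcf"))
      drop_id <- paste0(sim$junctions$id[4], "_2")
      ids <- vapply(strsplit(lines, "\t", fixed = TRUE),
                    function(x) if (length(x) >= 3) x[3] else "", "")
      writeLines(lines[ids != drop_id], p("breakends.vcf"))
    }
    write_snv_vcf(trio$child, p("child.vcf"), "CHILD")
    write_snv_vcf(trio$father, p("father.vcf"), "FATHER")
    write_snv_vcf(trio$mother, p("mother.vcf"), "MOTHER")
    write_depth_tsv(depth, p("depth.tsv"))
    files <- list(reference = p("reference.fa"), derivative = p("derivative.fa"),
                  bedpe = p("truth.bedpe"), segments = p("segments.tsv"),
                  junction_seqs = p("junction_seqs.fa"),
                  breakends = p("breakends.vcf"), child = p("child.vcf"),
                  father = p("father.vcf"), mother = p("mother.vcf"),
                  depth = p("depth.tsv"))
  }
  list(name = name, sim = sim, truth_walk = walk,
       case_segments = case_segments, phasing_segments = phasing_segments,
       origin = origin, trio = trio, depth = depth, contig_length = L,
       files = files)
}
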