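# Breakpoint graph and derivative-walk assembly.
#
# The graph formalises manual junction-following: nodes are segment-end
# breakends, reference edges connect abutting segment ends, novel edges
# come from junctions (each with multiplicity 1), and per-segment copy
# numbers say how often a segment is visited by the derivative walk
# (cn - 1 times: the other homolog is intact, so a CN=3 duplication puts
# two copies on the derivative and a CN=1 deletion none).

default_cn <- function(dosage) {
  unname(c(DEL = 1, TELDEL = 1, DUP = 3, INV = 2, NML = 2)[dosage])
}

#' Build a breakpoint graph from segments, junctions and copy numbers
#'
#' Segments must tile part of `[0, contig_length)` without overlap; gaps
#' are auto-filled as copy-neutral (`NML`, CN 2) segments. Junction
#' breakends must coincide with segment boundaries within `tolerance`
#' (and are snapped to the boundary). Junctions with an unresolved
#' partner cannot be traversed and are set aside in `$unresolved`.
#'
#' @param seg A `cgr_segments` table (one case, one contig).
#' @param junc A `cgr_junctions` table.
#' @param cn Integer copy number per row of `seg`; defaults from dosage
#'   (DEL/TELDEL 1, DUP 3, INV/NML 2).
#' @param contig_length Contig length in bases.
#' @param tolerance Max breakend-to-boundary distance (default 0).
#' @return A `cgr_graph` object.
#' @export
build_graph <- function(seg, junc, cn = NULL, contig_length, tolerance = 0) {
  L <- as.numeric(contig_length)
  if (is.null(cn)) cn <- default_cn(seg$dosage)
  if (length(cn) != nrow(seg)) stop("cn must match seg rows", call. = FALSE)
  if (any(cn < 0)) stop("copy numbers must be >= 0", call. = FALSE)
  contig <- unique(seg$contig)
  if (length(contig) != 1) stop("segments must be on one contig", call. = FALSE)

  o <- order(seg$start)
  seg <- seg[o, , drop = FALSE]; cn <- cn[o]
  if (any(seg$start[-1] < seg$end[-nrow(seg)]))
    stop("copy-number segments overlap", call. = FALSE)
  if (any(seg$end > L)) stop("segment beyond contig end", call. = FALSE)

  # tile [0, L) with auto-filled copy-neutral gaps
  atoms <- data.frame(label = character(), start = numeric(), end = numeric(),
                      cn = numeric(), stringsAsFactors = FALSE)
  cursor <- 0; fill <- 0L
  for (i in seq_len(nrow(seg))) {
    if (seg$start[i] > cursor) {
      fill <- fill + 1L
      atoms <- rbind(atoms, data.frame(label = paste0("fill", fill),
                                       start = cursor, end = seg$start[i],
                                       cn = 2))
    }
    atoms <- rbind(atoms, data.frame(label = seg$label[i], start = seg$start[i],
                                     end = seg$end[i], cn = cn[i]))
    cursor <- seg$end[i]
  }
  if (cursor < L) {
    atoms <- rbind(atoms, data.frame(label = paste0("fill", fill + 1L),
                                     start = cursor, end = L, cn = 2))
  }

  unresolved <- junc[!junc$resolved1 | !junc$resolved2, , drop = FALSE]
  junc <- junc[junc$resolved1 & junc$resolved2, , drop = FALSE]

  snap <- function(pos, side) {
    # breakend (pos, "L") sits on a segment 3' boundary (1-based end);
    # (pos, "R") on a 5' boundary (1-based start = 0-based start + 1)
    bounds <- if (side == "L") atoms$end else atoms$start + 1
    d <- abs(bounds - pos)
    k <- which.min(d)
    if (d[k] > tolerance) {
      near <- sort(bounds[order(abs(bounds - pos))][1:min(2, length(bounds))])
      stop(sprintf(
        "junction breakend %s:%s/%s does not match a segment boundary (tolerance %d); nearest boundaries: %s",
        contig, format(pos, scientific = FALSE), side, tolerance,
        paste(format(near, scientific = FALSE), collapse = ", ")),
        call. = FALSE)
    }
    bounds[k]
  }
  if (nrow(junc)) {
    junc$pos1 <- mapply(snap, junc$pos1, junc$side1)
    junc$pos2 <- mapply(snap, junc$pos2, junc$side2)
  }

  structure(list(segments = atoms, junctions = junc, unresolved = unresolved,
                 contig = contig, contig_length = L, tolerance = tolerance),
            class = "cgr_graph")
}

#' @export
print.cgr_graph <- function(x, ...) {
  cat(sprintf("Breakpoint graph: %d segments on %s (%s bp), %d novel edge(s)%s\n",
              nrow(x$segments), x$contig,
              format(x$contig_length, big.mark = ","), nrow(x$junctions),
              if (nrow(x$unresolved)) sprintf(", %d unresolved set aside",
                                              nrow(x$unresolved)) else ""))
  invisible(x)
}

# breakend key helpers ------------------------------------------------------

be_key <- function(pos, side)
  paste0(format(pos, scientific = FALSE, trim = TRUE), ":", side)

#' Assemble derivative walks from a breakpoint graph
#'
#' Exhaustive depth-first traversal: every returned walk starts at pter
#' (or the supplied 1-based start position), uses each novel edge exactly
#' once, visits each segment `cn - 1` times, and either ends at qter or
#' closes into a ring. When the pter segment carries no derivative copy
#' (terminal loss), ring walks are searched instead, anchored at the
#' lowest-coordinate segment still present. Tie-breaking is deterministic
#' (novel edges before reference continuation; lower coordinate first);
#' results are deduplicated up to rotation/reflection and sorted.
#'
#' @param graph A `cgr_graph`.
#' @param start `"pter"` or a 1-based position at which the walk begins.
#' @param max_states Node budget for the exhaustive search.
#' @param max_walks Stop after this many distinct solutions.
#' @return A `cgr_walkset`: list with `walks` (list of `cgr_walk`),
#'   `ambiguous`, `reason` (NULL, or why no walk exists), `states`.
#' @export
assemble_walk <- function(graph, start = "pter", max_states = 1e6,
                          max_walks = 1000) {
  at <- graph$segments
  n <- nrow(at)
  visits <- at$cn - 1
  if (any(visits < 0))
    stop("copy number 0 is below the intact homolog; cn must be >= 1",
         call. = FALSE)
  ej <- graph$junctions
  m <- nrow(ej)
  start1 <- at$start + 1  # 1-based starts
  end1 <- at$end          # 1-based ends

  seg_by_start <- structure(seq_len(n), names = be_key(start1, "R"))
  seg_by_end <- structure(seq_len(n), names = be_key(end1, "L"))

  # edge endpoints -> (segment to enter, orientation)
  enter_at <- function(pos, side) {
    key <- be_key(pos, side)
    if (side == "R") {
      i <- seg_by_start[key]
      if (is.na(i)) return(NULL)
      list(seg = unname(i), inverted = FALSE)
    } else {
      i <- seg_by_end[key]
      if (is.na(i)) return(NULL)
      list(seg = unname(i), inverted = TRUE)
    }
  }

  exit_of <- function(seg, inverted) {
    if (!inverted) list(pos = end1[seg], side = "L")
    else list(pos = start1[seg], side = "R")
  }
  entry_of <- function(seg, inverted) {
    if (!inverted) list(pos = start1[seg], side = "R")
    else list(pos = end1[seg], side = "L")
  }

  # incidence: for each edge, its two breakends
  e1p <- ej$pos1; e1s <- ej$side1; e2p <- ej$pos2; e2s <- ej$side2

  st <- new.env(parent = emptyenv())
  st$states <- 0L
  st$walks <- list()
  st$keys <- character()
  st$budget_hit <- FALSE

  mk_walk <- function(path, circular) {
    steps <- data.frame(contig = graph$contig,
                        start = at$start[vapply(path, `[[`, 0, "seg")],
                        end = at$end[vapply(path, `[[`, 0, "seg")],
                        inverted = vapply(path, `[[`, TRUE, "inverted"),
                        gap = FALSE)
    derivative_walk(steps, circular = circular)
  }

  record <- function(path, circular) {
    w <- mk_walk(path, circular)
    key <- canonical_walk(w)
    if (!key %in% st$keys) {
      st$keys <- c(st$keys, key)
      st$walks[[length(st$walks) + 1L]] <- w
    }
  }

  dfs <- function(cur, visits, used, path, mode, entry0) {
    if (length(st$walks) >= max_walks) return(invisible())
    st$states <- st$states + 1L
    if (st$states > max_states) { st$budget_hit <- TRUE; return(invisible()) }

    done <- all(visits == 0)
    if (done) {
      if (mode == "linear") {
        at_qter <- cur$pos == graph$contig_length && cur$side == "L"
        started_pter <- path[[1]]$seg == 1L && !path[[1]]$inverted
        if ((at_qter || started_pter) && all(used))
          record(path, circular = FALSE)
      } else {
        # ring closure: reference adjacency or one remaining novel edge
        ref_close <- (cur$side == "L" && entry0$side == "R" &&
                        cur$pos + 1 == entry0$pos) ||
          (cur$side == "R" && entry0$side == "L" && cur$pos - 1 == entry0$pos)
        if (ref_close && all(used)) record(path, circular = TRUE)
        if (!all(used)) {
          rem <- which(!used)
          for (e in rem) {
            hit <- (e1p[e] == cur$pos && e1s[e] == cur$side &&
                      e2p[e] == entry0$pos && e2s[e] == entry0$side) ||
              (e2p[e] == cur$pos && e2s[e] == cur$side &&
                 e1p[e] == entry0$pos && e1s[e] == entry0$side)
            if (hit && sum(!used) == 1) record(path, circular = TRUE)
          }
        }
      }
      # nothing left to place; no continuation possible
      if (all(visits == 0) && all(used)) return(invisible())
    }

    # moves: novel edges first (by partner coordinate), then reference
    moves <- list()
    if (m > 0) {
      for (e in which(!used)) {
        partner <- NULL
        if (e1p[e] == cur$pos && e1s[e] == cur$side)
          partner <- list(pos = e2p[e], side = e2s[e])
        else if (e2p[e] == cur$pos && e2s[e] == cur$side)
          partner <- list(pos = e1p[e], side = e1s[e])
        if (is.null(partner)) next
        ent <- enter_at(partner$pos, partner$side)
        if (is.null(ent) || visits[ent$seg] == 0) next
        moves[[length(moves) + 1L]] <-
          list(edge = e, seg = ent$seg, inverted = ent$inverted,
               ord = partner$pos)
      }
      if (length(moves) > 1) {
        moves <- moves[order(vapply(moves, `[[`, 0, "ord"))]
      }
    }
    # reference continuation
    if (cur$side == "L") {
      nxt <- seg_by_start[be_key(cur$pos + 1, "R")]
      if (!is.na(nxt) && visits[nxt] > 0)
        moves[[length(moves) + 1L]] <-
          list(edge = NA_integer_, seg = unname(nxt), inverted = FALSE, ord = Inf)
    } else {
      nxt <- seg_by_end[be_key(cur$pos - 1, "L")]
      if (!is.na(nxt) && visits[nxt] > 0)
        moves[[length(moves) + 1L]] <-
          list(edge = NA_integer_, seg = unname(nxt), inverted = TRUE, ord = Inf)
    }

    for (mv in moves) {
      v2 <- visits; v2[mv$seg] <- v2[mv$seg] - 1
      u2 <- used; if (!is.na(mv$edge)) u2[mv$edge] <- TRUE
      dfs(exit_of(mv$seg, mv$inverted), v2, u2,
          c(path, list(list(seg = mv$seg, inverted = mv$inverted))),
          mode, entry0)
      if (st$budget_hit || length(st$walks) >= max_walks) return(invisible())
    }
    invisible()
  }

  launch <- function(seg0, inverted0, mode) {
    if (visits[seg0] == 0) return(invisible())
    v <- visits; v[seg0] <- v[seg0] - 1
    dfs(exit_of(seg0, inverted0), v, rep(FALSE, m),
        list(list(seg = seg0, inverted = inverted0)),
        mode, entry_of(seg0, inverted0))
  }

  reason <- NULL
  if (identical(start, "pter")) {
    # a linear derivative either starts at pter forward or (when the
    # p-terminus is replaced) starts elsewhere and must end at qter:
    # launch from every retained (segment, orientation) and let the
    # telomere condition at acceptance time discriminate. Ring walks are
    # additionally searched anchored at the first retained segment
    # (every solution visits it, so one anchor is exhaustive up to
    # rotation and reflection, which canonical deduplication absorbs).
    if (!any(visits > 0)) {
      reason <- "no segment carries a derivative copy"
    } else {
      for (s0 in which(visits > 0)) {
        for (inv0 in c(FALSE, TRUE)) {
          launch(s0, inv0, "linear")
          if (st$budget_hit) break
        }
        if (st$budget_hit) break
      }
      if (!st$budget_hit) {
        seg0 <- which(visits > 0)[1]
        launch(seg0, FALSE, "ring")
        launch(seg0, TRUE, "ring")
      }
    }
  } else {
    seg0 <- seg_by_start[be_key(as.numeric(start), "R")]
    if (is.na(seg0)) stop("start position is not a segment boundary",
                          call. = FALSE)
    launch(unname(seg0), FALSE, "linear")
  }

  if (length(st$walks) == 0 && is.null(reason)) {
    reason <- if (st$budget_hit) "node budget exceeded before any solution"
    else paste("inconsistent evidence: no traversal uses every novel edge",
               "exactly once while matching the copy-number vector")
  }
  ord <- order(st$keys)
  structure(list(walks = st$walks[ord], ambiguous = length(st$walks) > 1,
                 reason = reason, states = st$states),
            class = "cgr_walkset")
}

#' @export
print.cgr_walkset <- function(x, ...) {
  cat(sprintf("Walk set: %d solution(s)%s\n", length(x$walks),
              if (x$ambiguous) " [ambiguous]" else ""))
  if (!is.null(x$reason)) cat("  ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Count breakpoints of a case under the 2-per-SV convention
#'
#' Every DEL/DUP/INV row contributes its two boundary coordinates;
#' identical coordinates (shared boundaries of abutting rows) are
#' deduplicated. Telomeric loss rows (`TELDEL`) are not counted.
#'
#' @param seg A `cgr_segments` table for one case.
#' @return Integer breakpoint count.
#' @export
count_breakpoints <- function(seg) {
  keep <- seg$dosage %in% c("DEL", "DUP", "INV")
  if (!any(keep)) return(0L)
  length(unique(c(seg$start[keep], seg$end[keep])))
}

#' Detect a ring derivative and summarise terminal losses
#'
#' @param walk A `cgr_walk`.
#' @param seg Optional case segment table; segments with no overlap with
#'   the walk's coverage are reported as lost, split into p-arm and q-arm
#'   groups at `cen_mid`.
#' @param cen_mid Centromere midpoint used to split lost segments
#'   (default 11.1e6, the chromosome 21 centromere region).
#' @return List with `ring` (flag), `lost_p`, `lost_q` (labels).
#' @export
detect_ring <- function(walk, seg = NULL, cen_mid = 11.1e6) {
  lost_p <- character(); lost_q <- character()
  if (!is.null(seg) && nrow(seg)) {
    stw <- walk$steps[!walk$steps$gap, , drop = FALSE]
    covered <- function(s, e) any(stw$start < e & stw$end > s)
    lost <- !mapply(covered, seg$start, seg$end)
    lost_p <- seg$label[lost & seg$start < cen_mid]
    lost_q <- seg$label[lost & seg$start >= cen_mid]
  }
  list(ring = isTRUE(walk$circular), lost_p = lost_p, lost_q = lost_q)
}

#' Derive graph inputs from a known walk
#'
#' Disjoins the walk's step intervals into atomic segments, counts how
#' many derivative copies cover each atom (copy number = 1 intact homolog
#' + copies), and extracts the walk's novel adjacencies. This is how the
#' bundled case fixtures and the simulator produce truth inputs for
#' [build_graph()]/[assemble_walk()] round trips.
#'
#' @param walk A `cgr_walk` without gap steps.
#' @param contig_length Contig length.
#' @return List with `segments` (a `cgr_segments` table including
#'   zero-copy deleted atoms), `cn` (copy-number vector) and `junctions`.
#' @export
walk_to_graph_inputs <- function(walk, contig_length) {
  st <- walk$steps
  if (any(st$gap))
    stop("walks with gap steps cannot be converted to graph inputs",
         call. = FALSE)
  L <- as.numeric(contig_length)
  cuts <- sort(unique(c(0, L, st$start, st$end)))
  atoms <- data.frame(start = cuts[-length(cuts)], end = cuts[-1])
  copies <- vapply(seq_len(nrow(atoms)), function(i) {
    sum(st$start <= atoms$start[i] & st$end >= atoms$end[i])
  }, numeric(1))
  dosage <- ifelse(copies == 0, "DEL", ifelse(copies == 1, "NML", "DUP"))
  seg <- segments(case_id = "truth",
                  label = make.unique(rep(LETTERS, length.out = nrow(atoms)),
                                      sep = ""),
                  contig = st$contig[1], start = atoms$start, end = atoms$end,
                  dosage = dosage)
  list(segments = seg, cn = copies + 1, junctions = walk_junctions(walk))
}
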