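# Derivative walks: an ordered, oriented list of reference intervals
# describing the derivative chromosome, possibly circular (ring).
#
# Steps are stored 0-based half-open. A step with gap = TRUE has an
# unresolved extent (unknown partner); its `end` (and possibly `start`)
# may be NA and every join touching it is, by definition, not a reference
# adjacency.

#' Construct a derivative walk
#'
#' @param steps A data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open), `inverted` (logical) and optionally `gap`
#'   (logical, default `FALSE`).
#' @param circular `TRUE` for a ring derivative (the last-to-first join is
#'   part of the walk).
#' @return A `cgr_walk` object.
#' @export
derivative_walk <- function(steps, circular = FALSE) {
  need <- c("contig", "start", "end", "inverted")
  if (!all(need %in% names(steps)))
    stop("steps need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(steps$gap)) steps$gap <- FALSE
  steps <- steps[, c("contig", "start", "end", "inverted", "gap")]
  steps$contig <- as.character(steps$contig)
  steps$start <- as.numeric(steps$start); steps$end <- as.numeric(steps$end)
  ok <- steps$gap | (!is.na(steps$start) & !is.na(steps$end) &
                       steps$start >= 0 & steps$end > steps$start)
  if (!all(ok)) stop("non-gap steps must be valid intervals", call. = FALSE)
  structure(list(steps = steps, circular = isTRUE(circular)), class = "cgr_walk")
}

#' @export
print.cgr_walk <- function(x, ...) {
  cat(sprintf("Derivative walk: %d step(s), %s, %d novel adjacenc%s\n",
              nrow(x$steps), if (x$circular) "circular (ring)" else "linear",
              count_novel_adjacencies(x),
              if (count_novel_adjacencies(x) == 1) "y" else "ies"))
  st <- x$steps
  lab <- ifelse(st$gap,
                paste0(ifelse(is.na(st$start), "?", st$start + 1), "_?"),
                paste0(st$start + 1, "_", st$end,
                       ifelse(st$inverted, " (inv)", "")))
  cat(paste0("  ", seq_len(nrow(st)), ": ", st$contig, ":", lab), sep = "\n")
  invisible(x)
}

# Is the join step i -> step j a reference adjacency? Forward steps abut
# left-to-right (end_i == start_j); inverted steps abut right-to-left
# (start_i == end_j), i.e. the walk keeps reading the reference minus
# strand without interruption.
is_reference_join <- function(steps, i, j) {
  a <- steps[i, ]; b <- steps[j, ]
  if (isTRUE(a$gap) || isTRUE(b$gap)) return(FALSE)
  if (a$contig != b$contig) return(FALSE)
  if (!a$inverted && !b$inverted) return(isTRUE(a$end == b$start))
  if (a$inverted && b$inverted) return(isTRUE(a$start == b$end))
  FALSE
}

#' Join table of a walk
#'
#' One row per join between consecutive steps (plus the closing join for a
#' ring), with a flag for reference adjacency. Every non-reference join is
#' a novel adjacency.
#'
#' @param walk A `cgr_walk`.
#' @return A data.frame with columns `from`, `to`, `reference`, `gap_join`.
#' @export
walk_joins <- function(walk) {
  n <- nrow(walk$steps)
  if (n == 0) return(data.frame(from = integer(), to = integer(),
                                reference = logical(), gap_join = logical()))
  from <- seq_len(n - 1); to <- from + 1
  if (walk$circular && n >= 1) { from <- c(from, n); to <- c(to, 1L) }
  if (length(from) == 0)
    return(data.frame(from = integer(), to = integer(),
                      reference = logical(), gap_join = logical()))
  ref <- mapply(function(i, j) is_reference_join(walk$steps, i, j), from, to)
  gapj <- walk$steps$gap[from] | walk$steps$gap[to]
  data.frame(from = from, to = to, reference = ref, gap_join = gapj)
}

#' Number of novel adjacencies (junctions) in a walk
#'
#' Joins between consecutive steps that are not reference adjacencies,
#' including the closing join of a ring. This equals the junction count of
#' the derivative and is a lower bound on template switches under a
#' replicative model.
#'
#' @param walk A `cgr_walk`.
#' @return Integer count.
#' @export
count_novel_adjacencies <- function(walk) {
  j <- walk_joins(walk)
  sum(!j$reference)
}

#' @rdname count_novel_adjacencies
#' @export
count_template_switches <- function(walk) count_novel_adjacencies(walk)

# Exit breakend of a step: where the derivative leaves the reference copy.
step_exit_breakend <- function(step) {
  if (isTRUE(step$gap)) return(NULL)
  if (!step$inverted) list(contig = step$contig, pos = step$end, side = "L")
  else list(contig = step$contig, pos = step$start + 1, side = "R")
}

# Entry breakend: where the derivative enters the reference copy. A gap
# step with a known start ("pos_?") still has a known entry.
step_entry_breakend <- function(step) {
  if (isTRUE(step$gap)) {
    if (!is.na(step$start) && !step$inverted)
      return(list(contig = step$contig, pos = step$start + 1, side = "R"))
    return(NULL)
  }
  if (!step$inverted) list(contig = step$contig, pos = step$start + 1, side = "R")
  else list(contig = step$contig, pos = step$end, side = "L")
}

#' Junctions realised by a walk
#'
#' Converts every novel join of the walk into a canonical junction record.
#' Joins involving a gap step become junctions with an unresolved partner.
#'
#' @param walk A `cgr_walk`.
#' @param prefix Prefix for generated junction ids.
#' @return A `cgr_junctions` table.
#' @export
walk_junctions <- function(walk, prefix = "J") {
  j <- walk_joins(walk)
  j <- j[!j$reference, , drop = FALSE]
  if (nrow(j) == 0) return(empty_junctions())
  rows <- lapply(seq_len(nrow(j)), function(k) {
    a <- step_exit_breakend(walk$steps[j$from[k], ])
    b <- step_entry_breakend(walk$steps[j$to[k], ])
    if (is.null(a)) a <- list(contig = walk$steps$contig[j$from[k]],
                              pos = NA_real_, side = "L", resolved = FALSE)
    else a$resolved <- TRUE
    if (is.null(b)) b <- list(contig = walk$steps$contig[j$to[k]],
                              pos = NA_real_, side = "R", resolved = FALSE)
    else b$resolved <- TRUE
    data.frame(contig1 = a$contig, pos1 = a$pos, side1 = a$side,
               resolved1 = a$resolved,
               contig2 = b$contig, pos2 = b$pos, side2 = b$side,
               resolved2 = b$resolved, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  junctions(id = paste0(prefix, seq_len(nrow(rows))),
            contig1 = rows$contig1, pos1 = rows$pos1, side1 = rows$side1,
            contig2 = rows$contig2, pos2 = rows$pos2, side2 = rows$side2,
            resolved1 = rows$resolved1, resolved2 = rows$resolved2)
}

#' Normalise a walk
#'
#' Merges runs of reference-contiguous, same-orientation, non-gap steps
#' into single steps (for a ring, also across the closing join). The novel
#' adjacency count is invariant under normalisation.
#'
#' @param walk A `cgr_walk`.
#' @return A `cgr_walk` with maximal steps.
#' @export
normalize_walk <- function(walk) {
  st <- walk$steps
  n <- nrow(st)
  if (n <= 1) return(walk)
  out <- st[1, , drop = FALSE]
  for (i in 2:n) {
    k <- nrow(out)
    if (is_reference_join(rbind(out[k, ], st[i, ]), 1, 2) &&
        identical(out$inverted[k], st$inverted[i])) {
      if (!st$inverted[i]) out$end[k] <- st$end[i] else out$start[k] <- st$start[i]
    } else {
      out <- rbind(out, st[i, ])
    }
  }
  # ring: the last step may continue into the first
  if (walk$circular && nrow(out) > 1) {
    k <- nrow(out)
    if (is_reference_join(rbind(out[k, ], out[1, ]), 1, 2) &&
        identical(out$inverted[k], out$inverted[1])) {
      if (!out$inverted[1]) out$start[1] <- out$start[k] else out$end[1] <- out$end[k]
      out <- out[-k, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  derivative_walk(out, circular = walk$circular)
}

step_serial <- function(st) {
  paste(st$contig,
        ifelse(is.na(st$start), "?", st$start),
        ifelse(is.na(st$end), "?", st$end),
        as.integer(st$inverted), as.integer(st$gap),
        sep = ":", collapse = "|")
}

# Reverse-complement view of a walk (the same molecule read the other way).
flip_walk <- function(walk) {
  st <- walk$steps[rev(seq_len(nrow(walk$steps))), , drop = FALSE]
  st$inverted <- !st$inverted & !st$gap
  rownames(st) <- NULL
  derivative_walk(st, circular = walk$circular)
}

#' Canonical serialisation of a walk
#'
#' Normalises the walk, and for rings picks the lexicographically smallest
#' serialisation over all rotations and the reverse-complement reading;
#' for linear walks the reverse-complement reading is also collapsed.
#' Two walks describe the same derivative molecule iff their canonical
#' serialisations are equal.
#'
#' @param walk A `cgr_walk`.
#' @return A character scalar.
#' @export
canonical_walk <- function(walk) {
  w <- normalize_walk(walk)
  candidates <- character()
  for (v in list(w, flip_walk(w))) {
    n <- nrow(v$steps)
    if (v$circular && n > 1) {
      for (r in seq_len(n)) {
        idx <- c(r:n, if (r > 1) 1:(r - 1))
        candidates <- c(candidates,
                        step_serial(v$steps[idx, , drop = FALSE]))
      }
    } else {
      candidates <- c(candidates, step_serial(v$steps))
    }
  }
  paste0(if (w$circular) "ring|" else "lin|", min(candidates))
}

#' Are two walks the same derivative molecule?
#'
#' @param a,b `cgr_walk` objects.
#' @return Logical flag.
#' @export
walk_equal <- function(a, b) identical(canonical_walk(a), canonical_walk(b))

#' Validate a walk against a junction list
#'
#' Checks the structural invariants of a derivative walk: every interior
#' join (and the closing join of a ring) is either a reference adjacency
#' or matches exactly one junction from `junc`, and no junction is used
#' twice.
#'
#' @param walk A `cgr_walk`.
#' @param junc A `cgr_junctions` table backing the novel joins.
#' @return Invisibly `TRUE`; stops with an informative message otherwise.
#' @export
validate_walk <- function(walk, junc) {
  wj <- walk_junctions(walk)
  if (nrow(wj) == 0) return(invisible(TRUE))
  have <- junction_key(junc)
  used <- junction_key(wj)
  if (anyDuplicated(used))
    stop("walk uses a novel adjacency more than once: ",
         used[duplicated(used)][1], call. = FALSE)
  missing <- setdiff(used, have)
  if (length(missing))
    stop("walk join not backed by any junction: ", missing[1], call. = FALSE)
  invisible(TRUE)
}
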