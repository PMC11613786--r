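# Core genomic data model: intervals, segments, coordinate conventions.
#
# Internally every interval is 0-based half-open [start, end). On-disk
# segment tables (the Table-1 dialect) and all user-facing nomenclature use
# 1-based inclusive coordinates; the two helpers below convert between the
# conventions and are the only place the "+/- 1" lives.

DOSAGE_LEVELS <- c("DEL", "DUP", "INV", "NML", "TELDEL")

#' Construct a genomic interval (0-based half-open)
#'
#' @param contig Contig identifier (e.g. `"chr21"`).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @return A `cgr_interval` object.
#' @examples
#' gi <- genomic_interval("chr21", 0, 10)
#' interval_length(gi)
#' @export
genomic_interval <- function(contig, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 0)
    stop("interval start must be >= 0", call. = FALSE)
  if (end <= start)
    stop(sprintf("empty or reversed interval [%s, %s)", start, end), call. = FALSE)
  structure(list(contig = as.character(contig), start = start, end = end),
            class = "cgr_interval")
}

#' @rdname genomic_interval
#' @param x A `cgr_interval`.
#' @export
interval_length <- function(x) x$end - x$start

#' Convert 1-based inclusive coordinates to internal 0-based half-open
#'
#' @param start,end 1-based inclusive coordinates (Table-1 convention).
#' @return List with elements `start`, `end` in 0-based half-open convention.
#' @export
coords_from_1based <- function(start, end) {
  list(start = as.numeric(start) - 1, end = as.numeric(end))
}

#' Convert internal 0-based half-open coordinates to 1-based inclusive
#'
#' @param start,end 0-based half-open coordinates.
#' @return List with elements `start`, `end` in 1-based inclusive convention.
#' @export
coords_to_1based <- function(start, end) {
  list(start = as.numeric(start) + 1, end = as.numeric(end))
}

#' Construct a segment table
#'
#' A segment is a labelled reference interval with a dosage class, the row
#' unit of the case breakpoint tables. Coordinates here are internal
#' (0-based half-open); use [read_segment_table()] for on-disk tables.
#'
#' @param case_id Case identifier, recycled.
#' @param label Single-letter segment labels, unique within a case.
#' @param contig Contig, recycled.
#' @param start,end 0-based half-open coordinates.
#' @param dosage One of `"DEL"`, `"DUP"`, `"INV"`, `"NML"`, `"TELDEL"`.
#' @param method Free-text detection-method annotation (kept as metadata).
#' @return A `data.frame` of class `cgr_segments`.
#' @export
segments <- function(case_id, label, contig, start, end, dosage,
                     method = NA_character_) {
  df <- data.frame(case_id = as.character(case_id),
                   label = as.character(label),
                   contig = as.character(contig),
                   start = as.numeric(start), end = as.numeric(end),
                   dosage = as.character(dosage),
                   method = as.character(method),
                   stringsAsFactors = FALSE)
  validate_segments(df)
}

validate_segments <- function(df) {
  if (any(df$start < 0) || any(df$end <= df$start))
    stop("segments must have 0 <= start < end", call. = FALSE)
  bad <- setdiff(unique(df$dosage), DOSAGE_LEVELS)
  if (length(bad))
    stop("unknown dosage type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (cid in unique(df$case_id)) {
    lab <- df$label[df$case_id == cid]
    if (anyDuplicated(lab))
      stop("duplicate segment labels within case ", cid, call. = FALSE)
  }
  class(df) <- c("cgr_segments", "data.frame")
  df
}

#' Segment lengths in nucleotides
#'
#' Returns `end - start` of the internal half-open interval, which equals
#' `End - Start + 1` for rows loaded from a 1-based inclusive table.
#'
#' @param seg A `cgr_segments` table (or any data.frame with `start`/`end`).
#' @return Numeric vector of lengths.
#' @export
segment_length <- function(seg) seg$end - seg$start

#' Total length of segments in a dosage class
#'
#' @param seg A `cgr_segments` table from one case.
#' @param dosage_filter Character vector of dosage classes to sum over;
#'   `NULL` sums everything.
#' @return Total nucleotides (0, with a warning, if nothing matches).
#' @export
total_length <- function(seg, dosage_filter = NULL) {
  keep <- if (is.null(dosage_filter)) rep(TRUE, nrow(seg))
          else seg$dosage %in% dosage_filter
  if (!any(keep)) {
    warning("no segments match the dosage filter; total is 0", call. = FALSE)
    return(0)
  }
  sum(segment_length(seg[keep, , drop = FALSE]))
}

#' Round a nucleotide count to megabases
#'
#' @param nt Nucleotides.
#' @param digits Decimal places (default 1, the reporting convention).
#' @return Length in Mb.
#' @export
mb <- function(nt, digits = 1) round(nt / 1e6, digits)

#' Are two intervals reference-adjacent?
#'
#' True iff `a` directly abuts `b` on the same contig (`a$end == b$start`
#' in half-open coordinates). Different contigs give `FALSE`, not an error.
#'
#' @param a,b `cgr_interval` objects.
#' @return Logical flag.
#' @export
reference_adjacent <- function(a, b) {
  if (!identical(a$contig, b$contig)) return(FALSE)
  isTRUE(a$end == b$start)
}
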