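# Breakpoints and novel-adjacency junctions.
#
# A breakend is (contig, pos, side) with pos in 1-based coordinates and
# side saying which reference flank of pos is retained in the derivative:
#   side "L": the sequence left of (and including) pos is retained -- the
#             junction attaches immediately after pos;
#   side "R": the sequence right of (and including) pos is retained -- the
#             junction attaches immediately before pos.
#
# A junction is an unordered pair of breakends. We canonicalise bp1 as the
# lower coordinate and derive the orientation class from the retained
# sides; in BEDPE strand terms (strand1 = "+" iff side1 == "L",
# strand2 = "+" iff side2 == "R"):
#   HT (+,+) deletion-like / reference-orientation join
#   TH (-,-) tandem-duplication-like join
#   HH (+,-) head-to-head inversion junction
#   TT (-,+) tail-to-tail inversion junction

ORIENTATIONS <- c("HT", "HH", "TT", "TH")

#' Construct a breakpoint (breakend)
#'
#' @param contig Contig identifier.
#' @param pos 1-based position (NA allowed when `resolved = FALSE`).
#' @param side `"L"` if the sequence left of `pos` is retained in the
#'   derivative, `"R"` if the right side is retained.
#' @param resolved `FALSE` for unknown ("?") partners, which carry no
#'   position claim.
#' @return A `cgr_breakpoint` object.
#' @export
breakpoint <- function(contig, pos, side, resolved = TRUE) {
  if (!side %in% c("L", "R")) stop("side must be 'L' or 'R'", call. = FALSE)
  if (resolved && (is.na(pos) || pos < 1))
    stop("resolved breakpoints need a position >= 1", call. = FALSE)
  if (!resolved) pos <- NA_real_
  structure(list(contig = as.character(contig), pos = as.numeric(pos),
                 side = side, resolved = resolved),
            class = "cgr_breakpoint")
}

orientation_from_sides <- function(side1, side2) {
  key <- paste0(side1, side2)
  c(LR = "HT", LL = "HH", RR = "TT", RL = "TH")[[key]]
}

sides_from_orientation <- function(orientation) {
  key <- c(HT = "LR", HH = "LL", TT = "RR", TH = "RL")[[orientation]]
  c(substr(key, 1, 1), substr(key, 2, 2))
}

#' Map between junction orientation classes and BEDPE strand pairs
#'
#' The fixed encoding is HT=(+,+), HH=(+,-), TT=(-,+), TH=(-,-).
#'
#' @param orientation One of `"HT"`, `"HH"`, `"TT"`, `"TH"`.
#' @return Character vector `c(strand1, strand2)`.
#' @export
orientation_to_strands <- function(orientation) {
  switch(orientation,
         HT = c("+", "+"), HH = c("+", "-"),
         TT = c("-", "+"), TH = c("-", "-"),
         stop("unknown orientation: ", orientation, call. = FALSE))
}

#' @rdname orientation_to_strands
#' @param strand1,strand2 BEDPE strand characters.
#' @export
strands_to_orientation <- function(strand1, strand2) {
  key <- paste0(strand1, strand2)
  out <- c("++" = "HT", "+-" = "HH", "-+" = "TT", "--" = "TH")[key]
  if (any(is.na(out))) stop("malformed strand pair: ", key[is.na(out)][1], call. = FALSE)
  unname(out)
}

#' Construct a junction table
#'
#' Each row is one novel adjacency between two breakends. Rows are stored
#' in canonical form: bp1 at the lower coordinate (unresolved breakends are
#' always bp2), with the orientation class derived from the retained sides.
#'
#' @param id Junction identifiers.
#' @param contig1,pos1,side1 First breakend (1-based position, retained side).
#' @param contig2,pos2,side2 Second breakend; `pos2 = NA` with
#'   `resolved2 = FALSE` encodes an unknown partner.
#' @param resolved1,resolved2 Logical; unresolved breakends carry no position.
#' @param seq Optional junction-spanning sequence (derivative orientation,
#'   `NA` when unobserved).
#' @return A `data.frame` of class `cgr_junctions` with an `orientation`
#'   column.
#' @export
junctions <- function(id, contig1, pos1, side1, contig2, pos2, side2,
                      resolved1 = TRUE, resolved2 = TRUE, seq = NA_character_) {
  n <- length(id)
  df <- data.frame(id = as.character(id),
                   contig1 = as.character(contig1), pos1 = as.numeric(pos1),
                   side1 = as.character(side1),
                   resolved1 = rep_len(resolved1, n),
                   contig2 = as.character(contig2), pos2 = as.numeric(pos2),
                   side2 = as.character(side2),
                   resolved2 = rep_len(resolved2, n),
                   seq = rep_len(as.character(seq), n),
                   stringsAsFactors = FALSE)
  if (any(!df$side1 %in% c("L", "R")) || any(!df$side2 %in% c("L", "R")))
    stop("breakend sides must be 'L' or 'R'", call. = FALSE)
  if (any(df$resolved1 & (is.na(df$pos1) | df$pos1 < 1)))
    stop("resolved breakends need positions >= 1", call. = FALSE)
  if (any(!is.na(df$seq) & !nzchar(df$seq)))
    stop("junction_seq, when present, must be non-empty", call. = FALSE)
  df <- canonicalize_junctions(df)
  class(df) <- c("cgr_junctions", "data.frame")
  df
}

# bp1 = lower coordinate (resolved breakends first); swapping breakends
# preserves each breakend's retained side.
canonicalize_junctions <- function(df) {
  swap <- (!df$resolved1 & df$resolved2) |
    (df$resolved1 & df$resolved2 &
       (df$contig1 > df$contig2 |
          (df$contig1 == df$contig2 & df$pos1 > df$pos2)))
  swap[is.na(swap)] <- FALSE
  if (any(swap)) {
    tmp <- df[swap, c("contig1", "pos1", "side1", "resolved1")]
    df[swap, c("contig1", "pos1", "side1", "resolved1")] <-
      df[swap, c("contig2", "pos2", "side2", "resolved2")]
    df[swap, c("contig2", "pos2", "side2", "resolved2")] <- tmp
  }
  df$orientation <- if (nrow(df) == 0) character(0) else
    mapply(orientation_from_sides, df$side1, df$side2)
  df
}

junction_key <- function(df) {
  paste(df$contig1, df$pos1, df$side1, df$contig2, df$pos2, df$side2, sep = ":")
}

empty_junctions <- function() {
  junctions(id = character(), contig1 = character(), pos1 = numeric(),
            side1 = character(), contig2 = character(), pos2 = numeric(),
            side2 = character())
}
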