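# Minimal read-depth copy-number caller: normalised binned depth to
# integer CN segments. Intentionally simple -- median normalisation, no
# GC correction -- sufficient for the synthetic references used here and
# documented as such for real data.

#' Normalise a depth profile to copy ratios
#'
#' @param depth A `cgr_depth` data.frame (`contig`, `bin_start`,
#'   `bin_end`, `mean_depth`).
#' @return The same data.frame with a `ratio` column
#'   (`mean_depth / genome median`); ratio 1 corresponds to CN 2.
#' @export
normalize_depth <- function(depth) {
  med <- stats::median(depth$mean_depth)
  if (is.na(med) || med <= 0) stop("median depth is not positive", call. = FALSE)
  depth$ratio <- depth$mean_depth / med
  attr(depth, "median_depth") <- med
  depth
}

round_half_up <- function(x) floor(x + 0.5)

#' Segment copy ratios into integer copy-number calls
#'
#' Greedy run-length merge of consecutive bins with equal
#' `round(2 * ratio)` (half-up); runs shorter than `min_bins` are
#' absorbed into the longer neighbouring run; the final CN of a segment
#' is `round(2 * mean ratio)` over its bins.
#'
#' @param depth Output of [normalize_depth()].
#' @param min_bins Minimum run length kept as its own segment (default 3).
#' @return A data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `n_bins`, `cn`.
#' @export
segment_cn <- function(depth, min_bins = 3) {
  out <- lapply(split(seq_len(nrow(depth)), depth$contig), function(idx) {
    d <- depth[idx, , drop = FALSE]
    cnb <- round_half_up(2 * d$ratio)
    r <- rle(cnb)
    # absorb short runs into the larger neighbour (ties: the left one)
    while (length(r$lengths) > 1 && any(r$lengths < min_bins)) {
      k <- which(r$lengths < min_bins)[1]
      nb <- c(if (k > 1) k - 1, if (k < length(r$lengths)) k + 1)
      tgt <- nb[which.max(r$lengths[nb])]
      r$values[k] <- r$values[tgt]
      r <- rle(inverse.rle(r))
    }
    ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    data.frame(contig = d$contig[1],
               start = d$bin_start[starts], end = d$bin_end[ends],
               n_bins = r$lengths,
               cn = vapply(seq_along(starts), function(i)
                 round_half_up(2 * mean(d$ratio[starts[i]:ends[i]])),
                 numeric(1)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
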