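# Trio-based parental-origin phasing of the rearranged homolog.
#
# At an informative site one parent is homozygous alternate and the other
# homozygous reference, so the parental origin of the allele(s) the child
# carries is identifiable:
#   child het      -> the alternate allele came from the hom-alt parent;
#   child hom-alt  -> only the hom-alt parent's allele is present
#                     (hemizygosity: the other parent's allele is lost);
#   child hom-ref  -> the hom-alt parent's allele is absent, the carried
#                     allele is the hom-ref parent's.
# The per-segment paternal fraction is the share of informative sites
# attributed to the father. Diploid segments sit at 0.5; hemizygous
# (deleted) segments go to 0 or 1 and implicate the *other* homolog as
# rearranged; duplicated segments shift with the dosage of the carrier
# haplotype (2 of 3 copies).

attribute_site <- function(informative, gt_child) {
  if (informative == "uninformative") return(NA_character_)
  hom_alt_parent <- informative  # "paternal" or "maternal"
  other <- if (informative == "paternal") "maternal" else "paternal"
  if (gt_child %in% c("0/1", "1/0")) return(hom_alt_parent)
  if (gt_child == "1/1") return(hom_alt_parent)
  if (gt_child == "0/0") return(other)
  NA_character_
}

#' Per-segment parental allele fractions
#'
#' @param sites Phase-informative site table from [read_phased_snvs()].
#' @param seg A `cgr_segments` table (internal 0-based coordinates).
#' @return A data.frame: `label`, `dosage`, `n_informative`,
#'   `paternal_fraction`, `maternal_fraction` (`NA` fractions for
#'   segments without informative sites).
#' @export
segment_allele_fractions <- function(sites, seg) {
  inf <- sites[sites$informative != "uninformative", , drop = FALSE]
  attr_to <- mapply(attribute_site, inf$informative, inf$gt_child)
  out <- lapply(seq_len(nrow(seg)), function(i) {
    inseg <- inf$chrom == seg$contig[i] &
      inf$pos > seg$start[i] & inf$pos <= seg$end[i]
    a <- attr_to[inseg & !is.na(attr_to)]
    n <- length(a)
    data.frame(label = seg$label[i], dosage = seg$dosage[i],
               n_informative = n,
               paternal_fraction = if (n) mean(a == "paternal") else NA_real_,
               maternal_fraction = if (n) mean(a == "maternal") else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Welch two-sample test of affected versus control paternal fractions
#'
#' @param affected_fractions Paternal fractions of rearranged segments
#'   (for deleted segments, pass the carrier-implied fraction: see
#'   [phase_case()]).
#' @param control_fractions Paternal fractions of unaffected diploid
#'   segments.
#' @return List `t`, `p`, `n_affected`, `n_control`; `p = NA` with an
#'   explanation when either group has fewer than 2 usable values.
#' @export
origin_test <- function(affected_fractions, control_fractions) {
  a <- affected_fractions[!is.na(affected_fractions)]
  b <- control_fractions[!is.na(control_fractions)]
  if (length(a) < 2 || length(b) < 2)
    return(list(t = NA_real_, p = NA_real_, n_affected = length(a),
                n_control = length(b),
                note = "fewer than 2 segments per group"))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constant groups
    if (mean(a) == mean(b))
      return(list(t = 0, p = 1, n_affected = length(a), n_control = length(b)))
    return(list(t = Inf * sign(mean(a) - mean(b)), p = 0,
                n_affected = length(a), n_control = length(b)))
  }
  tt <- stats::t.test(a, b, alternative = "two.sided", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       n_affected = length(a), n_control = length(b))
}

#' Origin call from a completed test
#'
#' @param affected_mean Mean carrier-implied paternal fraction of the
#'   affected segments.
#' @param control_mean Mean paternal fraction of control segments.
#' @param p Two-sided p value from [origin_test()].
#' @param alpha Significance level (default 0.05).
#' @return `"PATERNAL"`, `"MATERNAL"` or `"INCONCLUSIVE"`.
#' @export
call_origin <- function(affected_mean, control_mean, p, alpha = 0.05) {
  if (is.na(p) || p >= alpha || is.na(affected_mean) || is.na(control_mean))
    return("INCONCLUSIVE")
  if (affected_mean > control_mean) "PATERNAL" else "MATERNAL"
}

#' Phase a case: fractions, test and origin call
#'
#' Affected segments are the DEL/DUP/TELDEL rows; everything else with
#' informative sites serves as diploid control. For deleted segments the
#' transmitted-allele logic is inverted (the remaining allele's parent is
#' the unaffected homolog), so their carrier-implied paternal fraction is
#' `1 - paternal_fraction`.
#'
#' @param sites Phase-informative site table.
#' @param seg A `cgr_segments` table.
#' @param alpha Significance level (default 0.05, two-sided, no
#'   multiple-testing correction).
#' @return A `cgr_phasing` list: `per_segment`, `test`, `origin_call`.
#' @export
phase_case <- function(sites, seg, alpha = 0.05) {
  fr <- segment_allele_fractions(sites, seg)
  affected <- fr$dosage %in% c("DEL", "DUP", "TELDEL")
  usable <- !is.na(fr$paternal_fraction)
  implied <- ifelse(fr$dosage %in% c("DEL", "TELDEL"),
                    1 - fr$paternal_fraction, fr$paternal_fraction)
  test <- origin_test(implied[affected & usable],
                      fr$paternal_fraction[!affected & usable])
  call <- call_origin(mean(implied[affected & usable]),
                      mean(fr$paternal_fraction[!affected & usable]),
                      test$p, alpha = alpha)
  structure(list(per_segment = fr, test = test, origin_call = call),
            class = "cgr_phasing")
}

#' @export
print.cgr_phasing <- function(x, ...) {
  cat(sprintf("Parental origin: %s (t = %s, p = %s; %d affected vs %d control segments)\n",
              x$origin_call,
              if (is.na(x$test$t)) "NA" else sprintf("%.2f", x$test$t),
              if (is.na(x$test$p)) "NA" else format.pval(x$test$p, digits = 3),
              x$test$n_affected, x$test$n_control))
  invisible(x)
}
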