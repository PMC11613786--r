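# Per-case orchestration: run the available stages over a case bundle
# and summarise them in a stable, JSON-serialisable report; plus a
# Circos-style derivative plot.

#' Run all available pipeline stages for one case
#'
#' Executes segment summaries, walk reconstruction (from the bundle's
#' junctions and, when present, its karyotype string), junction
#' signatures (needs `fasta`), phasing (needs `trio`) and copy-number
#' calling (needs `depth`), skipping stages whose inputs are missing and
#' recording which ran.
#'
#' @param bundle A `cgr_bundle`.
#' @param fasta Optional named `DNAStringSet` reference.
#' @param trio Optional list with `child`, `father`, `mother` VCF paths.
#' @param depth Optional `cgr_depth` data.frame.
#' @param contig_length Contig length; defaults to the bundle metadata.
#' @return A `cgr_report` list.
#' @export
run_case <- function(bundle, fasta = NULL, trio = NULL, depth = NULL,
                     contig_length = NULL) {
  if (!inherits(bundle, "cgr_bundle")) stop("need a cgr_bundle", call. = FALSE)
  seg <- bundle$segments
  if (is.null(seg) || nrow(seg) == 0)
    stop("empty bundle: no segments", call. = FALSE)
  contig_length <- contig_length %||% bundle$metadata$contig_length
  stages <- character()

  seg_summary <- lapply(split(seq_len(nrow(seg)), seg$dosage), function(i)
    list(n = length(i), total_nt = sum(segment_length(seg[i, , drop = FALSE]))))
  seg_summary <- seg_summary[order(names(seg_summary))]
  stages <- c(stages, "segments")

  walk <- bundle$metadata$nomenclature_walk
  walk_summary <- NULL
  if (!is.null(walk)) {
    ring <- detect_ring(walk, seg)
    walk_summary <- list(
      steps = nrow(walk$steps),
      junctions = count_novel_adjacencies(walk),
      template_switches = count_template_switches(walk),
      breakpoints = count_breakpoints(seg),
      ring = ring$ring,
      lost_terminal_p = as.list(ring$lost_p),
      lost_terminal_q = as.list(ring$lost_q),
      gaps = sum(walk$steps$gap))
    stages <- c(stages, "reconstruct")
  }

  sig_summary <- NULL
  mech <- NULL
  if (!is.null(fasta) && nrow(bundle$junctions) > 0) {
    sig <- junction_signatures(bundle$junctions, fasta)
    mh <- sig$microhomology_len[sig$microhomology_len > 0]
    sig_summary <- list(
      n_resolved = nrow(sig),
      n_microhomology = sum(sig$microhomology_len > 0),
      microhomology_range = if (length(mh)) c(min(mh), max(mh)) else c(0, 0),
      n_blunt = sum(sig$blunt),
      n_nontemplated = sum(sig$insertion_origin == "NONTEMPLATED"),
      n_templated = sum(sig$insertion_origin == "TEMPLATED"))
    if (!is.null(walk)) mech <- call_mechanism(sig, walk)
    stages <- c(stages, "signature")
  }

  phasing <- NULL
  if (!is.null(trio)) {
    sites <- read_phased_snvs(trio$child, trio$father, trio$mother)
    ph <- phase_case(sites, seg)
    phasing <- list(origin_call = ph$origin_call, t = ph$test$t,
                    p = ph$test$p, n_affected = ph$test$n_affected,
                    n_control = ph$test$n_control)
    stages <- c(stages, "phasing")
  }

  cn <- NULL
  if (!is.null(depth)) {
    cn <- segment_cn(normalize_depth(depth))
    stages <- c(stages, "copy_number")
  }

  structure(list(schema_version = "1.0",
                 case_id = bundle$case_id,
                 stages_run = stages,
                 segments = seg_summary,
                 walk = walk_summary,
                 signatures = sig_summary,
                 mechanism = mech,
                 phasing = phasing,
                 copy_number = cn,
                 nomenclature = bundle$karyotype_string,
                 diagnostics = bundle$metadata$nomenclature_diagnostics),
            class = "cgr_report")
}

#' Write a case report as stable JSON
#'
#' Fixed key order, no timestamps: identical inputs give byte-identical
#' output.
#'
#' @param report A `cgr_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Circos-style plot of a derivative walk
#'
#' Draws the reference contig as a circle, colours each walk step by its
#' role (green for steps covering gained regions, blue for inverted
#' steps) against lost regions in red, and draws one chord per novel
#' adjacency.
#'
#' @param walk A `cgr_walk`.
#' @param out_png Output PNG path.
#' @param contig_length Contig length (defaults to the maximum step end).
#' @return Invisibly, `out_png`.
#' @export
plot_derivative <- function(walk, out_png, contig_length = NULL) {
  st <- walk$steps[!walk$steps$gap, , drop = FALSE]
  L <- contig_length %||% max(st$end)
  theta <- function(pos) 2 * pi * pos / L
  grDevices::png(out_png, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 3, 1))
  graphics::plot(NA, xlim = c(-1.25, 1.25), ylim = c(-1.25, 1.25), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("Derivative walk (%s; %d junctions)",
                                if (walk$circular) "ring" else "linear",
                                count_novel_adjacencies(walk)))
  tt <- seq(0, 2 * pi, length.out = 720)
  graphics::lines(cos(tt), sin(tt), col = "grey70", lwd = 10)

  # dosage colouring from step coverage
  cuts <- sort(unique(c(0, L, st$start, st$end)))
  a0 <- cuts[-length(cuts)]; a1 <- cuts[-1]
  cov <- vapply(seq_along(a0), function(i)
    sum(st$start <= a0[i] & st$end >= a1[i]), numeric(1))
  colr <- ifelse(cov == 0, "firebrick", ifelse(cov >= 2, "forestgreen", "grey40"))
  for (i in seq_along(a0)) {
    ts <- seq(theta(a0[i]), theta(a1[i]), length.out = 50)
    graphics::lines(cos(ts), sin(ts), col = colr[i], lwd = 10)
  }
  inv <- st[st$inverted, , drop = FALSE]
  for (i in seq_len(nrow(inv))) {
    ts <- seq(theta(inv$start[i]), theta(inv$end[i]), length.out = 50)
    graphics::lines(1.08 * cos(ts), 1.08 * sin(ts), col = "royalblue", lwd = 4)
  }
  # chords for novel adjacencies
  jn <- walk_junctions(walk)
  jn <- jn[jn$resolved1 & jn$resolved2, , drop = FALSE]
  for (i in seq_len(nrow(jn))) {
    t1 <- theta(jn$pos1[i]); t2 <- theta(jn$pos2[i])
    p1 <- c(cos(t1), sin(t1)); p2 <- c(cos(t2), sin(t2))
    # quadratic Bezier chord pulled through the origin
    s <- seq(0, 1, length.out = 100)
    xy <- sapply(s, function(u) (1 - u)^2 * p1 + 2 * u * (1 - u) * c(0, 0) +
                   u^2 * p2)
    graphics::lines(xy[1, ], xy[2, ], col = grDevices::adjustcolor("steelblue", 0.8))
  }
  graphics::legend("bottomright", bty = "n",
                   legend = c("gain", "loss", "inverted", "junction"),
                   col = c("forestgreen", "firebrick", "royalblue", "steelblue"),
                   lwd = c(8, 8, 4, 1))
  invisible(out_png)
}
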