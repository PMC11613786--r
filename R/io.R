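# Readers and writers for the on-disk formats: the Table-1 segment TSV
# dialect (1-based inclusive coordinates, columns Segment/Start/End/Type
# [/Method]), BEDPE junction files, a minimal VCF 4.2 subset (BND bracket
# records and GT/QUAL genotype records), per-bin depth TSVs and FASTA
# (through Biostrings).

#' Read a segment table in the Table-1 TSV dialect
#'
#' Expected columns: `Segment`, `Start`, `End`, `Type` and optionally
#' `Method`. Coordinates are 1-based inclusive and converted to the
#' internal 0-based half-open convention. `Type` values DEL/DUP/INV map
#' directly; rows labelled `Tel` (telomeric loss, `Start` may be `pter`)
#' map to `TELDEL`.
#'
#' @param path TSV file.
#' @param case_id Case identifier attached to every row.
#' @param contig Contig name (default `"chr21"`).
#' @return A `cgr_segments` table in file order.
#' @export
read_segment_table <- function(path, case_id, contig = "chr21") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Segment", "Start", "End", "Type")
  if (!all(need %in% names(df)))
    stop("segment table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  start <- ifelse(tolower(df$Start) == "pter", "1", gsub(",", "", df$Start))
  start <- as.numeric(start)
  end <- as.numeric(gsub(",", "", df$End))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop(sprintf("row %d (segment %s): invalid coordinates Start=%s End=%s",
                 bad[1], df$Segment[bad[1]], df$Start[bad[1]], df$End[bad[1]]),
         call. = FALSE)
  dosage <- ifelse(df$Segment == "Tel", "TELDEL", df$Type)
  unknown <- setdiff(unique(dosage), DOSAGE_LEVELS)
  if (length(unknown))
    stop("unknown Type value(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cc <- coords_from_1based(start, end)
  segments(case_id = case_id, label = df$Segment, contig = contig,
           start = cc$start, end = cc$end, dosage = dosage,
           method = if ("Method" %in% names(df)) df$Method else NA_character_)
}

#' Write a segment table in the Table-1 TSV dialect
#'
#' @param seg A `cgr_segments` table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_segment_table <- function(seg, path) {
  cc <- coords_to_1based(seg$start, seg$end)
  out <- data.frame(Segment = seg$label,
                    Start = format(cc$start, scientific = FALSE, trim = TRUE),
                    End = format(cc$end, scientific = FALSE, trim = TRUE),
                    Type = ifelse(seg$dosage == "TELDEL", "DEL", seg$dosage),
                    Method = ifelse(is.na(seg$method), "", seg$method))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ----------------------------------------------------------------- BEDPE --

#' Read junctions from a BEDPE file
#'
#' Standard 10-column BEDPE (chrom1 start1 end1 chrom2 start2 end2 name
#' score strand1 strand2) with an optional 11th column carrying the
#' junction-spanning sequence. Breakend positions are taken as `end1`/
#' `end2` (1-based); strands decode to retained sides under the fixed
#' mapping HT=(+,+), HH=(+,-), TT=(-,+), TH=(-,-). A `.` in the partner
#' chrom marks an unresolved breakend.
#'
#' @param path BEDPE file.
#' @param fasta Optional `DNAStringSet`; when given, coordinates are
#'   checked against contig bounds.
#' @return A `cgr_junctions` table (empty, with a warning, for an empty
#'   file).
#' @export
read_junctions_bedpe <- function(path, fasta = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    warning("empty BEDPE: no junctions read", call. = FALSE)
    return(empty_junctions())
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(f, length, 0L)
  if (any(ncol < 10)) stop("BEDPE needs at least 10 columns", call. = FALSE)
  get <- function(k) vapply(f, `[[`, "", k)
  strand1 <- get(9); strand2 <- get(10)
  if (any(!strand1 %in% c("+", "-")) || any(!strand2 %in% c("+", "-")))
    stop("malformed strand column in BEDPE", call. = FALSE)
  orientation <- strands_to_orientation(strand1, strand2)
  sides <- t(vapply(orientation, sides_from_orientation, character(2)))
  pos1 <- as.numeric(get(3)); pos2 <- as.numeric(get(6))
  contig2 <- get(4)
  unres2 <- contig2 == "."
  if (!is.null(fasta)) {
    lens <- stats::setNames(Biostrings::width(fasta), names(fasta))
    bad <- pos1 > lens[get(1)] | (!unres2 & pos2 > lens[contig2])
    if (any(bad, na.rm = TRUE))
      stop("BEDPE coordinates beyond contig end (line ",
           which(bad)[1], ")", call. = FALSE)
  }
  seq <- ifelse(ncol >= 11, vapply(f, function(x)
    if (length(x) >= 11 && nzchar(x[11]) && x[11] != ".") x[11]
    else NA_character_, ""), NA_character_)
  junctions(id = get(7),
            contig1 = get(1), pos1 = pos1, side1 = sides[, 1],
            contig2 = ifelse(unres2, get(1), contig2),
            pos2 = ifelse(unres2, NA_real_, pos2), side2 = sides[, 2],
            resolved2 = !unres2, seq = seq)
}

#' Write junctions to a BEDPE file
#'
#' @param junc A `cgr_junctions` table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junctions_bedpe <- function(junc, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  strands <- t(vapply(junc$orientation, orientation_to_strands, character(2)))
  lines <- vapply(seq_len(nrow(junc)), function(i) {
    unres <- !junc$resolved2[i]
    paste(junc$contig1[i], fmt(junc$pos1[i] - 1), fmt(junc$pos1[i]),
          if (unres) "." else junc$contig2[i],
          if (unres) "-1" else fmt(junc$pos2[i] - 1),
          if (unres) "0" else fmt(junc$pos2[i]),
          junc$id[i], ".", strands[i, 1], strands[i, 2],
          if (is.na(junc$seq[i])) "." else junc$seq[i],
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------ minimal VCF --

# Parse the body of a minimal VCF into a data.frame of the fixed columns
# plus QUAL as numeric and the first sample's GT.
read_vcf_body <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body))
    return(data.frame(chrom = character(), pos = numeric(), id = character(),
                      ref = character(), alt = character(), qual = numeric(),
                      info = character(), gt = character(),
                      line = integer()))
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(k) vapply(f, function(x) if (length(x) >= k) x[k] else NA_character_, "")
  gt <- vapply(f, function(x) {
    if (length(x) < 10) return(NA_character_)
    fmt <- strsplit(x[9], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    if (is.na(gi)) return(NA_character_)
    strsplit(x[10], ":", fixed = TRUE)[[1]][gi]
  }, "")
  data.frame(chrom = get(1), pos = as.numeric(get(2)), id = get(3),
             ref = get(4), alt = get(5),
             qual = suppressWarnings(as.numeric(get(6))),
             info = get(8), gt = gt,
             line = which(!startsWith(lines, "#") & nzchar(lines)),
             stringsAsFactors = FALSE)
}

# Decode one bracket ALT; returns list(side, mate_contig, mate_pos,
# mate_side) or NULL for a non-BND ALT.
parse_bnd_alt <- function(alt, line) {
  m <- regmatches(alt, regexec(
    "^([ACGTNacgtn]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([ACGTNacgtn]*)$",
    alt, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  pre <- m[2]; b1 <- m[3]; mctg <- m[4]; mpos <- as.numeric(m[5])
  b2 <- m[6]; post <- m[7]
  if (b1 != b2 || (nzchar(pre) == nzchar(post)))
    stop(sprintf("malformed bracket ALT '%s' at VCF line %d", alt, line),
         call. = FALSE)
  if (nzchar(pre)) {
    # t[p[ : retain left, mate retains right; t]p] : retain left, mate left
    list(side = "L", mate_contig = mctg, mate_pos = mpos,
         mate_side = if (b1 == "[") "R" else "L")
  } else {
    # ]p]t : retain right, mate retains left; [p[t : retain right, mate right
    list(side = "R", mate_contig = mctg, mate_pos = mpos,
         mate_side = if (b1 == "]") "L" else "R")
  }
}

info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))[[1]]
  if (length(m)) m[2] else NA_character_
}

#' Read breakend (BND) junctions from a VCF
#'
#' Minimal VCF 4.2 subset: BND records with bracket ALT notation, mates
#' paired by the `MATEID` INFO key. Each mate pair yields one junction;
#' unpaired breakends are reported and skipped.
#'
#' @param path VCF file.
#' @return A `cgr_junctions` table.
#' @export
read_vcf_bnd <- function(path) {
  v <- read_vcf_body(path)
  if (!nrow(v)) return(empty_junctions())
  dec <- lapply(seq_len(nrow(v)), function(i) parse_bnd_alt(v$alt[i], v$line[i]))
  keep <- !vapply(dec, is.null, TRUE)
  v <- v[keep, , drop = FALSE]; dec <- dec[keep]
  if (!nrow(v)) return(empty_junctions())
  mate <- vapply(v$info, info_field, "", key = "MATEID")
  idx <- match(mate, v$id)
  out <- list()
  done <- rep(FALSE, nrow(v))
  skipped <- 0L
  for (i in seq_len(nrow(v))) {
    if (done[i]) next
    j <- idx[i]
    if (is.na(j) || idx[j] != i) { skipped <- skipped + 1L; next }
    done[i] <- TRUE; done[j] <- TRUE
    d <- dec[[i]]
    # cross-check the mate record's view of this breakend
    out[[length(out) + 1L]] <- data.frame(
      id = sub("_[12]$", "", v$id[i]),
      contig1 = v$chrom[i], pos1 = v$pos[i], side1 = d$side,
      contig2 = d$mate_contig, pos2 = d$mate_pos, side2 = d$mate_side,
      seq = NA_character_, stringsAsFactors = FALSE)
  }
  if (skipped)
    warning(sprintf("%d unpaired BND record(s) skipped", skipped),
            call. = FALSE)
  if (!length(out)) return(empty_junctions())
  df <- do.call(rbind, out)
  junctions(id = df$id, contig1 = df$contig1, pos1 = df$pos1,
            side1 = df$side1, contig2 = df$contig2, pos2 = df$pos2,
            side2 = df$side2, seq = df$seq)
}

#' Write junctions as VCF BND mate pairs
#'
#' @param junc A `cgr_junctions` table (resolved junctions only; rows
#'   with an unresolved partner are written as single breakends without a
#'   mate).
#' @param path Output path.
#' @param contig_lengths Named vector for the `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf_bnd <- function(junc, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Mate id\">")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%s>", names(contig_lengths),
                          format(contig_lengths, scientific = FALSE,
                                 trim = TRUE)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  alt_of <- function(side, mctg, mpos, mside) {
    locus <- paste0(mctg, ":", fmt(mpos))
    if (side == "L") {
      if (mside == "R") paste0("N[", locus, "[") else paste0("N]", locus, "]")
    } else {
      if (mside == "L") paste0("]", locus, "]N") else paste0("[", locus, "[N")
    }
  }
  recs <- character()
  for (i in seq_len(nrow(junc))) {
    if (junc$resolved2[i]) {
      id1 <- paste0(junc$id[i], "_1"); id2 <- paste0(junc$id[i], "_2")
      recs <- c(recs,
                paste(junc$contig1[i], fmt(junc$pos1[i]), id1, "N",
                      alt_of(junc$side1[i], junc$contig2[i], junc$pos2[i],
                             junc$side2[i]),
                      "60", "PASS", paste0("SVTYPE=BND;MATEID=", id2),
                      sep = "\t"),
                paste(junc$contig2[i], fmt(junc$pos2[i]), id2, "N",
                      alt_of(junc$side2[i], junc$contig1[i], junc$pos1[i],
                             junc$side1[i]),
                      "60", "PASS", paste0("SVTYPE=BND;MATEID=", id1),
                      sep = "\t"))
    } else {
      recs <- c(recs,
                paste(junc$contig1[i], fmt(junc$pos1[i]),
                      paste0(junc$id[i], "_1"), "N", ".", "60", "PASS",
                      "SVTYPE=BND", sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# ------------------------------------------------------- trio SNV VCFs ----

read_snv_vcf <- function(path) {
  v <- read_vcf_body(path)
  v$gt <- gsub("|", "/", v$gt, fixed = TRUE)
  v
}

classify_trio_site <- function(gt_f, gt_m) {
  # informative iff one parent is hom-alt and the other hom-ref
  if (gt_f == "1/1" && gt_m == "0/0") return("paternal")
  if (gt_f == "0/0" && gt_m == "1/1") return("maternal")
  "uninformative"
}

#' Read trio genotypes and extract phase-informative sites
#'
#' Joins three minimal VCFs (child, father, mother) on chrom/pos,
#' retains sites with `QUAL` strictly greater than `min_qual` in all
#' three samples, and annotates each as paternal-informative (father
#' hom-alt, mother hom-ref), maternal-informative (the reverse), or
#' uninformative. Sites with a missing GT in any sample are skipped and
#' counted.
#'
#' @param path_child,path_father,path_mother Minimal VCFs with GT + QUAL.
#' @param min_qual Strict lower bound on QUAL (default 40; a site at
#'   exactly 40 is excluded).
#' @return A data.frame of sites: `chrom`, `pos`, `qual`, `gt_child`,
#'   `gt_father`, `gt_mother`, `informative`; the number of skipped
#'   sites is in `attr(, "skipped")`.
#' @export
read_phased_snvs <- function(path_child, path_father, path_mother,
                             min_qual = 40) {
  trio_sites(read_snv_vcf(path_child), read_snv_vcf(path_father),
             read_snv_vcf(path_mother), min_qual = min_qual)
}

#' @rdname read_phased_snvs
#' @param child,father,mother Site tables with columns `chrom`, `pos`,
#'   `qual`, `gt` (as read from VCF or produced by
#'   [simulate_trio_snvs()]).
#' @export
trio_sites <- function(child, father, mother, min_qual = 40) {
  ch <- child; fa <- father; mo <- mother
  key <- function(v) paste(v$chrom, v$pos)
  common <- Reduce(intersect, list(key(ch), key(fa), key(mo)))
  ch <- ch[match(common, key(ch)), , drop = FALSE]
  fa <- fa[match(common, key(fa)), , drop = FALSE]
  mo <- mo[match(common, key(mo)), , drop = FALSE]
  qual <- pmin(ch$qual, fa$qual, mo$qual)
  miss <- is.na(ch$gt) | is.na(fa$gt) | is.na(mo$gt) |
    ch$gt == "./." | fa$gt == "./." | mo$gt == "./."
  skipped <- sum(miss)
  keep <- !miss & !is.na(qual) & qual > min_qual
  out <- data.frame(chrom = ch$chrom[keep], pos = ch$pos[keep],
                    qual = qual[keep], gt_child = ch$gt[keep],
                    gt_father = fa$gt[keep], gt_mother = mo$gt[keep],
                    stringsAsFactors = FALSE)
  out$informative <- mapply(classify_trio_site, out$gt_father, out$gt_mother)
  attr(out, "skipped") <- skipped
  out
}

#' Write a minimal single-sample SNV VCF
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`, `qual`, `gt`.
#' @param path Output path.
#' @param sample Sample name for the header.
#' @return Invisibly, `path`.
#' @export
write_snv_vcf <- function(sites, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  recs <- paste(sites$chrom, format(sites$pos, scientific = FALSE, trim = TRUE),
                ".", sites$ref, sites$alt,
                format(sites$qual, trim = TRUE), "PASS", ".", "GT", sites$gt,
                sep = "\t")
  writeLines(c(hdr, recs), path)
  invisible(path)
}

# --------------------------------------------------------------- depth ----

#' Read a per-bin depth TSV
#'
#' Columns: `contig`, `bin_start` (0-based), `bin_end`, `mean_depth`.
#'
#' @param path TSV file.
#' @return A `cgr_depth` data.frame sorted by position.
#' @export
read_depth_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "bin_start", "bin_end", "mean_depth")
  if (!all(need %in% names(df)))
    stop("depth TSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$contig, df$bin_start), , drop = FALSE]
  if (any(df$bin_start[-1] < df$bin_end[-nrow(df)] &
            df$contig[-1] == df$contig[-nrow(df)]))
    stop("depth bins overlap", call. = FALSE)
  class(df) <- c("cgr_depth", "data.frame")
  df
}

#' @rdname read_depth_tsv
#' @param depth A `cgr_depth` data.frame.
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(depth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --------------------------------------------------------------- FASTA ----

#' Read/write FASTA (Biostrings wrappers)
#'
#' @param path FASTA file.
#' @return `read_fasta` a `DNAStringSet`; `write_fasta` invisibly `path`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_fasta
#' @param x A named `DNAStringSet` (or named character vector).
#' @export
write_fasta <- function(x, path) {
  if (!methods::is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# --------------------------------------------------------- case bundles ---

#' Bundle one case's inputs
#'
#' @param case_id Case identifier.
#' @param segments A `cgr_segments` table.
#' @param junctions A `cgr_junctions` table.
#' @param karyotype_string Optional derivative nomenclature string.
#' @param metadata Free-form list (e.g. detection methods).
#' @return A `cgr_bundle` object.
#' @export
case_bundle <- function(case_id, segments, junctions = empty_junctions(),
                        karyotype_string = NULL, metadata = list()) {
  structure(list(case_id = case_id, segments = segments,
                 junctions = junctions, karyotype_string = karyotype_string,
                 metadata = metadata),
            class = "cgr_bundle")
}

#' @export
print.cgr_bundle <- function(x, ...) {
  cat(sprintf("Case %s: %d segment(s), %d junction(s)%s\n", x$case_id,
              nrow(x$segments), nrow(x$junctions),
              if (!is.null(x$karyotype_string)) ", karyotype string present"
              else ""))
  invisible(x)
}

CHR21_LENGTH <- 45090682
CHR21_ACCESSION <- "NC_060945.1"

#' Bundled chromosome 21 rearrangement cases
#'
#' Returns the breakpoint table and derivative nomenclature of one of the
#' three bundled chromosome 21 CGR cases (`RD_P505`, `RD_P26`, `RD_P01`),
#' with junctions derived from the case's karyotype string.
#'
#' @param case_id One of `cgr_case_ids()`.
#' @return A `cgr_bundle`; the parsed walk is attached as
#'   `metadata$nomenclature_walk`.
#' @export
cgr_case <- function(case_id) {
  case_id <- match.arg(case_id, cgr_case_ids())
  tab <- system.file("extdata", paste0(tolower(gsub("_", "", case_id)),
                                       "_segments.tsv"), package = "cgrwalk")
  seg <- read_segment_table(tab, case_id)
  ks <- utils::read.delim(system.file("extdata", "karyotypes.tsv",
                                      package = "cgrwalk"),
                          stringsAsFactors = FALSE)
  kstr <- ks$karyotype[ks$case_id == case_id]
  expr <- parse_seq(kstr, contig_length = CHR21_LENGTH)
  walk <- seq_to_walk(expr, contig_length = CHR21_LENGTH)
  junc <- walk_junctions(walk, prefix = paste0(case_id, "_J"))
  case_bundle(case_id, seg, junc, karyotype_string = kstr,
              metadata = list(nomenclature_walk = walk,
                              nomenclature_diagnostics = expr$diagnostics,
                              contig_length = CHR21_LENGTH,
                              accession = CHR21_ACCESSION))
}

#' @rdname cgr_case
#' @export
cgr_case_ids <- function() c("RD_P505", "RD_P26", "RD_P01")
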