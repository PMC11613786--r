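# Parser and emitter for ISCN/HGVS-like derivative-chromosome descriptions
# of the form
#
#   NC_060945.1:g.[pter_(8275500_8277000)delins[2754001_3885184inv;...]::...]
#
# The grammar covers exactly the constructs seen in the bundled case
# tables: "::" and ";" concatenation, "_" ranges, "inv", "delins[...]",
# "ins" (bracketed list or bare range), "del", uncertain positions
# "(lo_hi)", "pter"/"qter" anchors, and unknown partners "?". Lenient mode
# additionally repairs two defect classes seen in printed strings --
# an "inv:" element separator (read as "inv;") and a position with a
# surplus digit (normalised against the contig length) -- recording each
# repair in a diagnostics list instead of failing.
#
# Positions in strings are 1-based inclusive; walks are 0-based half-open.

# ---------------------------------------------------------------- lexer --

g_tokenize <- function(s) {
  toks <- list()
  i <- 1L; n <- nchar(s)
  kw <- c("delins", "inv", "ins", "del", "pter", "qter")
  while (i <= n) {
    ch <- substr(s, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (grepl("^[0-9]$", ch)) {
      m <- regmatches(substr(s, i, n), regexpr("^[0-9]+", substr(s, i, n)))
      toks[[length(toks) + 1L]] <- list(type = "NUM", text = m, pos = i)
      i <- i + nchar(m); next
    }
    if (substr(s, i, i + 1L) == "::") {
      toks[[length(toks) + 1L]] <- list(type = "::", text = "::", pos = i)
      i <- i + 2L; next
    }
    if (ch %in% c("(", ")", "[", "]", "_", ";", ":", "?", ",")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L; next
    }
    hit <- NULL
    for (k in kw) {
      if (substr(s, i, i + nchar(k) - 1L) == k) { hit <- k; break }
    }
    if (!is.null(hit)) {
      toks[[length(toks) + 1L]] <- list(type = hit, text = hit, pos = i)
      i <- i + nchar(hit); next
    }
    stop(sprintf("unexpected character '%s' at offset %d", ch, i), call. = FALSE)
  }
  toks
}

# ------------------------------------------------------------ AST nodes --

node_pos <- function(value) list(kind = "pos", value = as.numeric(value))
node_uncertain <- function(lo, hi) list(kind = "uncertain", lo = as.numeric(lo),
                                        hi = as.numeric(hi))
node_pter <- function() list(kind = "pter")
node_qter <- function() list(kind = "qter")
node_unknown <- function() list(kind = "unknown")
node_range <- function(start, end = NULL, inverted = FALSE)
  list(kind = "range", start = start, end = end, inverted = inverted)
node_delins <- function(target, repl) list(kind = "delins", target = target,
                                           repl = repl)
node_del <- function(target) list(kind = "del", target = target)
node_ins <- function(at, repl) list(kind = "ins", at = at, repl = repl)
node_concat <- function(items, seps) list(kind = "concat", items = items,
                                          seps = seps)

# Resolve a position node to a coordinate (1-based). Uncertain positions
# resolve to the interval midpoint; unknown to NA.
resolve_pos <- function(p, contig_length = NA) {
  switch(p$kind,
         pos = p$value,
         uncertain = floor((p$lo + p$hi) / 2),
         pter = 1,
         qter = if (is.na(contig_length))
           stop("contig_length needed to resolve qter", call. = FALSE)
         else contig_length,
         unknown = NA_real_,
         stop("cannot resolve position node of kind ", p$kind, call. = FALSE))
}

# ----------------------------------------------------------------- parser --

#' Parse a derivative-chromosome nomenclature string
#'
#' Accepts either a bare `g.[...]` expression or a full karyotype field
#' (`seq[...] 46,XX,der(21)(...)NC_...:g.[...]`); everything before the
#' `g.[` is stored verbatim as the prefix and ignored for structure.
#'
#' @param text The nomenclature string.
#' @param contig_length Optional contig length (1-based qter coordinate);
#'   required to resolve `qter` at walk construction and to sanity-check
#'   positions in lenient mode.
#' @param lenient If `TRUE` (default), recoverable defects ("inv:"
#'   separators, surplus-digit positions) are repaired and recorded in the
#'   diagnostics; if `FALSE` they are errors.
#' @return A `cgr_seqexpr`: list with `ast`, `prefix`, `diagnostics`,
#'   `contig_length`.
#' @export
parse_seq <- function(text, contig_length = NULL, lenient = TRUE) {
  if (is.null(contig_length)) contig_length <- NA_real_
  gpos <- regexpr("g\\.\\[", text)
  if (gpos < 0) stop("no 'g.[' expression found", call. = FALSE)
  prefix <- substr(text, 1, gpos - 1)
  # find the matching close bracket of g.[
  depth <- 0L; i <- gpos + 3L; n <- nchar(text); endpos <- NA_integer_
  while (i <= n) {
    ch <- substr(text, i, i)
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") {
      if (depth == 0L) { endpos <- i; break }
      depth <- depth - 1L
    }
    i <- i + 1L
  }
  if (is.na(endpos))
    stop(sprintf("unbalanced brackets: 'g.[' at offset %d never closed",
                 as.integer(gpos)), call. = FALSE)
  body <- substr(text, gpos + 3L, endpos - 1L)

  st <- new.env(parent = emptyenv())
  st$toks <- g_tokenize(body)
  st$i <- 1L
  st$diag <- character()
  st$len <- contig_length
  st$lenient <- isTRUE(lenient)

  peek <- function(k = 0L) {
    j <- st$i + k
    if (j > length(st$toks)) list(type = "EOF", text = "", pos = nchar(body) + 1L)
    else st$toks[[j]]
  }
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  expect <- function(type) {
    t <- peek()
    if (t$type != type)
      stop(sprintf("expected '%s' but found '%s' at offset %d",
                   type, t$text, t$pos), call. = FALSE)
    advance()
  }

  fix_number <- function(value, text, prev = NA) {
    # surplus-digit repair: value exceeds the contig; try dropping one digit
    if (is.na(st$len) || value <= st$len) return(value)
    if (!st$lenient)
      stop(sprintf("position %s exceeds contig length %s", text, st$len),
           call. = FALSE)
    cand <- unique(vapply(seq_len(nchar(text)), function(k) {
      as.numeric(paste0(substr(text, 1, k - 1), substr(text, k + 1, nchar(text))))
    }, numeric(1)))
    pick <- NA_real_
    if (!is.na(prev) && (prev + 1) %in% cand) pick <- prev + 1
    else {
      ok <- cand[cand <= st$len & (is.na(prev) | cand >= prev)]
      if (length(ok)) pick <- ok[1]
    }
    if (is.na(pick))
      stop(sprintf("position %s exceeds contig length and cannot be repaired",
                   text), call. = FALSE)
    st$diag <- c(st$diag, sprintf(
      "position %s exceeds contig length %s; normalised to %s (surplus digit)",
      text, format(st$len, scientific = FALSE),
      format(pick, scientific = FALSE)))
    pick
  }

  p_pos <- function(prev = NA, allow_unknown = FALSE) {
    t <- peek()
    if (t$type == "(") {
      advance()
      lo <- as.numeric(expect("NUM")$text)
      expect("_")
      hi <- as.numeric(expect("NUM")$text)
      expect(")")
      return(node_uncertain(lo, hi))
    }
    if (t$type == "NUM") {
      advance()
      v <- fix_number(as.numeric(t$text), t$text, prev = prev)
      return(node_pos(v))
    }
    if (t$type == "pter") { advance(); return(node_pter()) }
    if (t$type == "qter") { advance(); return(node_qter()) }
    if (allow_unknown && t$type == "?") { advance(); return(node_unknown()) }
    stop(sprintf("expected a position but found '%s' at offset %d",
                 t$text, t$pos), call. = FALSE)
  }

  p_range <- function() {
    a <- p_pos()
    if (peek()$type == "_") {
      advance()
      aval <- tryCatch(resolve_pos(a, st$len), error = function(e) NA)
      b <- p_pos(prev = aval, allow_unknown = TRUE)
      node_range(a, b)
    } else node_range(a, NULL)
  }

  p_elem <- function() {
    if (peek()$type == "?") { advance(); return(node_unknown()) }
    r <- p_range()
    if (peek()$type == "inv") { advance(); r$inverted <- TRUE }
    r
  }

  is_sep <- function(t) t$type %in% c(";", "::", ":")
  eat_sep <- function() {
    t <- advance()
    if (t$type == ":") {
      if (!st$lenient)
        stop(sprintf("unexpected ':' separator at offset %d", t$pos),
             call. = FALSE)
      st$diag <- c(st$diag, sprintf(
        "separator ':' at offset %d read as ';'", t$pos))
      return(";")
    }
    t$type
  }

  p_repl <- function() {
    if (peek()$type == "[") {
      advance()
      elems <- list(p_elem())
      while (is_sep(peek())) { eat_sep(); elems[[length(elems) + 1L]] <- p_elem() }
      expect("]")
      elems
    } else list(p_elem())
  }

  p_expr <- function() {
    r <- p_range()
    t <- peek()
    if (t$type == "delins") { advance(); return(node_delins(r, p_repl())) }
    if (t$type == "del") { advance(); return(node_del(r)) }
    if (t$type == "ins") { advance(); return(node_ins(r, p_repl())) }
    r
  }

  items <- list(p_expr()); seps <- character()
  while (is_sep(peek())) {
    seps <- c(seps, eat_sep())
    items[[length(items) + 1L]] <- p_expr()
  }
  if (peek()$type != "EOF")
    stop(sprintf("trailing input '%s' at offset %d", peek()$text, peek()$pos),
         call. = FALSE)

  structure(list(ast = node_concat(items, seps), prefix = prefix,
                 diagnostics = st$diag, contig_length = contig_length),
            class = "cgr_seqexpr")
}

#' @export
print.cgr_seqexpr <- function(x, ...) {
  cat("Parsed derivative nomenclature:", length(x$ast$items),
      "top-level expression(s)\n")
  if (length(x$diagnostics))
    cat(paste0("  diagnostic: ", x$diagnostics), sep = "\n")
  invisible(x)
}

# -------------------------------------------------------- expr -> walk --

elem_to_step <- function(el, contig, contig_length) {
  if (el$kind == "unknown")
    return(data.frame(contig = contig, start = NA_real_, end = NA_real_,
                      inverted = FALSE, gap = TRUE))
  stopifnot(el$kind == "range")
  s <- resolve_pos(el$start, contig_length)
  e <- if (is.null(el$end)) s else resolve_pos(el$end, contig_length)
  if (is.na(e))  # known start, unknown partner: explicit gap step
    return(data.frame(contig = contig, start = s - 1, end = NA_real_,
                      inverted = isTRUE(el$inverted), gap = TRUE))
  data.frame(contig = contig, start = s - 1, end = e,
             inverted = isTRUE(el$inverted), gap = FALSE)
}

#' Convert a parsed nomenclature expression to a derivative walk
#'
#' The walk's steps are the non-deleted reference runs plus replacement
#' segments in order, with inversion flags from `inv` nodes. A derivative
#' whose expression removes both telomeres (first edit anchored at `pter`
#' and last at `qter`, with at least two edits) is taken to close into a
#' ring, the convention under which terminal deletions are rescued by ring
#' formation.
#'
#' @param expr A `cgr_seqexpr` from [parse_seq()].
#' @param contig_length Contig length; defaults to the one stored at parse
#'   time.
#' @param contig Contig name for the walk steps.
#' @return A `cgr_walk`.
#' @export
seq_to_walk <- function(expr, contig_length = NULL, contig = "chr21") {
  if (is.null(contig_length)) contig_length <- expr$contig_length
  if (is.null(contig_length) || is.na(contig_length))
    stop("contig_length is required to build a walk", call. = FALSE)
  L <- as.numeric(contig_length)
  items <- expr$ast$items

  # identity: a single bare range covering pter..qter
  if (length(items) == 1 && items[[1]]$kind == "range") {
    r <- items[[1]]
    s <- resolve_pos(r$start, L); e <- resolve_pos(r$end %||% r$start, L)
    if (s == 1 && e == L && !isTRUE(r$inverted))
      return(derivative_walk(data.frame(contig = contig, start = 0, end = L,
                                        inverted = FALSE, gap = FALSE)))
    stop("bare range expressions other than the identity are not supported",
         call. = FALSE)
  }

  edits <- lapply(items, function(it) {
    if (!it$kind %in% c("delins", "del", "ins"))
      stop("top-level expressions must be delins/del/ins edits", call. = FALSE)
    tgt <- if (it$kind == "ins") it$at else it$target
    ts <- resolve_pos(tgt$start, L)
    te <- resolve_pos(tgt$end %||% tgt$start, L)
    if (is.na(ts) || is.na(te))
      stop("edit targets must have resolvable positions", call. = FALSE)
    if (it$kind == "ins") {
      if (te != ts + 1)
        stop(sprintf("ins target %s_%s is not an adjacent-position pair",
                     format(ts, scientific = FALSE),
                     format(te, scientific = FALSE)), call. = FALSE)
      list(kind = "ins", from = ts + 1, to = ts, repl = it$repl,
           anchor_pter = FALSE, anchor_qter = FALSE)
    } else {
      list(kind = it$kind, from = ts, to = te,
           repl = if (it$kind == "del") list() else it$repl,
           anchor_pter = ts == 1, anchor_qter = te == L)
    }
  })
  ord <- order(vapply(edits, `[[`, numeric(1), "from"))
  edits <- edits[ord]
  froms <- vapply(edits, `[[`, numeric(1), "from")
  tos <- vapply(edits, `[[`, numeric(1), "to")
  if (length(edits) > 1 && any(froms[-1] <= tos[-length(tos)]))
    stop("overlapping edit targets", call. = FALSE)

  circular <- length(edits) >= 2 &&
    edits[[1]]$anchor_pter && edits[[length(edits)]]$anchor_qter

  steps <- list()
  cursor <- 0  # 0-based
  for (ed in edits) {
    flank_end <- ed$from - 1  # 0-based end of flank before this edit
    if (flank_end > cursor)
      steps[[length(steps) + 1L]] <-
        data.frame(contig = contig, start = cursor, end = flank_end,
                   inverted = FALSE, gap = FALSE)
    for (el in ed$repl)
      steps[[length(steps) + 1L]] <- elem_to_step(el, contig, L)
    cursor <- ed$to
  }
  if (cursor < L)
    steps[[length(steps) + 1L]] <-
      data.frame(contig = contig, start = cursor, end = L,
                 inverted = FALSE, gap = FALSE)
  st <- do.call(rbind, steps)
  # a ring exists only if the derivative truly lost both telomeres: an
  # edit anchored at pter/qter whose replacement still carries telomeric
  # sequence leaves a linear chromosome
  if (circular &&
      any(!st$gap & (st$start == 0 | st$end == L), na.rm = TRUE))
    circular <- FALSE
  derivative_walk(st, circular = circular)
}

# -------------------------------------------------------- walk -> expr --

fmt_pos <- function(x, contig_length) {
  if (x == 1) "pter"
  else if (!is.na(contig_length) && x == contig_length) "qter"
  else format(x, scientific = FALSE)
}

fmt_elem_step <- function(st, contig_length) {
  if (isTRUE(st$gap)) {
    if (is.na(st$start)) return("?")
    return(paste0(fmt_pos(st$start + 1, contig_length), "_?"))
  }
  paste0(fmt_pos(st$start + 1, contig_length), "_",
         fmt_pos(st$end, contig_length), if (st$inverted) "inv" else "")
}

fmt_edit <- function(target_from, target_to, elems, contig_length) {
  # target in 1-based coordinates; target_from > target_to encodes an
  # insertion point between target_to and target_from
  if (target_from > target_to) {
    stopifnot(length(elems) > 0)
    at <- paste0(fmt_pos(target_to, contig_length), "_",
                 fmt_pos(target_from, contig_length))
    body <- if (length(elems) == 1) elems else
      paste0("[", paste(elems, collapse = ";"), "]")
    return(paste0(at, "ins", body))
  }
  tgt <- paste0(fmt_pos(target_from, contig_length), "_",
                fmt_pos(target_to, contig_length))
  if (length(elems) == 0) return(paste0(tgt, "del"))
  paste0(tgt, "delins[", paste(elems, collapse = ";"), "]")
}

# Weighted longest-increasing-subsequence over forward non-gap steps:
# pick the backbone anchors (kept reference runs) maximising total kept
# length, respecting both walk order and genomic order.
pick_anchors <- function(st) {
  cand <- which(!st$inverted & !st$gap)
  if (!length(cand)) return(integer())
  len <- st$end - st$start
  best <- rep(-Inf, length(cand)); prev <- rep(0L, length(cand))
  for (a in seq_along(cand)) {
    i <- cand[a]
    best[a] <- len[i]
    for (b in seq_len(a - 1L)) {
      j <- cand[b]
      if (st$end[j] <= st$start[i] && best[b] + len[i] > best[a]) {
        best[a] <- best[b] + len[i]; prev[a] <- b
      }
    }
  }
  a <- which.max(best)
  chain <- integer()
  while (a != 0L) { chain <- c(cand[a], chain); a <- prev[a] }
  chain
}

#' Emit the canonical nomenclature string for a walk
#'
#' Inverse of [seq_to_walk()]: chooses backbone anchors (the kept
#' reference runs, by maximum total length), writes every non-backbone
#' run as a replacement element, and renders `delins`/`del`/`ins` edits in
#' genomic order. Rings are written as two telomere-anchored `delins`
#' expressions joined by `"::"`, the form used for ring derivatives.
#' Gap steps are written with `"?"` tokens. Uncertainty parentheses are
#' never emitted.
#'
#' @param walk A `cgr_walk` on a single contig.
#' @param contig_length Contig length (1-based qter coordinate).
#' @param accession Optional accession prefix (e.g. `"NC_060945.1"`).
#' @return A character scalar, e.g. `"g.[pter_qter]"`.
#' @export
walk_to_seq <- function(walk, contig_length, accession = NULL) {
  L <- as.numeric(contig_length)
  w <- normalize_walk(walk)
  st <- w$steps
  pre <- if (is.null(accession)) "" else paste0(accession, ":")

  if (!w$circular && nrow(st) == 1 && !st$gap[1] && !st$inverted[1] &&
      st$start[1] == 0 && st$end[1] == L)
    return(paste0(pre, "g.[pter_qter]"))

  if (w$circular) {
    # rotate so the longest kept forward run is the backbone
    cand <- which(!st$inverted & !st$gap)
    if (!length(cand))
      stop("cannot emit a ring walk with no forward reference run",
           call. = FALSE)
    anchor <- cand[which.max(st$end[cand] - st$start[cand])]
    n <- nrow(st)
    rest <- if (n > 1) ((anchor:(anchor + n - 2L)) %% n) + 1L else integer()
    # steps after the anchor in ring order that lie beyond it in the
    # genome go to the qter-side edit; the remainder to the pter side
    repl2_idx <- integer(); k <- 1L
    while (k <= length(rest) &&
           !is.na(st$start[rest[k]]) && st$start[rest[k]] >= st$end[anchor]) {
      repl2_idx <- c(repl2_idx, rest[k]); k <- k + 1L
    }
    repl1_idx <- if (k <= length(rest)) rest[k:length(rest)] else integer()
    e1 <- vapply(repl1_idx, function(i) fmt_elem_step(st[i, ], L), character(1))
    e2 <- vapply(repl2_idx, function(i) fmt_elem_step(st[i, ], L), character(1))
    part1 <- fmt_edit(1, st$start[anchor], e1, L)
    part2 <- fmt_edit(st$end[anchor] + 1, L, e2, L)
    return(paste0(pre, "g.[", part1, "::", part2, "]"))
  }

  anchors <- pick_anchors(st)
  edits <- character()
  prev_end <- 0  # 0-based end of previous anchor
  prev_idx <- 0L
  bounds <- c(anchors, nrow(st) + 1L)
  for (bi in seq_along(bounds)) {
    a <- bounds[bi]
    between <- setdiff(seq_len(nrow(st)),
                       c(anchors, seq_len(prev_idx)))
    between <- between[between < a]
    tgt_from <- prev_end + 1            # 1-based
    tgt_to <- if (a <= nrow(st)) st$start[a] else L
    elems <- vapply(between, function(i) fmt_elem_step(st[i, ], L),
                    character(1))
    if (tgt_from > tgt_to && length(elems) == 0) {
      # anchors abut with nothing between: nothing to emit
    } else if (tgt_from > tgt_to + 1) {
      stop("internal error: anchor chain is not increasing", call. = FALSE)
    } else if (tgt_from == tgt_to + 1 && length(elems) > 0) {
      edits <- c(edits, fmt_edit(tgt_from, tgt_to, elems, L))   # pure ins
    } else if (tgt_from <= tgt_to) {
      edits <- c(edits, fmt_edit(tgt_from, tgt_to, elems, L))
    }
    if (a <= nrow(st)) { prev_end <- st$end[a]; prev_idx <- a }
  }
  paste0(pre, "g.[", paste(edits, collapse = ";"), "]")
}

# --------------------------------------------------- AST equivalence ----

canonical_ast <- function(node, contig_length = NA) {
  k <- node$kind
  if (k %in% c("pos", "uncertain", "pter", "qter")) {
    v <- resolve_pos(node, contig_length)
    return(list("p", if (is.na(v)) k else v))
  }
  if (k == "unknown") return(list("unknown"))
  if (k == "range") {
    return(list("range", canonical_ast(node$start, contig_length),
                if (is.null(node$end)) NULL
                else canonical_ast(node$end, contig_length),
                isTRUE(node$inverted)))
  }
  if (k %in% c("delins", "del")) {
    return(list("delins", canonical_ast(node$target, contig_length),
                lapply(node$repl %||% list(), canonical_ast, contig_length)))
  }
  if (k == "ins") {
    return(list("ins", canonical_ast(node$at, contig_length),
                lapply(node$repl, canonical_ast, contig_length)))
  }
  if (k == "concat") {
    items <- lapply(node$items, canonical_ast, contig_length)
    ord <- order(vapply(items, function(x)
      paste(deparse(x), collapse = ""), character(1)))
    return(list("concat", items[ord]))
  }
  stop("unknown AST node kind: ", k, call. = FALSE)
}

#' Structural equivalence of two parsed expressions
#'
#' Compares two ASTs after canonical normalisation: uncertain positions
#' resolve to their midpoints, `pter`/`qter` to coordinates, lenient
#' separator repairs are already applied, and top-level edit order is
#' sorted.
#'
#' @param a,b `cgr_seqexpr` objects.
#' @param contig_length Contig length used to resolve anchors.
#' @return Logical flag.
#' @export
ast_equivalent <- function(a, b, contig_length = NULL) {
  L <- contig_length %||% a$contig_length %||% NA
  identical(canonical_ast(a$ast, L), canonical_ast(b$ast, L))
}

`%||%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
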