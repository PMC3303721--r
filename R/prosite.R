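# Prosite-syntax pattern parsing, rendering and exhaustive scanning.
#
# A pattern is an ordered list of elements, each one of:
#   literal        a single residue, e.g.  C
#   class          [VLI]   any listed residue (order preserved as written)
#   negated_class  {DE}    any residue NOT listed
#   wildcard       x       any residue
# with an optional repeat count (n) or range (n,m).  '<' anchors the
# match to the N-terminus, '>' to the C-terminus.  The unknown residue
# 'X' in a sequence matches nothing except wildcards.

new_element <- function(kind, residues, rep_min, rep_max) {
  list(kind = kind, residues = residues,
       rep_min = as.integer(rep_min), rep_max = as.integer(rep_max))
}

new_pattern <- function(elements, anchored_start = FALSE, anchored_end = FALSE,
                        name = "") {
  structure(list(name = name, elements = elements,
                 anchored_start = anchored_start, anchored_end = anchored_end),
            class = "prosite_pattern")
}

parse_fail <- function(offset, msg) {
  stop(sprintf("pattern parse error at character %d: %s", offset, msg),
       call. = FALSE)
}

#' Parse a Prosite-syntax pattern
#'
#' Accepts elements joined by `-`, an optional terminal `.`, wildcards
#' `x` / `x(n)` / `x(n,m)`, residue classes `[...]`, negated classes
#' `{...}` and the `<` / `>` terminal anchors.  Whitespace (and commas
#' inside classes, as in printed patterns like `[V, L, I]`) is tolerated.
#'
#' @param text pattern string.
#' @param name optional pattern name.
#' @return a `prosite_pattern`.
#' @export
#' @examples
#' parse_pattern("C-x(2)-V")
parse_pattern <- function(text, name = "") {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  i <- 1L
  skip_ws <- function() while (i <= n && grepl("[[:space:]]", chars[i])) i <<- i + 1L

  anchored_start <- FALSE; anchored_end <- FALSE
  elements <- list()

  skip_ws()
  if (i <= n && chars[i] == "<") { anchored_start <- TRUE; i <- i + 1L }

  expect_elem <- TRUE
  while (TRUE) {
    skip_ws()
    if (i > n) break
    ch <- chars[i]
    if (ch == ".") { i <- i + 1L; skip_ws(); if (i <= n) parse_fail(i, "text after terminal '.'"); break }
    if (ch == ">") {
      anchored_end <- TRUE; i <- i + 1L; skip_ws()
      if (i <= n && chars[i] == ".") { i <- i + 1L; skip_ws() }
      if (i <= n) parse_fail(i, "text after '>' anchor")
      break
    }
    if (!expect_elem) parse_fail(i, "expected '-' between elements")
    start <- i
    if (ch == "x") {
      elem <- new_element("wildcard", character(0), 1L, 1L)
      i <- i + 1L
    } else if (ch %in% c("[", "{")) {
      close <- if (ch == "[") "]" else "}"
      j <- i + 1L
      residues <- character(0)
      while (j <= n && chars[j] != close) {
        cj <- chars[j]
        if (grepl("[[:space:]]", cj) || cj == ",") { j <- j + 1L; next }
        if (!(cj %in% AA20))
          parse_fail(j, sprintf("unknown residue letter '%s' in class", cj))
        if (!(cj %in% residues)) residues <- c(residues, cj)
        j <- j + 1L
      }
      if (j > n) parse_fail(start, sprintf("unbalanced '%s'", ch))
      if (!length(residues)) parse_fail(start, "empty class")
      elem <- new_element(if (ch == "[") "class" else "negated_class",
                          residues, 1L, 1L)
      i <- j + 1L
    } else if (ch %in% AA20) {
      elem <- new_element("literal", ch, 1L, 1L)
      i <- i + 1L
    } else {
      parse_fail(i, sprintf("unknown residue letter '%s'", ch))
    }
    # optional repeat (n) or (n,m)
    skip_ws()
    if (i <= n && chars[i] == "(") {
      j <- i + 1L
      while (j <= n && chars[j] != ")") j <- j + 1L
      if (j > n) parse_fail(i, "unbalanced '('")
      inner <- gsub("[[:space:]]", "", paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      if (!(length(parts) %in% 1:2) || !all(grepl("^[0-9]+$", parts)))
        parse_fail(i, sprintf("non-integer repeat '%s'", inner))
      lo <- as.integer(parts[1])
      hi <- if (length(parts) == 2L) as.integer(parts[2]) else lo
      if (lo > hi) parse_fail(i, sprintf("inverted repeat (%d,%d)", lo, hi))
      elem$rep_min <- lo; elem$rep_max <- hi
      i <- j + 1L
    }
    elements <- c(elements, list(elem))
    # separator
    skip_ws()
    if (i <= n && chars[i] == "-") { i <- i + 1L; expect_elem <- TRUE }
    else expect_elem <- FALSE
  }
  if (!length(elements)) parse_fail(1L, "pattern has no elements")
  new_pattern(elements, anchored_start, anchored_end, name)
}

#' Render a pattern in canonical Prosite syntax
#'
#' `parse_pattern(render_pattern(p))` reproduces `p` exactly; rendering
#' an already-canonical string is idempotent.
#'
#' @param pattern a `prosite_pattern`.
#' @return single pattern string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "prosite_pattern"))
  tok <- vapply(pattern$elements, function(e) {
    body <- switch(e$kind,
      literal = e$residues,
      class = paste0("[", paste(e$residues, collapse = ""), "]"),
      negated_class = paste0("{", paste(e$residues, collapse = ""), "}"),
      wildcard = "x")
    if (e$rep_min == 1L && e$rep_max == 1L) body
    else if (e$rep_min == e$rep_max) sprintf("%s(%d)", body, e$rep_min)
    else sprintf("%s(%d,%d)", body, e$rep_min, e$rep_max)
  }, "")
  paste0(if (pattern$anchored_start) "<" else "",
         paste(tok, collapse = "-"),
         if (pattern$anchored_end) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  nm <- if (nzchar(x$name)) paste0(x$name, ": ") else ""
  cat(sprintf("<prosite_pattern> %s%s\n", nm, render_pattern(x)))
  invisible(x)
}

#' Built-in nsLTP patterns
#'
#' Returns the Prosite-styled patterns for Type I and Type II nsLTPs and
#' the Prosite PLANT_LTP entry PS00597.
#'
#' @return named list of `prosite_pattern` objects
#'   (`typeI`, `typeII`, `PS00597`).
#' @export
builtin_patterns <- function() {
  list(
    typeI = parse_pattern(paste0(
      "C-x(2)-V-x(5,7)-C-[VLI]-x-Y-[LAV]-x(8,13)-C-C-x-G-x(12)-D-x-[QKR]-",
      "x(2)-C-x-C-x(16,21)-P-x(2)-C-x(13,15)-C"), name = "typeI"),
    typeII = parse_pattern(paste0(
      "C-x(4)-L-x(2)-C-x(9,11)-P-[ST]-x(2)-C-C-x(5)-Q-x(2,4)-C-[LF]-C-",
      "x(2)-[ALI]-x-[DN]-P-x(10,12)-[KR]-x(4,5)-C-x(3,4)-P-x(0,2)-C"),
      name = "typeII"),
    PS00597 = parse_pattern(paste0(
      "[LIVM]-[PA]-x(2)-C-x-[LIVM]-x-[LIVM]-x-[LIVMFY]-x-[LIVM]-[ST]-",
      "x(3)-[DN]-C-x(2)-[LIVM]"), name = "PS00597")
  )
}

# Does a single sequence character satisfy one occurrence of an element?
# 'X' (unknown) matches only wildcards; '-' matches nothing.
element_char_ok <- function(elem, ch) {
  if (ch == "-") return(FALSE)
  switch(elem$kind,
    wildcard = TRUE,
    literal = ch == elem$residues,
    class = ch %in% elem$residues,
    negated_class = ch != "X" && !(ch %in% elem$residues))
}

# From a set of positions (1-based index of next unmatched character),
# return all positions reachable after consuming one element.
advance_element <- function(elem, chars, positions) {
  n <- length(chars)
  out <- integer(0)
  for (p in positions) {
    # consume k occurrences, k in [rep_min, rep_max]
    k <- 0L
    q <- p
    if (elem$rep_min == 0L) out <- c(out, q)
    while (k < elem$rep_max && q <= n && element_char_ok(elem, chars[q])) {
      k <- k + 1L; q <- q + 1L
      if (k >= elem$rep_min) out <- c(out, q)
    }
  }
  sort(unique(out))
}

#' Scan a sequence with a Prosite pattern
#'
#' Enumerates every distinct match span exhaustively (all start/end
#' combinations, not just leftmost or greedy), honouring `<` / `>`
#' anchors.  Zero-length matches are not reported.  The unknown residue
#' `X` matches nothing except wildcards.
#'
#' @param seq residue string (or single-row record data.frame).
#' @param pattern a `prosite_pattern` or pattern string.
#' @return data.frame with 1-based inclusive `start`, `end` columns,
#'   sorted by (start, end).
#' @export
#' @examples
#' scan_pattern("AGGC", "A-x(2,3)-C")
scan_pattern <- function(seq, pattern) {
  s <- residue_string(seq)
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  starts <- if (pattern$anchored_start) 1L else seq_len(max(n, 0L))
  res_start <- integer(0); res_end <- integer(0)
  for (st in starts) {
    pos <- st
    for (elem in pattern$elements) {
      pos <- advance_element(elem, chars, pos)
      if (!length(pos)) break
    }
    if (!length(pos)) next
    ends <- pos - 1L                    # inclusive end positions
    ends <- ends[ends >= st]            # drop zero-length matches
    if (pattern$anchored_end) ends <- ends[ends == n]
    if (length(ends)) {
      res_start <- c(res_start, rep.int(st, length(ends)))
      res_end <- c(res_end, ends)
    }
  }
  ord <- order(res_start, res_end)
  data.frame(start = res_start[ord], end = res_end[ord])
}

#' Does a pattern match anywhere in a sequence?
#'
#' @inheritParams scan_pattern
#' @return logical scalar: `TRUE` iff [scan_pattern()] finds a span.
#' @export
pattern_matches <- function(seq, pattern) {
  nrow(scan_pattern(seq, pattern)) > 0L
}

# Accept either a bare residue string or a one-row record data.frame.
residue_string <- function(seq) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L, "seq" %in% names(seq))
    return(seq$seq)
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  toupper(seq)
}

#' Scan many sequences with named patterns
#'
#' @param seqs record data.frame (`id`, `desc`, `seq`).
#' @param patterns named list of `prosite_pattern`s (default: built-ins).
#' @return data.frame `sequence_id`, `pattern_name`, `start_1based`,
#'   `end_1based`, `matched_subsequence`.
#' @export
scan_set <- function(seqs, patterns = builtin_patterns()) {
  if (inherits(patterns, "prosite_pattern")) patterns <- list(patterns)
  rows <- list()
  for (pn in seq_along(patterns)) {
    p <- patterns[[pn]]
    pname <- names(patterns)[pn] %||% ""
    if (is.null(names(patterns)) || !nzchar(pname)) pname <- p$name
    for (i in seq_len(nrow(seqs))) {
      sp <- scan_pattern(seqs$seq[i], p)
      if (nrow(sp))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = seqs$id[i], pattern_name = pname,
          start_1based = sp$start, end_1based = sp$end,
          matched_subsequence = substring(seqs$seq[i], sp$start, sp$end),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(0), pattern_name = character(0),
                      start_1based = integer(0), end_1based = integer(0),
                      matched_subsequence = character(0)))
  do.call(rbind, rows)
}

# One concrete realization (element -> span) of a pattern match starting
# at `start`; NULL if none.  Used by the decoy generator to locate
# conserved positions.  Depth-first, preferring the shortest repeat.
pattern_realization <- function(seq, pattern, start = NULL) {
  s <- residue_string(seq)
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  elems <- pattern$elements
  rec <- function(pos, ei, spans) {
    if (ei > length(elems)) {
      if (pattern$anchored_end && pos != n + 1L) return(NULL)
      return(spans)
    }
    e <- elems[[ei]]
    for (k in e$rep_min:e$rep_max) {
      if (pos + k - 1L > n) break
      ok <- k == 0L || all(vapply(chars[pos:(pos + k - 1L)],
                                  function(ch) element_char_ok(e, ch), TRUE))
      if (!ok) break
      res <- rec(pos + k, ei + 1L,
                 rbind(spans, data.frame(element = ei, kind = e$kind,
                                         start = if (k > 0L) pos else NA_integer_,
                                         end = if (k > 0L) pos + k - 1L else NA_integer_)))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  starts <- if (!is.null(start)) start
            else if (pattern$anchored_start) 1L else seq_len(n)
  for (st in starts) {
    res <- rec(st, 1L, data.frame(element = integer(0), kind = character(0),
                                  start = integer(0), end = integer(0)))
    if (!is.null(res)) return(res)
  }
  NULL
}
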