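# Five-type nsLTP classification from inter-cysteine spacing.
#
# Each type is characterised by admissible residue counts in the five
# inter-cysteine gaps (and, in strict mode, by the N-terminal offset and
# C-terminal tail).  Comma lists are unions of exact values, dashes
# inclusive integer ranges.

#' Spacing rule table for Types I-V
#'
#' Admissible inter-cysteine gap counts (g1..g5), N-terminal offsets and
#' C-terminal tail lengths for the five nsLTP types.  The Type III g4
#' entry contains an isolated value 2 alongside the 21-24 range; it is
#' transcribed literally by default and can be dropped as a suspected
#' typographic artifact with `iii_g4_drop_stray = TRUE`.
#'
#' @param iii_g4_drop_stray drop the isolated 2 from the Type III g4 set.
#' @return named list (`I`..`V`), each with integer vectors `n_offset`,
#'   `g1`..`g5`, `c_tail`.
#' @export
spacing_rules <- function(iii_g4_drop_stray = FALSE) {
  r <- list(
    I   = list(n_offset = c(0:12, 16), g1 = 8:10, g2 = 12:17,
               g3 = c(18:20, 29), g4 = 19:24, g5 = c(7, 13:15),
               c_tail = c(26, 37, 48)),
    II  = list(n_offset = 0:20, g1 = 7, g2 = c(13, 15), g3 = 8:10,
               g4 = c(16, 21, 24), g5 = 4:7, c_tail = 0:2),
    III = list(n_offset = 0:7, g1 = c(9, 10), g2 = c(12, 15, 17), g3 = 9,
               g4 = c(21:24, 2), g5 = c(6:10, 13), c_tail = c(0:5, 10)),
    IV  = list(n_offset = c(2:5, 10), g1 = 14, g2 = 14, g3 = 11:13,
               g4 = 24, g5 = 10, c_tail = c(6, 10, 12)),
    V   = list(n_offset = 2:17, g1 = 10, g2 = c(16, 17), g3 = 9,
               g4 = c(22, 23), g5 = c(7, 9), c_tail = 5:12)
  )
  if (iii_g4_drop_stray) r$III$g4 <- 21:24
  r
}

LTP_TYPES <- c("I", "II", "III", "IV", "V")

# Format an admissible integer set compactly ("8-10", "7,13-15", ...).
format_int_set <- function(v) {
  v <- sort(unique(v))
  runs <- split(v, cumsum(c(1L, diff(v) != 1L)))
  paste(vapply(runs, function(r) {
    if (length(r) == 1L) as.character(r) else sprintf("%d-%d", r[1], r[length(r)])
  }, ""), collapse = ",")
}

#' Classify a motif's spacing against the five-type rule table
#'
#' @param motif one-row data.frame from [find_cys_motifs()], or a named
#'   list/vector with `g1`..`g5` (and `n_offset`, `c_tail` for strict
#'   mode).
#' @param mode `"core"` tests only the inter-cysteine gaps g1..g5;
#'   `"strict"` additionally tests the N-terminal offset and C-terminal
#'   tail.
#' @param rules rule table from [spacing_rules()].
#' @param prefer optional priority order of types used to resolve an
#'   ambiguous call (e.g. `c("III", "V")`); by default ambiguity is
#'   reported, never broken.
#' @return list of class `ltp_type_assignment`: `compatible` (character
#'   vector), `resolved` (one of I..V, "ambiguous", "unclassified"),
#'   `evidence` (data.frame: type, slot, observed, admissible, hit).
#' @export
classify_spacing <- function(motif, mode = c("core", "strict"),
                             rules = spacing_rules(), prefer = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(motif)) { stopifnot(nrow(motif) == 1L); motif <- as.list(motif) }
  slots <- c("g1", "g2", "g3", "g4", "g5")
  if (mode == "strict") slots <- c("n_offset", slots, "c_tail")
  ev <- list()
  compatible <- character(0)
  for (ty in names(rules)) {
    ok <- TRUE
    for (sl in slots) {
      obs <- as.integer(motif[[sl]])
      adm <- rules[[ty]][[sl]]
      hit <- obs %in% adm
      ev[[length(ev) + 1L]] <- data.frame(
        type = ty, slot = sl, observed = obs,
        admissible = format_int_set(adm),
        hit = hit, stringsAsFactors = FALSE)
      if (!hit) ok <- FALSE
    }
    if (ok) compatible <- c(compatible, ty)
  }
  resolved <- if (length(compatible) == 1L) compatible
              else if (length(compatible) == 0L) "unclassified"
              else "ambiguous"
  if (resolved == "ambiguous" && !is.null(prefer)) {
    pick <- prefer[prefer %in% compatible]
    if (length(pick)) resolved <- pick[1]
  }
  structure(list(compatible = compatible, resolved = resolved,
                 evidence = do.call(rbind, ev)),
            class = "ltp_type_assignment")
}

#' @export
print.ltp_type_assignment <- function(x, ...) {
  cat(sprintf("Type assignment: %s (compatible: %s)\n", x$resolved,
              if (length(x$compatible)) paste(x$compatible, collapse = ",") else "none"))
  invisible(x)
}

#' Classify a single protein sequence
#'
#' Runs the motif search, classifies the spacing of each candidate motif
#' and reports the first candidate (in motif sort order) that yields a
#' non-unclassified assignment, falling back to the first candidate.
#' Without a full 8-Cys motif, cysteine-deficient categories are
#' reported; with neither, the sequence is unclassified.  When
#' `use_patterns = TRUE` the built-in Type I / Type II Prosite patterns
#' are also matched and an agreement flag records whether the pattern
#' evidence supports the spacing call.
#'
#' @param seq residue string or one-row record data.frame.
#' @param id identifier used in the report (default taken from `seq` or
#'   `"seq1"`).
#' @param mode,rules,prefer see [classify_spacing()].
#' @param use_patterns also match the built-in Type I/II patterns.
#' @return one-row data.frame: `sequence_id`, `resolved`, `compatible`,
#'   `g1`..`g5`, `n_offset`, `c_tail`, `patternI_match`,
#'   `patternII_match`, `pattern_agrees`, `deficient_category`, `cxc_x`,
#'   `cxc_polarity`, `mw_da`, `pi`.
#' @export
classify_sequence <- function(seq, id = NULL, mode = c("core", "strict"),
                              use_patterns = FALSE, rules = spacing_rules(),
                              prefer = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(seq)) { id <- id %||% seq$id; seq <- seq$seq }
  id <- id %||% "seq1"
  s <- toupper(seq)

  motifs <- find_cys_motifs(s)
  na_int <- NA_integer_
  rep0 <- data.frame(sequence_id = id, resolved = "unclassified",
                     compatible = ".", g1 = na_int, g2 = na_int, g3 = na_int,
                     g4 = na_int, g5 = na_int, n_offset = na_int,
                     c_tail = na_int, patternI_match = NA,
                     patternII_match = NA, pattern_agrees = NA,
                     deficient_category = ".", cxc_x = ".",
                     cxc_polarity = ".", mw_da = NA_real_, pi = NA_real_,
                     stringsAsFactors = FALSE)

  if (nrow(motifs)) {
    picked <- 1L
    assign <- NULL
    for (i in seq_len(nrow(motifs))) {
      a <- classify_spacing(motifs[i, ], mode = mode, rules = rules,
                            prefer = prefer)
      if (i == 1L) assign <- a
      if (a$resolved != "unclassified") { picked <- i; assign <- a; break }
    }
    m <- motifs[picked, ]
    rep0$resolved <- assign$resolved
    rep0$compatible <- if (length(assign$compatible))
      paste(assign$compatible, collapse = ",") else "."
    rep0[c("g1", "g2", "g3", "g4", "g5")] <- m[c("g1", "g2", "g3", "g4", "g5")]
    rep0$n_offset <- m$n_offset
    rep0$c_tail <- m$c_tail
    rep0$cxc_x <- m$cxc_x
    rep0$cxc_polarity <- cxc_polarity(m$cxc_x)
  } else {
    defs <- find_deficient_motifs(s, mode = mode)
    if (nrow(defs))
      rep0$deficient_category <- paste(sort(unique(defs$category)), collapse = ",")
  }

  if (use_patterns) {
    pats <- builtin_patterns()
    rep0$patternI_match <- pattern_matches(s, pats$typeI)
    rep0$patternII_match <- pattern_matches(s, pats$typeII)
    rep0$pattern_agrees <- switch(rep0$resolved,
      I = rep0$patternI_match, II = rep0$patternII_match, NA)
  }

  if (!grepl("X", s, fixed = TRUE) && nzchar(s)) {
    rep0$mw_da <- molecular_weight(s)
    rep0$pi <- isoelectric_point(s)
  }
  rep0
}

#' Classify a set of sequences
#'
#' @param seqs record data.frame (`id`, `desc`, `seq`).
#' @inheritParams classify_sequence
#' @return data.frame, one row per record (see [classify_sequence()]).
#' @export
classify_set <- function(seqs, mode = c("core", "strict"),
                         use_patterns = FALSE, rules = spacing_rules(),
                         prefer = NULL) {
  mode <- match.arg(mode)
  do.call(rbind, lapply(seq_len(nrow(seqs)), function(i)
    classify_sequence(seqs$seq[i], id = seqs$id[i], mode = mode,
                      use_patterns = use_patterns, rules = rules,
                      prefer = prefer)))
}
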