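# Synthetic sequence generator: pattern-conforming sequences,
# type-spaced sequences, single-violation decoys and alignments with
# controlled conservation.  The spacer alphabet excludes cysteine by
# default so motif detection is unambiguous.

default_background <- function() setdiff(AA20, "C")

sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Sample sequences realizing a Prosite pattern
#'
#' Literals are copied, class residues sampled uniformly, negated-class
#' positions sampled uniformly from the complement, and wildcards filled
#' from the background alphabet with lengths drawn uniformly from the
#' repeat range.  Optional random N/C flanks can be added.
#'
#' @param pattern `prosite_pattern` or pattern string.
#' @param n number of sequences.
#' @param seed RNG seed (set for reproducibility; `NULL` leaves the RNG
#'   state alone).
#' @param background residue alphabet for wildcards/flanks (default: the
#'   19 non-cysteine standard residues).
#' @param flank_max maximum random flank length on each side (default 0).
#' @return record data.frame; attribute `"realization"` holds, per
#'   sequence, a data.frame of element spans (element, kind, start, end)
#'   for the embedded (flank-shifted) match.
#' @export
sample_from_pattern <- function(pattern, n, seed = NULL,
                                background = default_background(),
                                flank_max = 0L) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nm <- if (nzchar(pattern$name)) pattern$name else "pattern"
  ids <- sprintf("%s_sim%d", nm, seq_len(n))
  seqs <- character(n)
  realiz <- vector("list", n)
  for (s in seq_len(n)) {
    parts <- character(0)
    spans <- list()
    pos <- 1L
    for (ei in seq_along(pattern$elements)) {
      e <- pattern$elements[[ei]]
      k <- sample_one(e$rep_min:e$rep_max)
      chunk <- if (k == 0L) "" else switch(e$kind,
        literal = strrep(e$residues, k),
        class = paste(sample(e$residues, k, replace = TRUE), collapse = ""),
        negated_class = paste(sample(setdiff(AA20, e$residues), k,
                                     replace = TRUE), collapse = ""),
        wildcard = paste(sample(background, k, replace = TRUE), collapse = ""))
      spans[[ei]] <- data.frame(element = ei, kind = e$kind,
                                start = if (k > 0L) pos else NA_integer_,
                                end = if (k > 0L) pos + k - 1L else NA_integer_)
      parts <- c(parts, chunk)
      pos <- pos + k
    }
    core <- paste(parts, collapse = "")
    lf <- if (flank_max > 0L) sample_one(0:flank_max) else 0L
    rf <- if (flank_max > 0L) sample_one(0:flank_max) else 0L
    left <- if (lf) paste(sample(background, lf, replace = TRUE), collapse = "") else ""
    right <- if (rf) paste(sample(background, rf, replace = TRUE), collapse = "") else ""
    seqs[s] <- paste0(left, core, right)
    sp <- do.call(rbind, spans)
    sp$start <- sp$start + lf; sp$end <- sp$end + lf
    realiz[[s]] <- sp
  }
  out <- aa_records(ids, seqs, desc = sprintf("simulated from pattern %s", nm))
  attr(out, "realization") <- realiz
  attr(out, "pattern") <- pattern
  out
}

#' Sample type-spaced nsLTP-like sequences
#'
#' Draws the N-terminal offset, the five inter-cysteine gaps and the
#' C-terminal tail uniformly from the given type's spacing rule sets and
#' fills spacers from a cysteine-free background alphabet, so each
#' sequence carries exactly eight cysteines.  The CXC X residue is drawn
#' hydrophilic for Type I and hydrophobic for Types II-V, following the
#' observed polarity trend.
#'
#' @param type one of `"I"`..`"V"`.
#' @param n number of sequences.
#' @param seed RNG seed (optional).
#' @param background spacer alphabet (default: 19 non-cysteine residues).
#' @param rules spacing rule table (see [spacing_rules()]).
#' @return record data.frame; attribute `"gaps"` is an `n x 7` matrix
#'   (`n_offset`, `g1`..`g5`, `c_tail`) of the generating draws.
#' @export
sample_type_sequences <- function(type, n, seed = NULL,
                                  background = default_background(),
                                  rules = spacing_rules()) {
  stopifnot(type %in% names(rules))
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  r <- rules[[type]]
  cxc_pool <- if (type == "I") POLARITY_HYDROPHILIC else POLARITY_HYDROPHOBIC
  ids <- sprintf("type%s_sim%d", type, seq_len(n))
  seqs <- character(n)
  draws <- matrix(0L, n, 7,
                  dimnames = list(NULL, c("n_offset", "g1", "g2", "g3",
                                          "g4", "g5", "c_tail")))
  spacer <- function(k) if (k == 0L) "" else
    paste(sample(background, k, replace = TRUE), collapse = "")
  for (s in seq_len(n)) {
    g <- c(n_offset = sample_one(r$n_offset), g1 = sample_one(r$g1),
           g2 = sample_one(r$g2), g3 = sample_one(r$g3),
           g4 = sample_one(r$g4), g5 = sample_one(r$g5),
           c_tail = sample_one(r$c_tail))
    draws[s, ] <- g
    seqs[s] <- paste0(
      spacer(g["n_offset"]), "C", spacer(g["g1"]), "C", spacer(g["g2"]),
      "CC", spacer(g["g3"]), "C", sample_one(cxc_pool), "C",
      spacer(g["g4"]), "C", spacer(g["g5"]), "C", spacer(g["c_tail"]))
  }
  out <- aa_records(ids, seqs,
                    desc = sprintf("simulated type %s (gaps %s)", type,
                                   apply(draws[, 2:6, drop = FALSE], 1,
                                         paste, collapse = ",")))
  attr(out, "gaps") <- draws
  out
}

#' Generate single-violation decoys
#'
#' Each output sequence carries exactly one engineered violation,
#' recorded in its description:
#' \describe{
#'   \item{drop_cys}{one motif cysteine (chosen at random among the
#'     eight; for sequences without a full motif, any cysteine) is
#'     replaced by alanine, destroying the original 8-tuple.}
#'   \item{shift_gap}{one spacer residue is inserted or deleted so that
#'     one inter-cysteine gap leaves the source type's admissible set
#'     (requires `type`).}
#'   \item{shuffle_conserved}{the residues at non-cysteine conserved
#'     positions (literal and class elements of the generating pattern)
#'     are permuted until the pattern no longer matches; spacing is left
#'     intact (requires input produced by [sample_from_pattern()], or
#'     `pattern`).}
#' }
#'
#' @param seqs record data.frame whose members contain a detectable
#'   motif (or pattern realization for `shuffle_conserved`).
#' @param mode one of `"drop_cys"`, `"shift_gap"`, `"shuffle_conserved"`.
#' @param seed RNG seed (optional).
#' @param type source type for `shift_gap`.
#' @param pattern generating pattern for `shuffle_conserved` (defaults
#'   to the attribute left by [sample_from_pattern()]).
#' @param rules spacing rule table.
#' @return record data.frame of decoys (ids suffixed with the mode).
#' @export
make_decoys <- function(seqs, mode = c("drop_cys", "shift_gap",
                                       "shuffle_conserved"),
                        seed = NULL, type = NULL, pattern = NULL,
                        rules = spacing_rules()) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  background <- default_background()
  n <- nrow(seqs)
  out_seq <- character(n); out_desc <- character(n)

  realiz <- attr(seqs, "realization")
  if (mode == "shuffle_conserved") {
    if (is.character(pattern)) pattern <- parse_pattern(pattern)
    pattern <- pattern %||% attr(seqs, "pattern")
    if (is.null(pattern) && is.null(realiz))
      stop("shuffle_conserved needs `pattern` or sequences from sample_from_pattern()",
           call. = FALSE)
  }
  if (mode == "shift_gap" && is.null(type))
    stop("shift_gap needs the source `type`", call. = FALSE)

  for (i in seq_len(n)) {
    s <- seqs$seq[i]
    chars <- strsplit(s, "")[[1]]
    if (mode == "drop_cys") {
      m <- find_cys_motifs(s)
      if (nrow(m)) {
        pos <- as.integer(m[1, sprintf("c%d", sample_one(1:8))])
      } else {
        # no full 8-Cys motif (e.g. a short pattern realization): any
        # cysteine is load-bearing for the generating pattern
        cys <- which(chars == "C")
        if (!length(cys)) stop(sprintf("no motif in '%s'", seqs$id[i]), call. = FALSE)
        pos <- sample_one(cys)
      }
      chars[pos] <- "A"
      out_seq[i] <- paste(chars, collapse = "")
      out_desc[i] <- sprintf("decoy drop_cys: C%d -> A", pos)
    } else if (mode == "shift_gap") {
      m <- find_cys_motifs(s)
      if (!nrow(m)) stop(sprintf("no motif in '%s'", seqs$id[i]), call. = FALSE)
      m <- m[1, ]
      slot <- sample_one(1:5)
      gname <- sprintf("g%d", slot)
      g <- as.integer(m[[gname]])
      adm <- rules[[type]][[gname]]
      # push the gap one residue outside the admissible set
      delta <- if (!((g + 1L) %in% adm)) 1L
               else if (g > 1L && !((g - 1L) %in% adm)) -1L
               else { # walk outward until the set is left
                 dd <- 1L
                 while ((g + dd) %in% adm) dd <- dd + 1L
                 dd
               }
      left_cys <- as.integer(m[[c("c1", "c2", "c4", "c6", "c7")[slot]]])
      if (delta > 0L) {
        ins <- sample(background, delta, replace = TRUE)
        chars <- append(chars, ins, after = left_cys)
      } else {
        chars <- chars[-(left_cys + 1L)]
      }
      out_seq[i] <- paste(chars, collapse = "")
      out_desc[i] <- sprintf("decoy shift_gap: g%d %d -> %d (type %s)",
                             slot, g, g + delta, type)
    } else { # shuffle_conserved
      sp <- if (!is.null(realiz)) realiz[[i]]
            else pattern_realization(s, pattern)
      if (is.null(sp)) stop(sprintf("no pattern match in '%s'", seqs$id[i]),
                            call. = FALSE)
      cons <- sp[sp$kind %in% c("literal", "class") & !is.na(sp$start), ]
      posns <- unlist(lapply(seq_len(nrow(cons)), function(k)
        cons$start[k]:cons$end[k]))
      posns <- posns[chars[posns] != "C"]
      if (length(posns) < 2L)
        stop("too few non-cysteine conserved positions to shuffle", call. = FALSE)
      pat <- pattern %||% NULL
      ok <- FALSE
      for (try in 1:50) {
        perm <- sample(posns)
        cand <- chars
        cand[posns] <- chars[perm]
        cs <- paste(cand, collapse = "")
        still <- if (!is.null(pat)) pattern_matches(cs, pat)
                 else !is.null(pattern_realization_check(cs, sp, chars))
        if (!still) { chars <- cand; ok <- TRUE; break }
      }
      if (!ok) {
        # force a violation: overwrite one conserved position with a
        # residue that cannot satisfy its element
        k <- cons$element[1]
        p <- cons$start[1]
        chars[p] <- if (chars[p] == "A") "G" else "A"
        if (!is.null(pat)) {
          e <- pat$elements[[k]]
          bad <- setdiff(AA20, c(e$residues, "C"))
          chars[p] <- bad[1]
        }
      }
      out_seq[i] <- paste(chars, collapse = "")
      out_desc[i] <- "decoy shuffle_conserved: conserved residues permuted"
    }
  }
  aa_records(paste0(seqs$id, "_", mode), out_seq, desc = out_desc)
}

# With only a realization (no pattern object), treat the permutation as
# violating when any conserved position changed; conservative stand-in
# used only when the generating pattern is unavailable.
pattern_realization_check <- function(cand, spans, orig_chars) {
  cc <- strsplit(cand, "")[[1]]
  if (identical(cc, orig_chars)) spans else NULL
}

#' Synthetic alignment from a pattern
#'
#' Columns of fixed-length elements are aligned directly; variable-length
#' wildcard runs are right-padded with gaps to the longest realized
#' length.  At conserved (literal/class) columns each residue is
#' replaced, with probability `1 - conservation`, by a random background
#' residue.
#'
#' @param pattern `prosite_pattern` or string.
#' @param n number of members (>= 2).
#' @param seed RNG seed (optional).
#' @param conservation probability a conserved column keeps its
#'   pattern-conforming residue (default 1.0).
#' @param background background alphabet.
#' @return an `ltp_alignment`.
#' @export
synthetic_alignment <- function(pattern, n, seed = NULL, conservation = 1.0,
                                background = default_background()) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(n >= 2L, conservation >= 0, conservation <= 1)
  if (!is.null(seed)) set.seed(seed)
  elems <- pattern$elements
  ne <- length(elems)
  # realize each element for each member
  chunks <- matrix("", n, ne)
  lens <- matrix(0L, n, ne)
  for (s in seq_len(n)) {
    for (ei in seq_len(ne)) {
      e <- elems[[ei]]
      k <- sample_one(e$rep_min:e$rep_max)
      ch <- if (k == 0L) "" else switch(e$kind,
        literal = strrep(e$residues, k),
        class = paste(sample(e$residues, k, replace = TRUE), collapse = ""),
        negated_class = paste(sample(setdiff(AA20, e$residues), k,
                                     replace = TRUE), collapse = ""),
        wildcard = paste(sample(background, k, replace = TRUE), collapse = ""))
      if (e$kind %in% c("literal", "class") && conservation < 1 && k > 0L) {
        cc <- strsplit(ch, "")[[1]]
        flip <- stats::runif(k) > conservation
        if (any(flip))
          cc[flip] <- sample(background, sum(flip), replace = TRUE)
        ch <- paste(cc, collapse = "")
      }
      chunks[s, ei] <- ch
      lens[s, ei] <- k
    }
  }
  # pad variable elements with gaps to max realized length
  aligned <- vapply(seq_len(n), function(s) {
    paste(vapply(seq_len(ne), function(ei) {
      w <- max(lens[, ei])
      paste0(chunks[s, ei], strrep("-", w - lens[s, ei]))
    }, ""), collapse = "")
  }, "")
  nm <- if (nzchar(pattern$name)) pattern$name else "pattern"
  as_alignment(aa_records(sprintf("%s_aln%d", nm, seq_len(n)), aligned,
                          desc = sprintf("synthetic alignment of %s", nm)))
}

#' Manifest table for simulated sequence sets
#'
#' @param seqs record data.frame from a generator.
#' @param generator generator name.
#' @param seed seed used.
#' @param type_or_pattern type or pattern label.
#' @return data.frame `sequence_id`, `generator`, `seed`,
#'   `type_or_pattern`, `violation` (from decoy descriptions, else ".").
#' @export
simulation_manifest <- function(seqs, generator, seed = NA_integer_,
                                type_or_pattern = ".") {
  viol <- ifelse(grepl("^decoy ", seqs$desc), seqs$desc, ".")
  data.frame(sequence_id = seqs$id, generator = generator, seed = seed,
             type_or_pattern = type_or_pattern, violation = viol,
             stringsAsFactors = FALSE)
}
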