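# Detection of the conserved eight-cysteine scaffold
# C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C and of its cysteine-deficient variants.
#
# All coordinates are 1-based (R / protein convention).  Gap counts g1..g5
# are the numbers of residues intervening between Cys1-Cys2, Cys2-Cys3,
# Cys4-Cys5, Cys6-Cys7 and Cys7-Cys8; the Cys3Cys4 pair is adjacent and
# Cys5/Cys6 enclose exactly one residue (the CXC block).

#' Find eight-cysteine motifs
#'
#' Enumerates every increasing 8-tuple of cysteine positions that
#' satisfies the scaffold constraints: Cys3/Cys4 adjacent, Cys5/Cys6
#' separated by exactly one residue, and at least one residue in each of
#' the five inter-cysteine gaps.  Candidates are sorted by (Cys1
#' position, total span).
#'
#' @param seq residue string or single-row record data.frame.
#' @param max_candidates abort with an error if more candidates than this
#'   exist (default 10000).
#' @return data.frame with columns `c1`..`c8` (1-based positions),
#'   `g1`..`g5`, `n_offset`, `c_tail`, `cxc_x`; zero rows if no motif.
#' @export
find_cys_motifs <- function(seq, max_candidates = 10000L) {
  stopifnot(max_candidates >= 1L)
  s <- residue_string(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  cpos <- which(chars == "C")

  cc <- cpos[(cpos + 1L) %in% cpos]              # Cys3 candidates (CC block)
  cxc <- cpos[(cpos + 2L) %in% cpos]             # Cys5 candidates (CXC block)

  rows <- list()
  count <- 0L
  for (c3 in cc) {
    c4 <- c3 + 1L
    c12 <- cpos[cpos <= c3 - 2L]                 # g2 >= 1
    if (length(c12) < 2L) next
    for (c5 in cxc[cxc >= c4 + 2L]) {            # g3 >= 1
      c6 <- c5 + 2L
      c78 <- cpos[cpos >= c6 + 2L]               # g4 >= 1
      if (length(c78) < 2L) next
      for (i1 in seq_len(length(c12) - 1L)) {
        c1 <- c12[i1]
        c2s <- c12[c12 >= c1 + 2L]               # g1 >= 1
        for (c2 in c2s[c2s <= c3 - 2L]) {
          for (i7 in seq_len(length(c78) - 1L)) {
            c7 <- c78[i7]
            for (c8 in c78[c78 >= c7 + 2L]) {    # g5 >= 1
              count <- count + 1L
              if (count > max_candidates)
                stop(sprintf(paste0("combinatorial explosion: more than %d motif",
                                    " candidates (sequence has %d cysteines)"),
                             max_candidates, length(cpos)), call. = FALSE)
              rows[[count]] <- c(c1, c2, c3, c4, c5, c6, c7, c8)
            }
          }
        }
      }
    }
  }
  if (!count) return(empty_motif_frame())
  m <- do.call(rbind, rows)
  out <- data.frame(c1 = m[, 1], c2 = m[, 2], c3 = m[, 3], c4 = m[, 4],
                    c5 = m[, 5], c6 = m[, 6], c7 = m[, 7], c8 = m[, 8])
  out$g1 <- out$c2 - out$c1 - 1L
  out$g2 <- out$c3 - out$c2 - 1L
  out$g3 <- out$c5 - out$c4 - 1L
  out$g4 <- out$c7 - out$c6 - 1L
  out$g5 <- out$c8 - out$c7 - 1L
  out$n_offset <- out$c1 - 1L
  out$c_tail <- n - out$c8
  out$cxc_x <- chars[out$c5 + 1L]
  out[order(out$c1, out$c8 - out$c1), , drop = FALSE]
}

empty_motif_frame <- function() {
  data.frame(c1 = integer(0), c2 = integer(0), c3 = integer(0),
             c4 = integer(0), c5 = integer(0), c6 = integer(0),
             c7 = integer(0), c8 = integer(0),
             g1 = integer(0), g2 = integer(0), g3 = integer(0),
             g4 = integer(0), g5 = integer(0),
             n_offset = integer(0), c_tail = integer(0),
             cxc_x = character(0))
}

# Cysteine-deficient scaffold categories: block skeletons and the
# admissible residue counts between blocks (and before/after), as unions
# of exact values and inclusive ranges.  NULL means unconstrained.
deficient_rules <- function() {
  list(
    A = list(blocks = c("C", "CC", "CXC", "C", "C"),
             n_offset = c(1:13, 18, 29),
             gaps = list(c(8, 13:16), c(8, 9, 16:19), c(22, 23), 6:14),
             c_tail = 1:6),
    B = list(blocks = c("C", "C", "CC", "CXC", "C"),
             n_offset = c(1:3, 11),
             gaps = list(c(7, 9), 13:16, c(8, 12, 19), c(21:24, 36)),
             c_tail = c(4, 10, 13, 33, 64)),
    C = list(blocks = c("C", "CC", "CXC", "C"),
             n_offset = c(4, 9),
             gaps = list(13, c(15, 19), c(22, 45)),
             c_tail = c(1, 11, 12)),
    D = list(blocks = c("C", "CC", "CXC", "C"),
             n_offset = NULL,
             gaps = list(1:11, 19, 21:23),
             c_tail = c(4, 5, 10, 12))
  )
}

block_width <- function(b) c(C = 1L, CC = 2L, CXC = 3L)[[b]]

# Is every cysteine slot of block `b` starting at `pos` a 'C'?
block_at <- function(chars, b, pos) {
  w <- block_width(b)
  if (pos < 1L || pos + w - 1L > length(chars)) return(FALSE)
  idx <- switch(b, C = pos, CC = c(pos, pos + 1L), CXC = c(pos, pos + 2L))
  all(chars[idx] == "C")
}

#' Find cysteine-deficient scaffold variants
#'
#' Applies only when no full 8-Cys motif exists (the full motif takes
#' precedence and yields an empty result here).  A candidate matches a
#' category when its block skeleton (drawn from C / CC / CXC blocks)
#' equals the category's skeleton and every inter-block residue count
#' lies in the category's admissible set.  Categories C and D share a
#' skeleton; a placement satisfying both is reported under both.
#'
#' @param seq residue string or single-row record data.frame.
#' @param mode `"core"` tests inter-block gaps only; `"strict"` also
#'   tests the N-terminal offset and C-terminal tail sets.
#' @return data.frame with `category`, `positions` (comma-joined 1-based
#'   cysteine positions), `gaps` (comma-joined inter-block counts),
#'   `n_offset`, `c_tail`.
#' @export
find_deficient_motifs <- function(seq, mode = c("core", "strict")) {
  mode <- match.arg(mode)
  s <- residue_string(seq)
  if (nrow(find_cys_motifs(s)) > 0L) return(empty_deficient_frame())
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  rules <- deficient_rules()
  out <- list()
  for (cat in names(rules)) {
    r <- rules[[cat]]
    placements <- place_blocks(chars, r$blocks, r$gaps)
    for (pl in placements) {
      n_offset <- pl$starts[1] - 1L
      last <- pl$starts[length(pl$starts)] + block_width(r$blocks[length(r$blocks)]) - 1L
      c_tail <- n - last
      if (mode == "strict") {
        if (!is.null(r$n_offset) && !(n_offset %in% r$n_offset)) next
        if (!is.null(r$c_tail) && !(c_tail %in% r$c_tail)) next
      }
      cys <- unlist(lapply(seq_along(r$blocks), function(k) {
        p <- pl$starts[k]
        switch(r$blocks[k], C = p, CC = c(p, p + 1L), CXC = c(p, p + 2L))
      }))
      out[[length(out) + 1L]] <- data.frame(
        category = cat,
        positions = paste(cys, collapse = ","),
        gaps = paste(pl$gaps, collapse = ","),
        n_offset = n_offset, c_tail = c_tail,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_deficient_frame())
  unique(do.call(rbind, out))
}

empty_deficient_frame <- function() {
  data.frame(category = character(0), positions = character(0),
             gaps = character(0), n_offset = integer(0), c_tail = integer(0))
}

# Enumerate placements of a block skeleton where the residue count
# between consecutive blocks lies in the given admissible sets.
place_blocks <- function(chars, blocks, gap_sets) {
  n <- length(chars)
  res <- list()
  rec <- function(k, starts, gaps) {
    if (k > length(blocks)) {
      res[[length(res) + 1L]] <<- list(starts = starts, gaps = gaps)
      return(invisible())
    }
    b <- blocks[k]
    if (k == 1L) {
      for (p in seq_len(n)) if (block_at(chars, b, p)) rec(2L, p, integer(0))
    } else {
      prev_end <- starts[k - 1L] + block_width(blocks[k - 1L]) - 1L
      for (g in gap_sets[[k - 1L]]) {
        p <- prev_end + g + 1L
        if (p + block_width(b) - 1L > n) next
        if (block_at(chars, b, p)) rec(k + 1L, c(starts, p), c(gaps, g))
      }
    }
  }
  rec(1L, integer(0), integer(0))
  res
}

#' Tabular motif report for a sequence set
#'
#' @param seqs record data.frame.
#' @param max_candidates passed to [find_cys_motifs()].
#' @return data.frame `sequence_id`, `cys1`..`cys8` (1-based), `g1`..`g5`,
#'   `n_offset`, `c_tail`, `cxc_x` — one row per motif candidate.
#' @export
motif_report <- function(seqs, max_candidates = 10000L) {
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    m <- find_cys_motifs(seqs$seq[i], max_candidates)
    if (!nrow(m)) return(NULL)
    data.frame(sequence_id = seqs$id[i],
               cys1 = m$c1, cys2 = m$c2, cys3 = m$c3, cys4 = m$c4,
               cys5 = m$c5, cys6 = m$c6, cys7 = m$c7, cys8 = m$c8,
               g1 = m$g1, g2 = m$g2, g3 = m$g3, g4 = m$g4, g5 = m$g5,
               n_offset = m$n_offset, c_tail = m$c_tail, cxc_x = m$cxc_x,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(sequence_id = character(0), cys1 = integer(0),
                      cys2 = integer(0), cys3 = integer(0), cys4 = integer(0),
                      cys5 = integer(0), cys6 = integer(0), cys7 = integer(0),
                      cys8 = integer(0), g1 = integer(0), g2 = integer(0),
                      g3 = integer(0), g4 = integer(0), g5 = integer(0),
                      n_offset = integer(0), c_tail = integer(0),
                      cxc_x = character(0)))
  do.call(rbind, rows)
}
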