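# Prosite-styled pattern induction from a multiple alignment by
# per-column amino-acid occurrence.

#' Per-column residue occurrence profiles
#'
#' @param aln an `ltp_alignment` (see [read_alignment()]).
#' @return data.frame with `column_index`, `occupancy` (fraction of
#'   non-gap members) and a list-column `counts` (named integer vectors
#'   over non-gap residues).
#' @export
column_profiles <- function(aln) {
  stopifnot(inherits(aln, "ltp_alignment"))
  mat <- alignment_matrix(aln)
  n <- nrow(mat)
  profs <- lapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    counts <- if (length(res)) table(res) else table(character(0))
    list(column_index = j, occupancy = length(res) / n,
         counts = setNames(as.integer(counts), names(counts)))
  })
  data.frame(column_index = vapply(profs, `[[`, 1L, "column_index"),
             occupancy = vapply(profs, `[[`, 1, "occupancy"),
             counts = I(lapply(profs, `[[`, "counts")))
}

alignment_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seq, ""))
}

#' Induce a Prosite-styled pattern from an alignment
#'
#' Per column: if the most frequent non-gap residue reaches
#' `literal_threshold` the column becomes a literal; otherwise, if the
#' smallest frequency-descending residue set whose cumulative frequency
#' reaches `class_cum_threshold` has at most `class_max_size` members,
#' the column becomes a class (residues in descending frequency, ties
#' alphabetical); otherwise — or whenever occupancy falls below
#' `min_occupancy` — the column is a wildcard.  Maximal runs of wildcard
#' columns collapse into `x(m,M)`, where `m`/`M` are the minimum/maximum
#' per-member non-gap residue counts over the run, so every member's
#' de-gapped run length is representable.  With `anchor_cys = TRUE` a
#' column whose non-gap residues are all cysteine is always emitted as a
#' literal `C` regardless of occupancy, pinning the scaffold.
#'
#' @param aln an `ltp_alignment` with at least 2 members.
#' @param literal_threshold top-residue frequency needed for a literal
#'   (default 0.90).
#' @param class_cum_threshold cumulative frequency a class must reach
#'   (default 0.90).
#' @param class_max_size largest class emitted (default 4).
#' @param min_occupancy minimum non-gap fraction for a non-wildcard
#'   column (default 0.50).
#' @param anchor_cys always emit all-cysteine columns as literal C
#'   (default TRUE).
#' @param name name for the induced pattern.
#' @return a `prosite_pattern`; attribute `"column_report"` holds a
#'   data.frame (`column`, `decision`, `top_residues`, `frequencies`).
#' @export
induce_pattern <- function(aln, literal_threshold = 0.90,
                           class_cum_threshold = 0.90, class_max_size = 4L,
                           min_occupancy = 0.50, anchor_cys = TRUE,
                           name = "induced") {
  stopifnot(inherits(aln, "ltp_alignment"))
  if (length(aln$id) < 2L)
    stop("insufficient data: pattern induction needs at least 2 members",
         call. = FALSE)
  stopifnot(literal_threshold > 0, literal_threshold <= 1,
            class_cum_threshold > 0, class_cum_threshold <= 1,
            class_max_size >= 2L)
  mat <- alignment_matrix(aln)

  decide <- function(j) {
    col <- mat[, j]
    res <- col[col != "-"]
    occ <- length(res) / length(col)
    if (!length(res)) return(list(decision = "wildcard", residues = character(0)))
    counts <- table(res)
    # descending frequency, ties alphabetical
    ord <- order(-as.integer(counts), names(counts))
    freqs <- as.integer(counts)[ord] / length(res)
    resid <- names(counts)[ord]
    if (anchor_cys && all(res == "C"))
      return(list(decision = "literal", residues = "C", freqs = 1))
    if (occ < min_occupancy)
      return(list(decision = "wildcard", residues = resid, freqs = freqs))
    if (freqs[1] >= literal_threshold && resid[1] != "X")
      return(list(decision = "literal", residues = resid[1], freqs = freqs[1]))
    k <- which(cumsum(freqs) >= class_cum_threshold)[1]
    if (!is.na(k) && k <= class_max_size && !("X" %in% resid[seq_len(k)]))
      return(list(decision = "class", residues = resid[seq_len(k)],
                  freqs = freqs[seq_len(k)]))
    list(decision = "wildcard", residues = resid, freqs = freqs)
  }

  decisions <- lapply(seq_len(ncol(mat)), decide)
  kinds <- vapply(decisions, `[[`, "", "decision")

  elements <- list()
  report <- list()
  j <- 1L
  while (j <= ncol(mat)) {
    d <- decisions[[j]]
    if (d$decision != "wildcard") {
      elements <- c(elements, list(new_element(d$decision, d$residues, 1L, 1L)))
      report[[length(report) + 1L]] <- data.frame(
        column = j, decision = d$decision,
        top_residues = paste(d$residues, collapse = ","),
        frequencies = paste(sprintf("%.3f", d$freqs), collapse = ","),
        stringsAsFactors = FALSE)
      j <- j + 1L
    } else {
      run <- j
      while (run < ncol(mat) && kinds[run + 1L] == "wildcard") run <- run + 1L
      lens <- vapply(seq_len(nrow(mat)), function(i)
        sum(mat[i, j:run] != "-"), 0L)
      m <- min(lens); M <- max(lens)
      if (M > 0L)
        elements <- c(elements, list(new_element("wildcard", character(0),
                                                 as.integer(m), as.integer(M))))
      report[[length(report) + 1L]] <- data.frame(
        column = j, decision = sprintf("wildcard_run[%d-%d]->x(%d,%d)",
                                       j, run, m, M),
        top_residues = ".", frequencies = ".", stringsAsFactors = FALSE)
      j <- run + 1L
    }
  }
  if (!length(elements))
    stop("insufficient data: no pattern elements could be induced", call. = FALSE)
  p <- new_pattern(elements, name = name)
  attr(p, "column_report") <- do.call(rbind, report)
  p
}
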