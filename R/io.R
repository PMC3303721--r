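# Sequence and alignment input/output.
#
# Sequence sets are plain data.frames with columns `id`, `desc`, `seq`
# (uppercase one-letter residues).  Alignments are "ltp_alignment"
# objects: list(id, desc, seq, ncol) where every seq has the same number
# of characters including '-' gaps.

#' Construct a sequence record set
#'
#' @param id character vector of identifiers (non-empty, no whitespace).
#' @param seq character vector of residue strings (uppercased here).
#' @param desc optional descriptions (default "").
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
aa_records <- function(id, seq, desc = "") {
  stopifnot(length(id) == length(seq))
  if (any(!nzchar(id)) || any(grepl("[[:space:]]", id)))
    stop("identifiers must be non-empty and contain no whitespace")
  data.frame(id = as.character(id),
             desc = rep_len(as.character(desc), length(id)),
             seq = toupper(as.character(seq)),
             stringsAsFactors = FALSE)
}

# Resolve a `source` argument into raw text lines: a file path, a single
# string with embedded newlines, or an already-split character vector.
source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  if (length(source) == 1L)
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  as.character(source)
}

validate_residue_line <- function(line, lineno, allow_gap = TRUE) {
  chars <- strsplit(line, "")[[1]]
  legal <- if (allow_gap) RESIDUE_CHARS else setdiff(RESIDUE_CHARS, "-")
  bad <- setdiff(unique(chars), legal)
  if (length(bad))
    stop(sprintf("parse error at line %d: illegal residue character(s) %s",
                 lineno, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  chars
}

#' Read protein sequences from FASTA
#'
#' Residues are uppercased and a single terminal '*' (stop) is stripped.
#' Duplicate identifiers are renamed with a numeric suffix (`_2`, `_3`,
#' ...) and a warning is raised.  Residue characters outside the 20
#' standard amino acids, `X` and `-` cause a parse error naming the
#' offending line.
#'
#' @param source file path, a single FASTA string, or a character vector
#'   of lines.
#' @return data.frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(source) {
  lines <- source_lines(source)
  lines <- sub("\r$", "", lines)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no records: input contains no FASTA headers", call. = FALSE)
  if (any(nzchar(trimws(lines[seq_len(which(hdr)[1] - 1)]))))
    stop("parse error: residue data before first header", call. = FALSE)

  idx <- which(hdr)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  for (k in seq_along(idx)) {
    h <- sub("^>", "", lines[idx[k]])
    id <- sub("[[:space:]].*$", "", h)
    if (!nzchar(id))
      stop(sprintf("parse error at line %d: empty identifier", idx[k]), call. = FALSE)
    desc <- if (grepl("[[:space:]]", h)) trimws(sub("^[^[:space:]]+[[:space:]]+", "", h)) else ""
    from <- idx[k] + 1L
    to <- if (k < length(idx)) idx[k + 1L] - 1L else length(lines)
    body <- character(0)
    stop_at <- NA_integer_
    for (ln in seq(from, length.out = max(0L, to - from + 1L))) {
      piece <- toupper(gsub("[[:space:]]", "", lines[ln]))
      if (!nzchar(piece)) next
      if (grepl("\\*", piece)) {
        if (!grepl("^[^*]*\\*$", piece))
          stop(sprintf("parse error at line %d: '*' only allowed as terminal stop", ln),
               call. = FALSE)
        piece <- sub("\\*$", "", piece)
        stop_at <- ln
      } else if (!is.na(stop_at)) {
        stop(sprintf("parse error at line %d: residues after terminal stop (line %d)",
                     ln, stop_at), call. = FALSE)
      }
      if (nzchar(piece)) validate_residue_line(piece, ln)
      body <- c(body, piece)
    }
    res <- paste(body, collapse = "")
    if (!nzchar(res))
      stop(sprintf("no records: record '%s' has an empty residue string", id),
           call. = FALSE)
    ids <- c(ids, id); descs <- c(descs, desc); seqs <- c(seqs, res)
  }

  # duplicate identifiers get a numeric suffix
  if (anyDuplicated(ids)) {
    seen <- new.env(parent = emptyenv())
    for (i in seq_along(ids)) {
      n <- (get0(ids[i], envir = seen) %||% 0L) + 1L
      assign(ids[i], n, envir = seen)
      if (n > 1L) {
        warning(sprintf("duplicate identifier '%s' renamed to '%s_%d'",
                        ids[i], ids[i], n), call. = FALSE)
        ids[i] <- sprintf("%s_%d", ids[i], n)
      }
    }
  }
  data.frame(id = ids, desc = descs, seq = seqs, stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' Residue lines are wrapped at 60 columns.
#'
#' @param seqs data.frame with columns `id`, `desc`, `seq`.
#' @param path output file; if `NULL` the lines are returned invisibly.
#' @param width wrap width (default 60).
#' @return invisibly, the FASTA lines.
#' @export
write_fasta <- function(seqs, path = NULL, width = 60L) {
  out <- character(0)
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(seqs$desc[i])) paste0(">", seqs$id[i], " ", seqs$desc[i])
           else paste0(">", seqs$id[i])
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA and Clustal formats.  Clustal conservation
#' lines (the `* : .` annotation rows) and per-line residue counts are
#' ignored.  All members must have identical aligned lengths.
#'
#' @param source file path, string, or lines (see [read_fasta()]).
#' @param format `"fasta"` or `"clustal"`.
#' @return an `ltp_alignment`: list with `id`, `desc`, `seq`, `ncol`.
#' @export
read_alignment <- function(source, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  recs <- if (format == "fasta") read_fasta(source) else read_clustal(source)
  as_alignment(recs)
}

#' Assemble an alignment object from gapped records
#'
#' @param recs data.frame with `id`, `desc`, `seq` (gapped residues).
#' @return an `ltp_alignment`.
#' @export
as_alignment <- function(recs) {
  if (nrow(recs) < 2L)
    stop("alignment must have at least 2 members", call. = FALSE)
  lens <- nchar(recs$seq)
  if (length(unique(lens)) != 1L) {
    modal <- as.integer(names(which.max(table(lens))))
    off <- recs$id[lens != modal]
    if (!length(off)) off <- recs$id
    stop(sprintf("alignment-shape error: unequal aligned lengths for: %s",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  structure(list(id = recs$id, desc = recs$desc, seq = recs$seq,
                 ncol = lens[1]),
            class = "ltp_alignment")
}

#' @export
print.ltp_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d members x %d columns\n", length(x$id), x$ncol))
  invisible(x)
}

read_clustal <- function(source) {
  lines <- source_lines(source)
  lines <- sub("\r$", "", lines)
  ids <- character(0)
  segs <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (i == 1L && grepl("^(CLUSTAL|MUSCLE)", ln, ignore.case = TRUE)) next
    if (!nzchar(trimws(ln))) next
    # conservation rows start with whitespace or contain only * : . and space
    if (grepl("^[[:space:]]", ln) || grepl("^[*:. ]+$", ln)) next
    m <- regmatches(ln, regexec("^([^[:space:]]+)[[:space:]]+([A-Za-z.-]+)([[:space:]]+[0-9]+)?[[:space:]]*$", ln))[[1]]
    if (length(m) == 0)
      stop(sprintf("parse error at line %d: malformed Clustal row", i), call. = FALSE)
    id <- m[2]; seg <- toupper(gsub("\\.", "-", m[3]))
    validate_residue_line(seg, i)
    if (!(id %in% ids)) { ids <- c(ids, id); segs[[id]] <- character(0) }
    segs[[id]] <- c(segs[[id]], seg)
  }
  if (!length(ids)) stop("no records: empty Clustal input", call. = FALSE)
  data.frame(id = ids, desc = "",
             seq = vapply(segs[ids], paste, "", collapse = ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove 100 percent identical sequences
#'
#' Two records are redundant iff their residue strings are byte-identical
#' (descriptions are ignored).  The first occurrence is kept; order is
#' preserved.
#'
#' @param seqs data.frame with `id`, `desc`, `seq`.
#' @return list with `kept` (data.frame) and `removed`
#'   (data.frame `removed_id`, `kept_id`).
#' @export
dedupe_identical <- function(seqs) {
  first <- !duplicated(seqs$seq)
  rep_id <- seqs$id[first][match(seqs$seq, seqs$seq[first])]
  removed <- data.frame(removed_id = seqs$id[!first],
                        kept_id = rep_id[!first],
                        stringsAsFactors = FALSE)
  list(kept = seqs[first, , drop = FALSE], removed = removed)
}
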