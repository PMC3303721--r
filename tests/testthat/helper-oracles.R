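# Independent oracles used across the suite.  These deliberately take a
# different route than the package implementation: mechanical regex
# translation + brute-force substring matching for the pattern engine,
# exhaustive combination scans for the motif finder, fine-grid search
# for the isoelectric point.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Translate a prosite_pattern into a PCRE regular expression encoding the
# same semantics ('X' in a sequence matches only wildcards).
pattern_to_regex <- function(pattern) {
  pieces <- vapply(pattern$elements, function(e) {
    body <- switch(e$kind,
      literal = e$residues,
      class = paste0("[", paste(e$residues, collapse = ""), "]"),
      # X matches nothing except wildcards: spell out the allowed set
      negated_class = paste0("[", paste(setdiff(AA20_T, e$residues),
                                        collapse = ""), "]"),
      wildcard = ".")
    if (e$rep_min == 1L && e$rep_max == 1L) body
    else sprintf("(?:%s){%d,%d}", body, e$rep_min, e$rep_max)
  }, "")
  paste0(pieces, collapse = "")
}

# All match spans by brute force: test the anchored regex against every
# substring.  Returns a data.frame like scan_pattern().
oracle_spans <- function(seq, pattern) {
  n <- nchar(seq)
  rx <- paste0("^(?:", pattern_to_regex(pattern), ")$")
  starts <- if (pattern$anchored_start) 1L else seq_len(max(n, 0L))
  ss <- integer(0); ee <- integer(0)
  for (st in starts) {
    ends <- st:n
    if (pattern$anchored_end) ends <- n
    if (!length(ends) || n == 0L) next
    hit <- grepl(rx, substring(seq, st, ends), perl = TRUE)
    if (any(hit)) { ss <- c(ss, rep.int(st, sum(hit))); ee <- c(ee, ends[hit]) }
  }
  ord <- order(ss, ee)
  data.frame(start = ss[ord], end = ee[ord])
}

# Random pattern over a small alphabet: <=10 elements mixing all kinds.
random_pattern <- function(max_elems = 10L, alphabet = c("A", "C", "D", "G", "L")) {
  ne <- sample(1:max_elems, 1L)
  elems <- lapply(seq_len(ne), function(i) {
    kind <- sample(c("literal", "class", "negated_class", "wildcard"), 1L,
                   prob = c(0.35, 0.25, 0.1, 0.3))
    reps <- if (kind == "wildcard") sort(sample(0:4, 2L, replace = TRUE))
            else if (stats::runif(1) < 0.25) sort(sample(1:3, 2L, replace = TRUE))
            else c(1L, 1L)
    if (reps[2] == 0L) reps <- c(0L, 1L)
    res <- switch(kind,
      literal = sample(alphabet, 1L),
      class = sample(alphabet, sample(2:3, 1L)),
      negated_class = sample(alphabet, sample(1:2, 1L)),
      wildcard = character(0))
    list(kind = kind, residues = res,
         rep_min = as.integer(reps[1]), rep_max = as.integer(reps[2]))
  })
  anch_s <- stats::runif(1) < 0.15
  anch_e <- stats::runif(1) < 0.15
  structure(list(name = "rnd", elements = elems,
                 anchored_start = anch_s, anchored_end = anch_e),
            class = "prosite_pattern")
}

random_sequence <- function(max_len = 60L,
                            alphabet = c("A", "C", "D", "G", "L", "X")) {
  n <- sample(0:max_len, 1L)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force 8-Cys motif enumeration over all 8-combinations of
# cysteine indices (practical for sequences with <= 12 cysteines).
brute_cys_motifs <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  cpos <- which(chars == "C")
  out <- list()
  if (length(cpos) >= 8L) {
    for (comb in utils::combn(cpos, 8L, simplify = FALSE)) {
      p <- comb
      if (p[4] != p[3] + 1L) next
      if (p[6] != p[5] + 2L) next
      g <- c(p[2] - p[1] - 1L, p[3] - p[2] - 1L, p[5] - p[4] - 1L,
             p[7] - p[6] - 1L, p[8] - p[7] - 1L)
      if (any(g < 1L)) next
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

# Equivalence check between a pair of span data.frames.
same_spans <- function(a, b) {
  isTRUE(all.equal(as.data.frame(a), as.data.frame(b),
                   check.attributes = FALSE)) ||
    (nrow(a) == 0L && nrow(b) == 0L)
}

# Build an additive distance matrix from a fixed unrooted 4/5-taxon tree
# description (leaf branch lengths + internal edges), for NJ oracles.
additive_matrix_4 <- function(la, lb, lc, ld, uv) {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- la + lb
  d["a", "c"] <- la + uv + lc
  d["a", "d"] <- la + uv + ld
  d["b", "c"] <- lb + uv + lc
  d["b", "d"] <- lb + uv + ld
  d["c", "d"] <- lc + ld
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# caterpillar 5-taxon: a,b join u; u,c join v; v,d join w; e on w
additive_matrix_5 <- function(la, lb, lc, ld, le, uv, vw) {
  leaves <- letters[1:5]
  d <- matrix(0, 5, 5, dimnames = list(leaves, leaves))
  d["a", "b"] <- la + lb
  d["a", "c"] <- la + uv + lc
  d["b", "c"] <- lb + uv + lc
  d["a", "d"] <- la + uv + vw + ld
  d["b", "d"] <- lb + uv + vw + ld
  d["c", "d"] <- lc + vw + ld
  d["a", "e"] <- la + uv + vw + le
  d["b", "e"] <- lb + uv + vw + le
  d["c", "e"] <- lc + vw + le
  d["d", "e"] <- ld + le
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}
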