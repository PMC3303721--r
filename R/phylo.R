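# Pairwise-identity distances and UPGMA / neighbor-joining trees.
#
# Global (end-to-end) alignment uses the Gotoh affine-gap algorithm with
# BLOSUM62 substitution scores, gap open 10 and gap extend 0.5 (a gap of
# length L costs open + (L-1)*extend).  Identity is the fraction of
# identical aligned pairs over all aligned columns.

# Standard BLOSUM62 substitution scores (20 residues); pairs involving
# the unknown residue X score -1.
blosum62 <- function() {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4)
  m <- matrix(v, 20, 20, byrow = TRUE, dimnames = list(aa, aa))
  full <- matrix(-1, 21, 21, dimnames = list(c(aa, "X"), c(aa, "X")))
  full[aa, aa] <- m
  full
}

#' Global pairwise alignment (Gotoh, affine gaps)
#'
#' @param a,b residue strings.
#' @param gap_open gap opening penalty (first gap position; default 10).
#' @param gap_extend per-additional-position extension penalty
#'   (default 0.5).
#' @param submat substitution matrix (default BLOSUM62; pairs with `X`
#'   score -1).
#' @return list with aligned strings `a`, `b` (with `-` gaps) and
#'   `score`.
#' @export
align_global <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         submat = blosum62()) {
  a <- residue_string(a); b <- residue_string(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e18
  op <- gap_open; ex <- gap_extend

  M <- matrix(NEG, n + 1L, m + 1L)    # ends with a match/mismatch
  Ix <- matrix(NEG, n + 1L, m + 1L)   # ends with gap in b (vertical)
  Iy <- matrix(NEG, n + 1L, m + 1L)   # ends with gap in a (horizontal)
  M[1, 1] <- 0
  if (n >= 1) Ix[2:(n + 1L), 1] <- -op - (seq_len(n) - 1L) * ex
  if (m >= 1) Iy[1, 2:(m + 1L)] <- -op - (seq_len(m) - 1L) * ex

  js <- seq_len(m)
  for (i in seq_len(n)) {
    srow <- submat[ca[i], cb]
    # match state: from any state at (i-1, j-1)
    prevdiag <- pmax(M[i, js], Ix[i, js], Iy[i, js])
    M[i + 1L, js + 1L] <- srow + prevdiag
    # vertical gap: from row i
    Ix[i + 1L, ] <- pmax(M[i, ] - op, Ix[i, ] - ex, Iy[i, ] - op)
    # horizontal gap along row i+1: unrolled running maximum
    B <- pmax(M[i + 1L, ], Ix[i + 1L, ])
    k <- 0:m
    Iy[i + 1L, js + 1L] <- -op - (js - 1L) * ex +
      cummax(B + k * ex)[js]
  }
  list(M = M, Ix = Ix, Iy = Iy,
       score = max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L]),
       ca = ca, cb = cb, op = op, ex = ex, submat = submat) -> dp

  tb <- traceback_global(dp)
  list(a = tb$a, b = tb$b, score = dp$score)
}

# Deterministic traceback preferring diagonal, then up (gap in b), then
# left (gap in a).
traceback_global <- function(dp) {
  eps <- 1e-9
  n <- length(dp$ca); m <- length(dp$cb)
  M <- dp$M; Ix <- dp$Ix; Iy <- dp$Iy
  op <- dp$op; ex <- dp$ex
  i <- n; j <- m
  fin <- c(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
  state <- c("M", "Ix", "Iy")[which(fin >= max(fin) - eps)[1]]
  ra <- character(0); rb <- character(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      ra <- c(dp$ca[i], ra); rb <- c(dp$cb[j], rb)
      target <- M[i + 1L, j + 1L] - dp$submat[dp$ca[i], dp$cb[j]]
      cand <- c(M[i, j], Ix[i, j], Iy[i, j])
      state <- c("M", "Ix", "Iy")[which(abs(cand - target) < eps)[1]]
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      ra <- c(dp$ca[i], ra); rb <- c("-", rb)
      target <- Ix[i + 1L, j + 1L]
      cand <- c(M[i, j + 1L] - op, Ix[i, j + 1L] - ex, Iy[i, j + 1L] - op)
      state <- c("M", "Ix", "Iy")[which(abs(cand - target) < eps)[1]]
      i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(dp$cb[j], rb)
      target <- Iy[i + 1L, j + 1L]
      cand <- c(M[i + 1L, j] - op, Ix[i + 1L, j] - op, Iy[i + 1L, j] - ex)
      state <- c("M", "Ix", "Iy")[which(abs(cand - target) < eps)[1]]
      j <- j - 1L
    }
    if (i == 0L && j > 0L) state <- "Iy"
    if (j == 0L && i > 0L) state <- "Ix"
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""))
}

#' Pairwise sequence identity from global alignment
#'
#' @inheritParams align_global
#' @param denominator `"columns"` (all aligned columns; default) or
#'   `"shortest"` (length of the shorter sequence).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, denominator = c("columns", "shortest"),
                              gap_open = 10, gap_extend = 0.5,
                              submat = blosum62()) {
  denominator <- match.arg(denominator)
  aln <- align_global(a, b, gap_open, gap_extend, submat)
  ca <- strsplit(aln$a, "")[[1]]; cb <- strsplit(aln$b, "")[[1]]
  matches <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
                columns = length(ca),
                shortest = min(nchar(residue_string(a)), nchar(residue_string(b))))
  matches / den
}

#' Pairwise distance matrix (1 - identity)
#'
#' @param seqs record data.frame with at least 3 rows and distinct ids.
#' @param ... passed to [pairwise_identity()].
#' @return symmetric numeric matrix with zero diagonal, labelled by `id`.
#' @export
distance_matrix <- function(seqs, ...) {
  if (nrow(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (anyDuplicated(seqs$id)) stop("duplicate labels", call. = FALSE)
  n <- nrow(seqs)
  d <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- 1 - pairwise_identity(seqs$seq[i], seqs$seq[j], ...)
    d[i, j] <- v; d[j, i] <- v
  }
  d
}

#' Candidate filter on maximum pairwise identity
#'
#' Keeps sequences whose best global-alignment identity against any
#' reference exceeds `threshold` (default 0.15, the classical candidate
#' cut-off).  Note that global-alignment identities differ numerically
#' from local/BLAST-style identities.
#'
#' @param seqs query record data.frame.
#' @param refs reference record data.frame.
#' @param threshold identity fraction (default 0.15).
#' @param ... passed to [pairwise_identity()].
#' @return `seqs` rows whose maximum identity to `refs` is > threshold,
#'   with a `max_identity` column appended.
#' @export
identity_filter <- function(seqs, refs, threshold = 0.15, ...) {
  mx <- vapply(seq_len(nrow(seqs)), function(i)
    max(vapply(seq_len(nrow(refs)), function(j)
      pairwise_identity(seqs$seq[i], refs$seq[j], ...), 0)), 0)
  out <- seqs[mx > threshold, , drop = FALSE]
  out$max_identity <- mx[mx > threshold]
  out
}

# ---- trees -----------------------------------------------------------

# Internal recursive node: leaf = list(label);
# internal = list(children = list(...), blen = numeric lengths to children).
new_leaf <- function(label) list(label = label)
is_leaf <- function(node) !is.null(node$label)

# smallest leaf label in a subtree (used for deterministic ordering)
min_label <- function(node) {
  if (is_leaf(node)) return(node$label)
  min(vapply(node$children, min_label, ""))
}

# order children by their smallest leaf label (stable output)
ordered_internal <- function(children, blens) {
  keys <- vapply(children, min_label, "")
  o <- order(keys)
  list(children = children[o], blen = blens[o])
}

new_tree <- function(root, rooted) {
  structure(list(root = root, rooted = rooted), class = "ltp_tree")
}

#' @export
print.ltp_tree <- function(x, ...) {
  cat(sprintf("%s tree with %d leaves: %s\n",
              if (x$rooted) "Rooted" else "Unrooted",
              length(tree_leaves(x)), write_newick(x)))
  invisible(x)
}

#' Leaf labels of a tree
#' @param tree an `ltp_tree`.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  rec <- function(node) {
    if (is_leaf(node)) return(node$label)
    unlist(lapply(node$children, rec))
  }
  rec(tree$root)
}

check_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs))
    stop("distance matrix must have distinct labels", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("matrix not symmetric", call. = FALSE)
  if (any(diag(d) != 0)) stop("diagonal must be zero", call. = FALSE)
  d
}

# lexicographically smallest (min,max) label pair among tied candidates
pick_pair <- function(cand, keys) {
  pairkey <- t(apply(cand, 1L, function(ij) {
    k <- sort(c(keys[ij[1]], keys[ij[2]]))
    k
  }))
  o <- order(pairkey[, 1], pairkey[, 2])
  cand[o[1], ]
}

#' UPGMA clustering
#'
#' Average-linkage agglomeration weighted by cluster sizes; node heights
#' are half the merge distance, so the result is ultrametric.  Ties are
#' broken on the lexicographically smallest pair of cluster labels (a
#' cluster is labelled by its smallest leaf).
#'
#' @param d symmetric distance matrix with labelled rows/columns.
#' @return a rooted `ltp_tree`.
#' @export
upgma <- function(d) {
  d <- check_dist(d)
  labs <- rownames(d)
  nodes <- lapply(labs, new_leaf)
  sizes <- rep(1L, length(labs))
  heights <- rep(0, length(labs))
  D <- d
  active <- seq_along(labs)
  while (length(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    mn <- min(sub[upper.tri(sub)])
    idx <- which(upper.tri(sub) & abs(sub - mn) < 1e-12, arr.ind = TRUE)
    cand <- cbind(active[idx[, 1]], active[idx[, 2]])
    keys <- vapply(nodes, min_label, "")
    ij <- pick_pair(cand, keys)
    i <- ij[1]; j <- ij[2]
    h <- D[i, j] / 2
    oi <- ordered_internal(list(nodes[[i]], nodes[[j]]),
                           c(h - heights[i], h - heights[j]))
    node <- list(children = oi$children, blen = oi$blen)
    # weighted average linkage
    k <- length(nodes) + 1L
    newrow <- (sizes[i] * D[i, ] + sizes[j] * D[j, ]) / (sizes[i] + sizes[j])
    D <- rbind(cbind(D, newrow), c(newrow, 0))
    nodes[[k]] <- node
    sizes[k] <- sizes[i] + sizes[j]
    heights[k] <- h
    active <- c(setdiff(active, c(i, j)), k)
  }
  new_tree(nodes[[active]], rooted = TRUE)
}

#' Neighbor-joining tree
#'
#' Standard Q-criterion agglomeration producing an unrooted tree (the
#' final three clusters join at a trifurcating root node).  Ties are
#' broken on the lexicographically smallest cluster-label pair; negative
#' branch lengths are clamped to zero with a message.
#'
#' @param d symmetric distance matrix with at least 3 labels.
#' @return an unrooted `ltp_tree`.
#' @export
neighbor_joining <- function(d) {
  d <- check_dist(d)
  if (nrow(d) < 3L) stop("need at least 3 labels", call. = FALSE)
  labs <- rownames(d)
  nodes <- lapply(labs, new_leaf)
  D <- d
  active <- seq_along(labs)
  clamp <- function(x) {
    if (x < 0) { message("neighbor_joining: negative branch length clamped to 0"); 0 }
    else x
  }
  while (length(active) > 3L) {
    na <- length(active)
    sub <- D[active, active, drop = FALSE]
    r <- rowSums(sub)
    Q <- (na - 2) * sub - outer(r, r, `+`)
    diag(Q) <- Inf
    mn <- min(Q)
    idx <- which(upper.tri(Q) & abs(Q - mn) < 1e-9, arr.ind = TRUE)
    cand <- cbind(active[idx[, 1]], active[idx[, 2]])
    keys <- vapply(nodes, min_label, "")
    ij <- pick_pair(cand, keys)
    i <- ij[1]; j <- ij[2]
    ri <- sum(D[i, active]); rj <- sum(D[j, active])
    li <- clamp(D[i, j] / 2 + (ri - rj) / (2 * (na - 2)))
    lj <- clamp(D[i, j] / 2 + (rj - ri) / (2 * (na - 2)))
    oi <- ordered_internal(list(nodes[[i]], nodes[[j]]), c(li, lj))
    k <- length(nodes) + 1L
    newrow <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- rbind(cbind(D, newrow), c(newrow, 0))
    D[k, i] <- D[i, k] <- 0; D[k, j] <- D[j, k] <- 0
    nodes[[k]] <- list(children = oi$children, blen = oi$blen)
    active <- c(setdiff(active, c(i, j)), k)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- clamp((D[a, b] + D[a, c3] - D[b, c3]) / 2)
  lb <- clamp((D[a, b] + D[b, c3] - D[a, c3]) / 2)
  lc <- clamp((D[a, c3] + D[b, c3] - D[a, b]) / 2)
  oi <- ordered_internal(nodes[c(a, b, c3)], c(la, lb, lc))
  new_tree(list(children = oi$children, blen = oi$blen), rooted = FALSE)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are printed with 6 decimal places; labels containing
#' characters outside `[A-Za-z0-9_.|-]` are single-quoted (embedded
#' quotes doubled).  The root carries branch length 0.
#'
#' @param tree an `ltp_tree`.
#' @return Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  quote_label <- function(lab) {
    if (grepl("^[A-Za-z0-9_.|-]+$", lab)) lab
    else paste0("'", gsub("'", "''", lab), "'")
  }
  rec <- function(node) {
    if (is_leaf(node)) return(quote_label(node$label))
    inner <- vapply(seq_along(node$children), function(k)
      sprintf("%s:%.6f", rec(node$children[[k]]), node$blen[k]), "")
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(rec(tree$root), ":0.000000;")
}

#' Convert to an ape "phylo" object
#'
#' @param tree an `ltp_tree`.
#' @return an [ape][ape::read.tree] `phylo` object.
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Leaf-to-leaf path lengths of a tree
#'
#' @param tree an `ltp_tree`.
#' @return symmetric matrix of summed branch lengths between leaves.
#' @export
tree_path_lengths <- function(tree) {
  # depth of every leaf below each node, then combine across child pairs
  leaves <- tree_leaves(tree)
  n <- length(leaves)
  out <- matrix(0, n, n, dimnames = list(leaves, leaves))
  rec <- function(node) {
    if (is_leaf(node)) return(setNames(0, node$label))
    depth_sets <- lapply(seq_along(node$children), function(k)
      rec(node$children[[k]]) + node$blen[k])
    for (x in seq_along(depth_sets)) for (y in seq_along(depth_sets)) {
      if (x >= y) next
      for (lx in names(depth_sets[[x]])) for (ly in names(depth_sets[[y]])) {
        v <- depth_sets[[x]][lx] + depth_sets[[y]][ly]
        out[lx, ly] <<- v; out[ly, lx] <<- v
      }
    }
    unlist(depth_sets)
  }
  rec(tree$root)
  out
}

#' Root-to-leaf path lengths (for ultrametricity checks)
#'
#' @param tree a rooted `ltp_tree`.
#' @return named numeric vector of root-to-leaf path lengths.
#' @export
tree_leaf_depths <- function(tree) {
  rec <- function(node, acc) {
    if (is_leaf(node)) return(setNames(acc, node$label))
    unlist(lapply(seq_along(node$children), function(k)
      rec(node$children[[k]], acc + node$blen[k])))
  }
  rec(tree$root, 0)
}

#' Read / write a labelled distance matrix as TSV
#'
#' Square tab-separated matrix with a header row and a label column.
#'
#' @param d matrix (for writing) or path (for reading).
#' @param path output path.
#' @return the matrix (reading) or invisibly the path (writing).
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  labs <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(labs, labs)
  check_dist(m)
}
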