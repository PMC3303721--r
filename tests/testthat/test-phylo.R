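# Global-alignment identities, distance matrices, UPGMA / NJ trees,
# Newick serialization.

test_that("pairwise identity handles the worked examples and is symmetric", {
  expect_equal(pairwise_identity("ACDE", "ACDE"), 1.0)
  expect_equal(pairwise_identity("ACDE", "ACDF"), 0.75)
  expect_error(pairwise_identity("", "ACDE"), "empty")
  set.seed(91)
  for (i in 1:30) {
    a <- paste(sample(AA20_T, sample(5:40, 1), replace = TRUE), collapse = "")
    b <- paste(sample(AA20_T, sample(5:40, 1), replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-12)
  }
})

test_that("global alignment recovers a planted gap", {
  a <- "MKVLCDEFGHIKLW"
  b <- "MKVLCDEIKLW"      # FGH deleted
  aln <- align_global(a, b)
  expect_equal(nchar(aln$a), nchar(aln$b))
  expect_equal(gsub("-", "", aln$a), a)
  expect_equal(gsub("-", "", aln$b), b)
  expect_equal(aln$b, "MKVLCDE---IKLW")
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  seqs <- rbind(sample_type_sequences("I", 3, seed = 92),
                sample_type_sequences("II", 3, seed = 93))
  d <- distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 6))
  expect_true(all(d >= 0 & d <= 1))
  # identical sequences give a zero matrix
  same <- aa_records(c("a", "b", "c"), rep("MKVLCY", 3))
  expect_true(all(distance_matrix(same) == 0))
  expect_error(distance_matrix(aa_records(c("a", "a2"), c("AC", "AD"))),
               "at least 3")
  # shared conserved architecture: within-type closer than between-type
  within <- c(d[1, 2], d[1, 3], d[2, 3], d[4, 5], d[4, 6], d[5, 6])
  between <- d[1:3, 4:6]
  expect_lt(mean(within), mean(between))
})

test_that("UPGMA recovers ultrametric trees exactly", {
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(write_newick(upgma(d2)), "(a:1.000000,b:1.000000):0.000000;")

  # forward-simulated heights: (a,b) at 1, (c,d) at 1.5, root at 3
  dm <- matrix(6, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm) <- 0
  dm["a", "b"] <- dm["b", "a"] <- 2
  dm["c", "d"] <- dm["d", "c"] <- 3
  t4 <- upgma(dm)
  expect_equal(write_newick(t4),
    "((a:1.000000,b:1.000000):2.000000,(c:1.500000,d:1.500000):1.500000):0.000000;")
  depths <- tree_leaf_depths(t4)
  expect_equal(unname(depths), rep(3, 4))
  expect_setequal(tree_leaves(t4), letters[1:4])
})

test_that("UPGMA trees are always ultrametric", {
  set.seed(94)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    seqs <- matrix(stats::runif(n * n), n)
    d <- (seqs + t(seqs)) / 2
    diag(d) <- 0
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    dep <- tree_leaf_depths(upgma(d))
    expect_lt(max(dep) - min(dep), 1e-9)
  }
})

test_that("NJ reconstructs additive matrices exactly", {
  d4 <- additive_matrix_4(1, 2, 3, 4, 1)
  t4 <- neighbor_joining(d4)
  pl <- tree_path_lengths(t4)
  expect_lt(max(abs(pl[rownames(d4), colnames(d4)] - d4)), 1e-9)

  d5 <- additive_matrix_5(0.5, 1.2, 2.0, 0.7, 1.9, 0.6, 1.1)
  t5 <- neighbor_joining(d5)
  pl5 <- tree_path_lengths(t5)
  expect_lt(max(abs(pl5[rownames(d5), colnames(d5)] - d5)), 1e-9)

  # three taxa: closed-form star solution
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  pl3 <- tree_path_lengths(t3)
  expect_equal(pl3["a", "b"], 3)
  expect_equal(pl3["a", "c"], 4)
  expect_equal(pl3["b", "c"], 5)
  # la = (3+4-5)/2 = 1 etc.
  expect_equal(sort(unname(t3$root$blen)), c(1, 2, 3))
})

test_that("negative NJ branch lengths are clamped with a message", {
  # triangle-inequality violation forces a negative three-point solution
  d <- matrix(c(0, 10, 1,
                10, 0, 2,
                1, 2, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_message(tn <- neighbor_joining(d), "clamped")
  rec_min <- function(node) {
    if (!is.null(node$label)) return(Inf)
    min(c(node$blen, vapply(node$children, rec_min, 0)))
  }
  expect_gte(rec_min(tn$root), 0)
})

test_that("tree builders are input-order invariant", {
  set.seed(95)
  n <- 6
  m <- matrix(stats::runif(n * n, 0.1, 1), n)
  d <- (m + t(m)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
  perm <- sample(n)
  dp <- d[perm, perm]
  expect_equal(write_newick(upgma(d)), write_newick(upgma(dp)))
  expect_equal(write_newick(suppressMessages(neighbor_joining(d))),
               write_newick(suppressMessages(neighbor_joining(dp))))
})

test_that("Newick output round-trips through an independent reader", {
  seqs <- rbind(sample_type_sequences("I", 3, seed = 96),
                sample_type_sequences("II", 2, seed = 97))
  d <- distance_matrix(seqs)
  tu <- upgma(d)
  nw <- write_newick(tu)
  expect_match(nw, ";$")
  ph <- ape::read.tree(text = nw)
  expect_setequal(ph$tip.label, seqs$id)
  # path lengths agree with the independent parser's cophenetic distances
  coph <- stats::cophenetic(ph)
  pl <- tree_path_lengths(tu)
  expect_equal(pl[rownames(coph), colnames(coph)], coph, tolerance = 1e-6)
})

test_that("labels with special characters are quoted", {
  d <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("x y", "b"), c("x y", "b")))
  nw <- write_newick(upgma(d))
  expect_match(nw, "'x y'", fixed = TRUE)
})

test_that("distance TSV round-trips", {
  seqs <- sample_type_sequences("III", 3, seed = 98)
  d <- distance_matrix(seqs)
  f <- tempfile(fileext = ".tsv")
  write_distance_tsv(d, f)
  d2 <- read_distance_tsv(f)
  expect_equal(d2, d, tolerance = 1e-12)
})
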