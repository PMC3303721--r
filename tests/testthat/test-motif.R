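# Eight-cysteine motif detection and deficient variants.

spacer <- function(k) strrep("A", k)
build_8cys <- function(n_offset, g, c_tail, cxc_x = "N") {
  paste0(spacer(n_offset), "C", spacer(g[1]), "C", spacer(g[2]), "CC",
         spacer(g[3]), "C", cxc_x, "C", spacer(g[4]), "C", spacer(g[5]), "C",
         spacer(c_tail))
}

test_that("a constructed scaffold yields exactly one motif with the recipe's arithmetic", {
  s <- build_8cys(2, c(9, 14, 19, 21, 14), 26, cxc_x = "N")
  m <- find_cys_motifs(s)
  expect_equal(nrow(m), 1L)
  expect_equal(unlist(m[1, c("g1", "g2", "g3", "g4", "g5")], use.names = FALSE),
               c(9L, 14L, 19L, 21L, 14L))
  expect_equal(m$n_offset, 2L)
  expect_equal(m$c_tail, 26L)
  expect_equal(m$cxc_x, "N")
  # index arithmetic from the construction recipe
  expect_equal(m$c1, 3L)
  expect_equal(m$c4, m$c3 + 1L)
  expect_equal(m$c6, m$c5 + 2L)
  expect_true(all(strsplit(s, "")[[1]][unlist(m[1, paste0("c", 1:8)])] == "C"))
})

test_that("seven cysteines cannot form the full motif", {
  s <- sub("C", "A", build_8cys(2, c(9, 14, 19, 21, 14), 26))
  expect_equal(nrow(find_cys_motifs(s)), 0L)
})

test_that("an extra tail cysteine adds candidates but keeps the original first", {
  s0 <- build_8cys(2, c(9, 14, 19, 21, 14), 26)
  s <- paste0(s0, "C")
  m0 <- find_cys_motifs(s0)
  m <- find_cys_motifs(s)
  expect_gte(nrow(m), 1L)
  expect_equal(unlist(m[1, paste0("c", 1:8)]), unlist(m0[1, paste0("c", 1:8)]))
})

test_that("enumeration equals brute-force 8-combination scanning", {
  set.seed(21)
  for (rep in 1:25) {
    # random sequences enriched in C so several candidates can arise
    n <- sample(40:90, 1)
    chars <- sample(c("A", "G", "S", "C"), n, replace = TRUE,
                    prob = c(0.3, 0.3, 0.2, 0.2))
    s <- paste(chars, collapse = "")
    if (sum(chars == "C") > 12) next
    brute <- brute_cys_motifs(s)
    got <- find_cys_motifs(s, max_candidates = 1e6)
    expect_equal(nrow(got), length(brute))
    if (length(brute)) {
      brute_mat <- do.call(rbind, brute)
      got_mat <- as.matrix(got[, paste0("c", 1:8)])
      o1 <- do.call(order, as.data.frame(brute_mat))
      o2 <- do.call(order, as.data.frame(got_mat))
      expect_equal(unname(got_mat[o2, , drop = FALSE]),
                   unname(brute_mat[o1, , drop = FALSE]))
    }
  }
})

test_that("generated type sequences are recovered with their generating gaps", {
  types <- c("I", "II", "III", "IV", "V")
  for (ty in types) {
    seqs <- sample_type_sequences(ty, 20, seed = 100 + match(ty, types))
    gaps <- attr(seqs, "gaps")
    for (i in seq_len(nrow(seqs))) {
      m <- find_cys_motifs(seqs$seq[i])
      expect_gte(nrow(m), 1L)
      hit <- apply(as.matrix(m[, paste0("g", 1:5)]), 1, function(g)
        all(g == gaps[i, paste0("g", 1:5)]))
      expect_true(any(hit))
    }
  }
})

test_that("replacing any single motif cysteine removes the original 8-tuple", {
  seqs <- sample_type_sequences("I", 3, seed = 31)
  for (i in 1:3) {
    m <- find_cys_motifs(seqs$seq[i])[1, ]
    orig <- unlist(m[paste0("c", 1:8)])
    for (k in 1:8) {
      chars <- strsplit(seqs$seq[i], "")[[1]]
      chars[orig[k]] <- "A"
      m2 <- find_cys_motifs(paste(chars, collapse = ""))
      if (nrow(m2)) {
        still <- apply(as.matrix(m2[, paste0("c", 1:8)]), 1, function(p)
          all(p == orig))
        expect_false(any(still))
      } else succeed()
    }
  }
})

test_that("candidate explosion raises an informative error", {
  s <- paste(rep("CCA", 30), collapse = "")   # 60 cysteines, dense CC/CXC
  expect_error(find_cys_motifs(s, max_candidates = 50),
               "combinatorial explosion.*60 cysteines")
})

test_that("deficient category A is recognised and full motifs take precedence", {
  # skeleton C, CC, CXC, C, C with gaps from the category-A sets
  s <- paste0(spacer(3), "C", spacer(8), "CC", spacer(9), "CLC", spacer(22),
              "C", spacer(7), "C", spacer(4))
  expect_equal(nrow(find_cys_motifs(s)), 0L)
  d <- find_deficient_motifs(s)
  expect_true("A" %in% d$category)
  d_strict <- find_deficient_motifs(s, mode = "strict")
  expect_true("A" %in% d_strict$category)

  expect_equal(nrow(find_deficient_motifs("AAAA")), 0L)

  # a full-motif sequence reports no deficient category
  full <- build_8cys(2, c(9, 14, 19, 21, 14), 26)
  expect_equal(nrow(find_deficient_motifs(full)), 0L)
})

test_that("categories C and D share a skeleton and can both be reported", {
  sC <- paste0(spacer(4), "C", spacer(13), "CC", spacer(19), "CFC",
               spacer(22), "C", spacer(1))
  dC <- find_deficient_motifs(sC, mode = "strict")
  expect_true("C" %in% dC$category)

  sD <- paste0(spacer(4), "C", spacer(5), "CC", spacer(19), "CFC",
               spacer(22), "C", spacer(4))
  dD <- find_deficient_motifs(sD)
  expect_true("D" %in% dD$category)
  expect_false("C" %in% dD$category)

  # the C and D g1 sets are disjoint ({13} vs 1-11), so no single
  # placement satisfies both rows; a sequence carrying two placements of
  # the shared C,CC,CXC,C skeleton reports both categories
  sBoth <- paste0(spacer(4), "C", spacer(7), "C", spacer(5), "CC",
                  spacer(19), "CFC", spacer(22), "C", spacer(4))
  dBoth <- find_deficient_motifs(sBoth)
  expect_true(all(c("C", "D") %in% dBoth$category))
})

test_that("motif_report emits one 1-based row per candidate", {
  seqs <- sample_type_sequences("II", 4, seed = 41)
  rep <- motif_report(seqs)
  expect_true(all(seqs$id %in% rep$sequence_id))
  expect_true(all(rep$cys1 >= 1))
  expect_named(rep, c("sequence_id", paste0("cys", 1:8), paste0("g", 1:5),
                      "n_offset", "c_tail", "cxc_x"))
})
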