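# Synthetic sequence generation: pattern realizations, type spacing,
# decoys, alignments.

test_that("pattern sampling is reproducible and honours the pattern", {
  b <- builtin_patterns()
  s1 <- sample_from_pattern(b$typeII, 10, seed = 101)
  s2 <- sample_from_pattern(b$typeII, 10, seed = 101)
  expect_identical(s1$seq, s2$seq)

  lit <- parse_pattern("M-K-V")
  sl <- sample_from_pattern(lit, 5, seed = 102)
  expect_true(all(sl$seq == "MKV"))

  # realization spans reconstruct the sequence
  r <- attr(s1, "realization")[[1]]
  expect_equal(max(r$end, na.rm = TRUE), nchar(s1$seq[1]))
})

test_that("flanked pattern samples still match and record shifted spans", {
  b <- builtin_patterns()
  sf <- sample_from_pattern(b$PS00597, 10, seed = 103, flank_max = 6)
  expect_true(all(vapply(sf$seq, pattern_matches, TRUE, pattern = b$PS00597)))
  r <- attr(sf, "realization")[[1]]
  first <- r$start[which(!is.na(r$start))[1]]
  ch <- substring(sf$seq[1], first, first)
  expect_true(ch %in% c("L", "I", "V", "M"))
})

test_that("type sampling stays inside the rule sets with the right polarity", {
  rules <- spacing_rules()
  for (ty in names(rules)) {
    seqs <- sample_type_sequences(ty, 50, seed = 110 + match(ty, names(rules)))
    gaps <- attr(seqs, "gaps")
    for (slot in colnames(gaps))
      expect_true(all(gaps[, slot] %in% rules[[ty]][[slot]]))
    # exactly eight cysteines (spacers exclude C)
    ncys <- vapply(seqs$seq, function(s)
      sum(strsplit(s, "")[[1]] == "C"), 0L)
    expect_true(all(ncys == 8L))
    m1 <- find_cys_motifs(seqs$seq[1])
    expect_equal(cxc_polarity(m1$cxc_x[1]),
                 if (ty == "I") "hydrophilic" else "hydrophobic")
    a <- classify_spacing(find_cys_motifs(seqs$seq[1])[1, ])
    expect_true(ty %in% a$compatible)
  }
})

test_that("drop_cys decoys lose the original 8-tuple", {
  seqs <- sample_type_sequences("I", 10, seed = 121)
  dec <- make_decoys(seqs, "drop_cys", seed = 122)
  for (i in 1:10) {
    orig <- unlist(find_cys_motifs(seqs$seq[i])[1, paste0("c", 1:8)])
    m2 <- find_cys_motifs(dec$seq[i])
    if (nrow(m2)) {
      expect_false(any(apply(as.matrix(m2[, paste0("c", 1:8)]), 1,
                             function(p) all(p == orig))))
    } else succeed()
  }
  expect_true(all(grepl("drop_cys", dec$desc)))
})

test_that("shift_gap decoys leave the source type's compatible set", {
  seqs <- sample_type_sequences("II", 10, seed = 123)
  dec <- make_decoys(seqs, "shift_gap", seed = 124, type = "II")
  for (i in 1:10) {
    m <- find_cys_motifs(dec$seq[i])
    if (!nrow(m)) { succeed(); next }
    compat <- unique(unlist(lapply(seq_len(nrow(m)), function(k)
      classify_spacing(m[k, ])$compatible)))
    expect_false("II" %in% compat)
  }
})

test_that("shuffle_conserved decoys stop matching while keeping spacing", {
  b <- builtin_patterns()
  seqs <- sample_from_pattern(b$typeII, 10, seed = 125)
  dec <- make_decoys(seqs, "shuffle_conserved", seed = 126)
  expect_true(all(!vapply(dec$seq, pattern_matches, TRUE, pattern = b$typeII)))
  # cysteine architecture untouched
  for (i in 1:10)
    expect_equal(which(strsplit(dec$seq[i], "")[[1]] == "C"),
                 which(strsplit(seqs$seq[i], "")[[1]] == "C"))
})

test_that("decoy generation validates its inputs", {
  expect_error(make_decoys(aa_records("x", "AAAA"), "drop_cys"), "no motif")
  expect_error(make_decoys(aa_records("x", "AAAA"), "shift_gap"), "type")
  expect_error(make_decoys(aa_records("x", "AAAA"), "shuffle_conserved"),
               "pattern")
})

test_that("synthetic alignments have constant width and controlled conservation", {
  b <- builtin_patterns()
  aln <- synthetic_alignment(b$typeI, 25, seed = 131, conservation = 1)
  expect_true(all(nchar(aln$seq) == aln$ncol))
  # degapped members match the generating pattern at full conservation
  expect_true(all(vapply(gsub("-", "", aln$seq), pattern_matches, TRUE,
                         pattern = b$typeI)))

  # conservation 0 on a single literal column: the literal is lost
  one <- parse_pattern("W")
  aln0 <- synthetic_alignment(one, 100, seed = 132, conservation = 0)
  p0 <- induce_pattern(aln0, literal_threshold = 0.9)
  e1 <- p0$elements[[1]]
  expect_false(e1$kind == "literal" && identical(e1$residues, "W"))
})

test_that("simulation manifests record decoy violations", {
  seqs <- sample_type_sequences("I", 3, seed = 133)
  dec <- make_decoys(seqs, "drop_cys", seed = 134)
  man <- simulation_manifest(dec, "sample_type_sequences+drop_cys", 134, "I")
  expect_equal(nrow(man), 3L)
  expect_true(all(grepl("drop_cys", man$violation)))
  man2 <- simulation_manifest(seqs, "sample_type_sequences", 133, "I")
  expect_true(all(man2$violation == "."))
})
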