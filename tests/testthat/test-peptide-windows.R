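test_that("an interior single-site mutation yields k windows per length", {
  # interior means at least k-1 residues on both sides of the site, for
  # every k in the range; a site at 40 in an 80-mer satisfies that for
  # k up to 30 (it does NOT hold for shorter proteins, where the window
  # count is boundary-clipped)
  mp <- applyMissense(strrep("A", 80), 40, "A", "W", "v1", "G1")
  wI <- extractWindows(mp, mhc_class = "I")
  expect_equal(nrow(wI), 8 + 9 + 10 + 11)   # 38
  expect_equal(as.vector(table(wI$k)), c(8L, 9L, 10L, 11L))
  # every window covers position 40
  expect_true(all(wI$start <= 40 & wI$start + wI$k - 1 >= 40))

  wII <- extractWindows(mp, mhc_class = "II")
  expect_equal(nrow(wII), sum(15:30))       # 360

  # k = 9: starts pos-(k-1) .. pos
  w9 <- wI[wI$k == 9, ]
  expect_equal(w9$start, 32:40)
})

test_that("a mutation at position 1 yields one window per length", {
  mp <- applyMissense(strrep("A", 30), 1, "A", "W", "v1", "G1")
  w <- extractWindows(mp, mhc_class = "I")
  expect_equal(nrow(w), 4)
  expect_true(all(w$start == 1))
  expect_equal(sort(w$k), 8:11)
})

test_that("short proteins yield an empty window table, not an error", {
  mp <- MutantProtein("v", "G", "missense", "MKTAW", 5, 5)
  w <- extractWindows(mp, mhc_class = "I")
  expect_equal(nrow(w), 0)
})

test_that("windows overlapping non-standard residues are dropped", {
  sq <- paste0(strrep("A", 10), "X", strrep("A", 4), "W", strrep("A", 15))
  mp <- MutantProtein("v", "G", "missense", sq, 16, 16)
  w <- extractWindows(mp, mhc_class = "I")
  expect_true(all(!grepl("X", w$peptide, fixed = TRUE)))
  expect_gt(attr(w, "n_dropped_nonstandard"), 0)
})

test_that("window extraction equals brute-force enumeration on random mutants", {
  set.seed(31)
  for (i in 1:100) {
    L <- sample(10:80, 1)
    sq <- rand_pep(L)
    a <- sample(seq_len(L), 1)
    b <- min(L, a + sample(0:10, 1))
    cl <- sample(c("missense", "inframe_del", "frameshift", "fusion"), 1)
    mp <- MutantProtein("v", "G", cl, sq, a, b)
    k_min <- sample(7:9, 1)
    k_max <- k_min + sample(0:4, 1)
    got <- extractWindows(mp, k_min, k_max, "I")
    want <- oracle_windows(sq, a, b, k_min, k_max)
    expect_equal(got[, c("peptide", "k", "start")], want,
                 label = sprintf("case %d", i))
    # emitted windows are substrings at the recorded start and cover the region
    if (nrow(got) > 0) {
      expect_equal(substring(sq, got$start, got$start + got$k - 1), got$peptide)
      expect_true(all(got$start <= b & got$start + got$k - 1 >= a))
    }
  }
})

test_that("mutant-position annotation points at altered residues", {
  mp <- applyMissense("MKTAYIAKLM", 5, "Y", "F", "v1", "G1")
  w <- extractWindows(mp, 8, 8, "I")
  for (i in seq_len(nrow(w))) {
    rel <- as.integer(strsplit(w$mut_positions[i], ",")[[1]])
    expect_equal(w$start[i] + rel - 1L, 5L)
    expect_equal(substr(w$peptide[i], rel, rel), "F")
  }
})

test_that("per-variant dedup keeps first-start provenance", {
  # periodic sequence: identical windows appear at several starts
  mp <- MutantProtein("v", "G", "frameshift", strrep("ACDE", 8), 5, 32)
  w <- extractWindows(mp, 8, 8, "I")
  expect_false(any(duplicated(w$peptide)))
  expect_equal(nrow(w), 4)   # only 4 distinct 8-mers in a period-4 sequence
  expect_equal(min(w$start), 1L)
})

test_that("wild-type windows are removed only when the flag is on", {
  prots <- c(P1 = "MKTAYIAKLMNPQRST")
  proteome <- new("ReferenceProteome", sequences = prots,
                  geneToProtein = list(G1 = "P1"))
  cand <- data.frame(peptide = c("KTAYIAKL", "KTAFIAKL"), k = 8L,
                     start = 2L, mut_positions = "4",
                     variant_id = "v", gene = "G1", var_class = "missense",
                     mhc_class = "I", stringsAsFactors = FALSE)
  kept <- dropWildtypeWindows(cand, proteome, enabled = TRUE)
  expect_equal(kept$peptide, "KTAFIAKL")
  expect_equal(attr(kept, "n_removed_wildtype"), 1L)
  expect_identical(dropWildtypeWindows(cand, proteome, enabled = FALSE)$peptide,
                   cand$peptide)
  empty <- dropWildtypeWindows(cand[0, ], proteome, enabled = TRUE)
  expect_equal(nrow(empty), 0)
})
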