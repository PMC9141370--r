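test_that("missense substitution edits one residue and flags mismatches", {
  mp <- applyMissense("MKTAYIAK", 5, "Y", "F")
  expect_equal(proteinSeq(mp), "MKTAFIAK")
  expect_equal(mutRegion(mp), c(5L, 5L))

  mp1 <- applyMissense("MKTAYIAK", 1, "M", "V")
  expect_equal(mutRegion(mp1), c(1L, 1L))

  err <- tryCatch(applyMissense("MKTAYIAK", 5, "W", "F"), condition = identity)
  expect_s3_class(err, "neoforge_ref_mismatch")
  expect_equal(err$expected, "W")
  expect_equal(err$observed, "Y")
})

test_that("in-frame indels edit the sequence and set junction regions", {
  del <- VariantRecord("d", "G", varClass = "inframe_del", proteinPos = 4,
                       proteinEnd = 5, refAA = "AY")
  mp <- applyInframeIndel("MKTAYIAK", del)
  expect_equal(proteinSeq(mp), "MKTIAK")
  expect_equal(mutRegion(mp), c(3L, 4L))

  ins <- VariantRecord("i", "G", varClass = "inframe_ins", proteinPos = 2,
                       proteinEnd = 3, refAA = "KT", altAA = "QQ")
  mp2 <- applyInframeIndel("MKTAYIAK", ins)
  expect_equal(proteinSeq(mp2), "MKQQTAYIAK")
  expect_equal(mutRegion(mp2), c(3L, 4L))

  # N-terminal deletion clamps the junction region to [1, 1]
  del1 <- VariantRecord("d1", "G", varClass = "inframe_del", proteinPos = 1,
                        refAA = "M")
  mp3 <- applyInframeIndel("MKTAYIAK", del1)
  expect_equal(proteinSeq(mp3), "KTAYIAK")
  expect_equal(mutRegion(mp3), c(1L, 1L))

  # C-terminal deletion clamps to the last mutant residue
  del8 <- VariantRecord("d8", "G", varClass = "inframe_del", proteinPos = 8,
                        refAA = "K")
  mp4 <- applyInframeIndel("MKTAYIAK", del8)
  expect_equal(mutRegion(mp4), c(7L, 7L))

  bad <- VariantRecord("x", "G", varClass = "inframe_del", proteinPos = 4,
                       proteinEnd = 5, refAA = "AW")
  expect_error(applyInframeIndel("MKTAYIAK", bad),
               class = "neoforge_ref_mismatch")
})

test_that("frameshift translation matches the worked example", {
  mp <- translateFrameshift("ATGGCCAAAGAATGGTAA", "c.6_7insC")
  expect_equal(proteinSeq(mp), "MAQRMV")
  expect_false(stopFound(mp))
  expect_equal(mutRegion(mp), c(3L, 6L))
})

test_that("a frameshift creating an immediate stop truncates the product", {
  # ref: ATG GCC AAA TGA -> MAK; deleting base 7 (A) gives ATG GCC AAT GA
  # -> MAN (runs off), while deleting base 9 of ATG GCC AAA AAT GAT AA
  # shifts TGA into frame right after the altered codon
  mp <- translateFrameshift("ATGGCCAAAAATGATAA", "c.8del")
  or <- oracle_translate(oracle_apply_edit("ATGGCCAAAAATGATAA", "del", 8))
  expect_equal(proteinSeq(mp), or$seq)
  expect_equal(stopFound(mp), or$stop)
})

test_that("in-frame edits are rejected by the frameshift translator", {
  expect_error(translateFrameshift("ATGGCCAAAGAATGGTAA", "c.6_7insCCC"),
               class = "neoforge_invalid_variant")
  expect_error(translateFrameshift("ATGGCCAAA", "c.100_101del"),
               class = "neoforge_invalid_variant")
})

test_that("frameshift translation agrees with a hand-rolled codon oracle", {
  set.seed(101)
  non_stop <- setdiff(names(GENETIC_CODE_ORACLE),
                      c("TAA", "TAG", "TGA"))
  for (rep in 1:200) {
    n_codons <- sample(10:40, 1)
    cds <- paste0("ATG", paste(sample(non_stop, n_codons, replace = TRUE),
                               collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
    L <- nchar(cds)
    if (sample(c(TRUE, FALSE), 1)) {
      pos <- sample(3:(L - 6), 1)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(c(1, 2), 1),
                          replace = TRUE), collapse = "")
      chg <- sprintf("c.%d_%dins%s", pos, pos + 1, ins)
      edited <- oracle_apply_edit(cds, "ins", pos, seq = ins)
    } else {
      pos <- sample(3:(L - 6), 1)
      dlen <- sample(c(1, 2), 1)
      chg <- if (dlen == 1) sprintf("c.%ddel", pos) else
        sprintf("c.%d_%ddel", pos, pos + 1)
      edited <- oracle_apply_edit(cds, "del", pos, pos + dlen - 1)
    }
    or <- oracle_translate(edited)
    if (!nzchar(or$seq)) next
    mp <- translateFrameshift(cds, chg, variantId = paste0("r", rep))
    expect_equal(proteinSeq(mp), or$seq, label = sprintf("case %d seq", rep))
    expect_equal(stopFound(mp), or$stop, label = sprintf("case %d stop", rep))
    # altered region: first residue differing from the reference translation
    ref_aa <- oracle_translate(cds)$seq
    ncmp <- min(nchar(or$seq), nchar(ref_aa))
    mm <- which(strsplit(substr(or$seq, 1, ncmp), "")[[1]] !=
                  strsplit(substr(ref_aa, 1, ncmp), "")[[1]])
    expected_a <- if (length(mm) > 0) mm[1] else
      min(nchar(or$seq), ncmp + 1L)
    expect_equal(mutRegion(mp), c(expected_a, nchar(or$seq)),
                 label = sprintf("case %d region", rep))
  }
})

test_that("fusion products carry junction-anchored regions", {
  f <- FusionRecord("f1", "GA", "GB", strrep("AC", 10), 10, "in_frame")
  mp <- fusionToMutant(f)
  expect_equal(mutRegion(mp), c(10L, 11L))
  expect_equal(variantClass(mp), "fusion")

  f2 <- FusionRecord("f2", "GA", "GB", strrep("AC", 10), 10,
                     "frameshift_3prime")
  expect_equal(mutRegion(fusionToMutant(f2)), c(10L, 20L))

  expect_error(FusionRecord("f3", "GA", "GB", strrep("AC", 10), 20,
                            "in_frame"), "junctionIndex")
})

test_that("apply operations change length exactly as the class implies", {
  set.seed(23)
  for (i in 1:25) {
    L <- sample(30:60, 1)
    ref <- rand_pep(L)
    pos <- sample(5:(L - 5), 1)
    mp <- applyMissense(ref, pos, substr(ref, pos, pos),
                        sample(setdiff(AA20, substr(ref, pos, pos)), 1))
    expect_equal(nchar(proteinSeq(mp)), L)

    ilen <- sample(1:4, 1)
    ins <- VariantRecord("i", "G", varClass = "inframe_ins", proteinPos = pos,
                         proteinEnd = pos + 1L,
                         refAA = substr(ref, pos, pos + 1), altAA = rand_pep(ilen))
    expect_equal(nchar(proteinSeq(applyInframeIndel(ref, ins))), L + ilen)

    dlen <- sample(1:4, 1)
    del <- VariantRecord("d", "G", varClass = "inframe_del", proteinPos = pos,
                         proteinEnd = pos + dlen - 1L,
                         refAA = paste0(substr(ref, pos, pos),
                                        substr(ref, pos + dlen - 1, pos + dlen - 1)))
    expect_equal(nchar(proteinSeq(applyInframeIndel(ref, del))), L - dlen)
  }
})

test_that("custom database assembly counts, prefixes and deduplicates", {
  prots <- c(P1 = "MKTAYIAKQR", P2 = "MDDDEEEFFF", P3 = "MGGGHHHLLL")
  proteome <- new("ReferenceProteome", sequences = prots,
                  geneToProtein = list(G1 = "P1", G2 = "P2", G3 = "P3"))
  cont <- c(TRYP_PIG = "MKWVTFISLL", KERA_HUMAN = "MTSYSYRQSS")
  muts <- list(MutantProtein("v1", "G1", "missense", "MKTAFIAKQR", 5, 5),
               MutantProtein("v2", "G1", "missense", "MKTAFIAKQR", 5, 5),
               MutantProtein("v3", "G2", "missense", "MDDDWEEFFF", 5, 5))
  fa <- tempfile(fileext = ".fasta")
  manifest <- buildCustomDB(proteome, cont, muts, fa)
  expect_equal(manifest$n[manifest$category == "normal"], 3L)
  expect_equal(manifest$n[manifest$category == "contaminant"], 2L)
  expect_equal(manifest$n[manifest$category == "mutant"], 2L)       # v2 merged
  expect_equal(manifest$n[manifest$category == "mutant_merged"], 1L)
  expect_match(manifest$note[manifest$category == "mutant_merged"], "v2->v1")

  ss <- Biostrings::readAAStringSet(fa)
  expect_length(ss, 7)
  expect_equal(sum(startsWith(names(ss), "CON__")), 2)
  expect_equal(sum(startsWith(names(ss), "MUT|")), 2)
  expect_match(names(ss)[startsWith(names(ss), "MUT|v1")], "region=5-5")

  expect_warning(buildCustomDB(proteome, cont, list(), tempfile()), "empty")
})
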