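test_that("annovar-dialect rows map to typed records", {
  f <- write_lines_tmp(c(
    "Gene\tTranscript\tExonicFunc\tAAChange",
    "GENE1\tNM_1\tnonsynonymous SNV\tp.Y5F",
    "GENE2\tNM_2\tsynonymous SNV\tp.L7L",
    "GENE3\tNM_3\tframeshift insertion\tGENE3:NM_3:exon1:c.6_7insC:p.K3fs",
    "GENE4\tNM_4\tnonframeshift deletion\tGENE4:NM_4:exon2:c.10_15del:p.A4_Y5del"))
  suppressMessages(res <- parseVariantTable(f, dialect = "annovar"))
  expect_length(res$records, 3)
  expect_equal(res$skipped, 1L)
  expect_equal(nrow(res$rejects), 0)

  r1 <- res$records[[1]]
  expect_s4_class(r1, "VariantRecord")
  expect_equal(variantClass(r1), "missense")
  expect_equal(r1@proteinPos, 5L)
  expect_equal(r1@refAA, "Y")
  expect_equal(r1@altAA, "F")

  r2 <- res$records[[2]]
  expect_equal(variantClass(r2), "frameshift")
  expect_equal(r2@cdnaChange, "c.6_7insC")
  expect_equal(r2@proteinPos, 2L)   # base 6 lies in codon 2

  r3 <- res$records[[3]]
  expect_equal(variantClass(r3), "inframe_del")
  expect_equal(r3@proteinPos, 4L)
  expect_equal(r3@proteinEnd, 5L)
})

test_that("empty input, unknown classes and bad grammar are handled", {
  f <- write_lines_tmp("Gene\tTranscript\tExonicFunc\tAAChange")
  res <- parseVariantTable(f, dialect = "annovar")
  expect_length(res$records, 0)
  expect_equal(nrow(res$rejects), 0)

  f2 <- write_lines_tmp(c(
    "Gene\tTranscript\tExonicFunc\tAAChange",
    "G1\tNM_1\tstopgain\tp.Q10X",
    "G2\tNM_2\tnonsynonymous SNV\tp.5YF"))
  res2 <- parseVariantTable(f2, dialect = "annovar")
  expect_length(res2$records, 0)
  expect_equal(nrow(res2$rejects), 2)
  expect_match(res2$rejects$reason[1], "unknown ExonicFunc")

  f3 <- write_lines_tmp(c("Gene\tTranscript\tAAChange", "G\tT\tp.Y5F"))
  expect_error(parseVariantTable(f3, dialect = "annovar"), "ExonicFunc")
})

test_that("multi-transcript annotations yield one record per transcript", {
  f <- write_lines_tmp(c(
    "Gene\tTranscript\tExonicFunc\tAAChange",
    "G1\tNM_1\tnonsynonymous SNV\tG1:NM_1:exon1:c.A13T:p.Y5F,G1:NM_9:exon2:c.A73T:p.Y25F"))
  res <- parseVariantTable(f, dialect = "annovar")
  expect_length(res$records, 2)
  expect_equal(vapply(res$records, function(r) r@transcriptId, ""),
               c("NM_1", "NM_9"))
  expect_equal(vapply(res$records, function(r) r@proteinPos, 1L), c(5L, 25L))
})

test_that("simple-dialect records survive a serialize/parse round trip", {
  set.seed(7)
  recs <- list(
    VariantRecord("v1", "G1", "T1", "P1", "missense", proteinPos = 5,
                  refAA = "Y", altAA = "F", genomicLocus = "chr1:100:A:T"),
    VariantRecord("v2", "G2", "T2", "P2", "inframe_ins", proteinPos = 3,
                  proteinEnd = 4, refAA = "KT", altAA = "QQ"),
    VariantRecord("v3", "G3", "T3", "P3", "inframe_del", proteinPos = 4,
                  proteinEnd = 6, refAA = "AW"),
    VariantRecord("v4", "G4", "T4", "P4", "frameshift", proteinPos = 2,
                  cdnaChange = "c.6_7insC"))
  f <- tempfile(fileext = ".tsv")
  writeVariantTable(recs, f)
  res <- parseVariantTable(f, dialect = "simple")
  expect_equal(nrow(res$rejects), 0)
  expect_length(res$records, length(recs))
  for (i in seq_along(recs)) {
    for (sl in slotNames("VariantRecord")) {
      expect_equal(slot(res$records[[i]], sl), slot(recs[[i]], sl),
                   label = sprintf("record %d slot %s", i, sl))
    }
  }
})

test_that("parser never emits a record violating class invariants", {
  set.seed(11)
  classes <- c("missense", "inframe_ins", "inframe_del", "frameshift")
  rows <- vapply(1:60, function(i) {
    cl <- sample(classes, 1)
    pc <- switch(cl,
      missense = sprintf("p.%s%d%s", sample(AA20, 1), sample(1:50, 1),
                         sample(AA20, 1)),
      inframe_ins = sprintf("p.%s%d_%s%dins%s", sample(AA20, 1), 7, sample(AA20, 1),
                            8, rand_pep(sample(1:3, 1))),
      inframe_del = sprintf("p.%s%d_%s%ddel", sample(AA20, 1), 4,
                            sample(AA20, 1), sample(4:9, 1)),
      frameshift = "")
    cdna <- if (cl == "frameshift")
      sprintf("c.%d_%dins%s", i + 3, i + 4,
              paste(sample(c("A", "C", "G", "T"), sample(3, 1),
                           replace = TRUE), collapse = "")) else ""
    sprintf("v%d\tG%d\tT%d\tP%d\t%s\t%s\t%s", i, i, i, i, cl, pc, cdna)
  }, character(1))
  f <- write_lines_tmp(c(
    "variant_id\tgene\ttranscript_id\tprotein_id\tvar_class\tprotein_change\tcdna_change",
    rows))
  res <- parseVariantTable(f, dialect = "simple")
  # some random rows are legitimately rejected (e.g. missense with equal
  # residues, or an in-frame cDNA edit on a frameshift row); every record
  # that does come through must satisfy its class validity
  expect_equal(length(res$records) + nrow(res$rejects), 60)
  for (r in res$records) expect_true(validObject(r))
})

test_that("expression parsing applies the max-TPM duplicate rule", {
  f <- write_lines_tmp(c("target_id\tlength\ttpm", "tx1\t300\t5.0",
                         "tx2\t210\t0.0"))
  tab <- parseExpression(f)
  expect_equal(sort(names(tab)), c("tx1", "tx2"))
  expect_equal(unname(tab["tx2"]), 0)

  f2 <- write_lines_tmp(c("target_id\ttpm", "tx1\t5.0", "tx1\t7.0"))
  expect_message(tab2 <- parseExpression(f2), "duplicate")
  expect_equal(unname(tab2["tx1"]), 7.0)

  f3 <- write_lines_tmp(c("target_id\ttpm", "tx1\t-1"))
  expect_error(parseExpression(f3), "negative TPM")
})

test_that("neoantigen database loads from FASTA and TSV with tier handling", {
  fa <- write_lines_tmp(c(">n1 tier=high", "KTAFIAKLQ",
                          ">n2 tier=medium", "MLLAVLYCL",
                          ">n3 tier=high", "SIINFEKLW"), ".fasta")
  db <- loadNeoDB(fa)
  expect_equal(nrow(db), 3)
  expect_equal(sum(db$tier == "high"), 2)

  # same peptide in both tiers stays as two entries; bad residues rejected
  ts <- write_lines_tmp(c("KTAFIAKLQ\thigh", "KTAFIAKLQ\tmedium",
                          "KTAFIAKLQ\thigh", "AB1CD\thigh"))
  expect_warning(db2 <- loadNeoDB(ts), "rejected")
  expect_equal(nrow(db2), 2)
  expect_setequal(db2$tier, c("high", "medium"))
})

test_that("MS evidence enforces the minimum peptide length", {
  f <- write_lines_tmp(c("Sequence", "KTAFIAKLQ", "SHORT", "AAAAAAA"))
  expect_message(ms <- parseMSEvidence(f), "shorter")
  expect_setequal(ms, c("KTAFIAKLQ", "AAAAAAA"))
})

test_that("fusion records parse and validate the junction index", {
  f <- write_lines_tmp(c(
    "fusion_id\tgene5\tgene3\tjunction_protein_seq\tjunction_index\tframe_status",
    sprintf("f1\tGA\tGB\t%s\t10\tin_frame", strrep("AC", 10)),
    sprintf("f2\tGA\tGB\t%s\t20\tin_frame", strrep("AC", 10))))
  res <- parseFusionTable(f)
  expect_length(res$records, 1)
  expect_equal(nrow(res$rejects), 1)   # junction_index == length is invalid
})
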