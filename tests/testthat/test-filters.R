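make_cand <- function(peptide, variant_id = "v1", gene = "G1",
                      var_class = "missense", mhc_class = "I",
                      start = 1L, mut_positions = "1", ...) {
  data.frame(peptide = peptide, k = nchar(peptide), start = start,
             mut_positions = mut_positions, variant_id = variant_id,
             gene = gene, var_class = var_class, mhc_class = mhc_class,
             ..., stringsAsFactors = FALSE)
}

test_that("expression filter keeps positive-TPM candidates and attaches TPM", {
  cand <- rbind(make_cand("KTAFIAKL", "v1", "G1"),
                make_cand("MLLAVLYC", "v2", "G2"),
                make_cand("SIINFEKL", "v3", "G3"))
  vars <- list(VariantRecord("v1", "G1", "T1", "P1", "missense",
                             proteinPos = 4, refAA = "Y", altAA = "F"),
               VariantRecord("v2", "G2", "T2", "P2", "missense",
                             proteinPos = 4, refAA = "A", altAA = "V"),
               VariantRecord("v3", "G3", "T3", "P3", "missense",
                             proteinPos = 4, refAA = "N", altAA = "K"))
  expr <- c(T1 = 5.2, T2 = 0.0)   # v3 absent: no expression data
  out <- filterExpression(cand, expr, vars)
  expect_equal(out$variant_id, "v1")
  expect_equal(out$tpm, 5.2)
  expect_equal(attr(out, "n_removed_unexpressed"), 1L)
  expect_equal(attr(out, "n_removed_no_data"), 1L)

  # a negative exclusive threshold removes nothing by value
  out2 <- filterExpression(cand[1:2, ], expr, vars,
                           FilterConfig(tpmMinExclusive = -1))
  expect_equal(nrow(out2), 2)

  # fusion candidates use the max over partner genes
  fc <- make_cand("AAAAKAAA", "fus1", "G9::G2", var_class = "fusion")
  expr2 <- c(G9 = 0, G2 = 44)
  expect_equal(filterExpression(fc, expr2)$tpm, 44)
})

test_that("MS filter requires shared residues covering a mutant position", {
  mp <- applyMissense("MKTAYIAKLMNPQRSTVWYA", 5, "Y", "F", "v1", "G1")
  cand <- extractWindows(mp, 8, 8, "I")
  # identified peptide containing a candidate, overlapping the mutant F
  keep <- filterMS(cand, "MKTAFIAKL", list(mp))
  expect_true("KTAFIAKL" %in% keep$peptide)
  expect_true(all(grepl("F", keep$peptide)))
  expect_equal(unique(keep$ms_support), "MKTAFIAKL")

  # evidence overlapping only wild-type residues never supports
  none <- filterMS(cand, "NPQRSTVW", list(mp))
  expect_equal(nrow(none), 0)

  # no supporting peptide at all
  expect_equal(nrow(filterMS(cand, character(0), list(mp))), 0)
})

test_that("MS filter honors the substring and co-located overlap clauses", {
  mp <- applyMissense(strrep("A", 11), 6, "A", "W", "v1", "G1")
  cand <- extractWindows(mp, 11, 11, "I")   # the full 11-mer, W at pos 6
  expect_equal(nrow(cand), 1)
  # short identified peptide inside the candidate, covering the W
  got <- filterMS(cand, "AAWAAA", list(mp), FilterConfig(msMinOverlap = 6))
  expect_equal(nrow(got), 1)
  # same length but only wild-type As: shares no mutant position
  got2 <- filterMS(cand, "AAAAAA", list(mp), FilterConfig(msMinOverlap = 6))
  expect_equal(nrow(got2), 0)

  # co-located overlap: evidence and candidate overlap on the protein
  mp2 <- applyMissense(strrep("C", 30), 15, "C", "W", "v2", "G2")
  cand2 <- extractWindows(mp2, 9, 9, "I")
  c7 <- cand2[cand2$start == 7, ]           # covers 7..15, W at its end
  ev <- substr(proteinSeq(mp2), 9, 22)      # covers 9..22 incl. the W
  got3 <- filterMS(c7, ev, list(mp2))
  expect_equal(nrow(got3), 1)               # overlap 7 >= 7 and covers W
  got4 <- filterMS(c7, ev, list(mp2), FilterConfig(msMinOverlap = 8))
  expect_equal(nrow(got4), 0)               # overlap 7 < 8
})

test_that("database filter applies the similarity window to best hits", {
  db <- data.frame(peptide = c("KTAFIAKLQ", "WWWWWWWWW"),
                   tier = c("high", "medium"), stringsAsFactors = FALSE)
  cand <- rbind(make_cand("KTAFIAKLQ", "v1"),   # identity: similarity 100
                make_cand("DDDDDDDDD", "v2"))   # similarity 0 vs both
  res <- filterNeoDB(cand, db)
  expect_equal(res$candidates$peptide, "KTAFIAKLQ")
  expect_equal(res$candidates$best_similarity, 100)
  expect_equal(res$candidates$best_tier, "high")
  expect_equal(res$matching_ratio, 50)

  # empty candidate set: ratio undefined, not zero
  res0 <- filterNeoDB(cand[0, ], db)
  expect_true(is.na(res0$matching_ratio))
})

test_that("strict filter boundaries are inclusive and class I only", {
  cand <- rbind(
    cbind(make_cand("AAAAKAAA", "v1"), ic50_nM = 34, tpm = 33),
    cbind(make_cand("AAAAKAAC", "v2"), ic50_nM = 34.0001, tpm = 33),
    cbind(make_cand("AAAAKAAD", "v3"), ic50_nM = 34, tpm = 32.9999),
    cbind(make_cand("AAAAKAAE", "v4"), ic50_nM = 10, tpm = 100))
  out <- filterStrict(cand)
  expect_setequal(out$variant_id, c("v1", "v4"))

  c2 <- cbind(make_cand(strrep("AK", 8), "v5", mhc_class = "II"),
              ic50_nM = 1, tpm = 1000)
  expect_warning(out2 <- filterStrict(rbind(cand[1, ], c2)), "class I only")
  expect_equal(out2$variant_id, "v1")

  # unbounded thresholds are the identity on class I candidates
  out3 <- filterStrict(cand, FilterConfig(strictIc50MaxNM = Inf,
                                          strictTpmMin = 0))
  expect_equal(nrow(out3), nrow(cand))

  expect_error(filterStrict(make_cand("AAAAKAAA")), "ic50_nM and tpm")
})

test_that("matching ratio matches exact rational arithmetic", {
  expect_equal(matchingRatio(0, 10), 0)
  expect_true(is.na(matchingRatio(0, 0)))
  expect_error(matchingRatio(5, 4), "matched")
  set.seed(71)
  for (i in 1:300) {
    n <- sample(1:10000, 1)
    m <- sample(0:n, 1)
    r <- matchingRatio(m, n)
    expect_lte(abs(r - 100 * m / n), 0.005 + 1e-9)
    expect_lt(abs(r * 100 - round(r * 100)), 1e-9)   # at most 2 decimals
  }
})

test_that("the cascade is monotone: every stage shrinks its input", {
  d <- file.path(tempdir(), "fx-mono")
  if (!dir.exists(d)) generateFixture(FixtureSpec(seed = 9L), d)
  suppressMessages(res <- runPipeline(d, seed = 9L))
  s <- res$cascade$summary
  expect_true(all(s$n_out <= s$n_in))
  # stage outputs nest: binders >= expressed >= ms_supported >= strict
  key <- function(df) sprintf("%s|%s|%s", df$variant_id, df$peptide, df$allele)
  expect_true(all(key(res$cascade$expressed) %in% key(res$cascade$binders)))
  expect_true(all(key(res$cascade$ms_supported) %in% key(res$cascade$expressed)))
  expect_true(all(key(res$cascade$strict) %in% key(res$cascade$ms_supported)))
  expect_true(all(key(res$cascade$db_matched) %in% key(res$cascade$ms_supported)))
})
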