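fixture_files <- c("proteome.fasta", "cds.fasta", "variants.tsv",
                   "fusions.tsv", "expression.tsv", "ms_peptides.tsv",
                   "neodb.fasta", "ground_truth.json")

test_that("identical spec and seed give byte-identical file sets", {
  d1 <- file.path(tempdir(), "fx-det1")
  d2 <- file.path(tempdir(), "fx-det2")
  spec <- FixtureSpec(nProteins = 40L, nVariantsPerClass = 3L, seed = 17L)
  generateFixture(spec, d1)
  generateFixture(spec, d2)
  for (f in fixture_files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  d3 <- file.path(tempdir(), "fx-det3")
  generateFixture(FixtureSpec(nProteins = 40L, nVariantsPerClass = 3L,
                              seed = 18L), d3)
  expect_false(identical(readLines(file.path(d1, "proteome.fasta")),
                         readLines(file.path(d3, "proteome.fasta"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  generateFixture(FixtureSpec(nProteins = 40L, nVariantsPerClass = 3L,
                              seed = 21L), file.path(tempdir(), "fx-rng"))
  expect_identical(.Random.seed, before)
})

test_that("an all-zero variant spec yields valid empty pipeline inputs", {
  d <- file.path(tempdir(), "fx-empty")
  gt <- generateFixture(FixtureSpec(nProteins = 10L, nVariantsPerClass = 0L,
                                    seed = 5L), d)
  expect_length(gt$expected$binders, 0)
  suppressMessages(res <- runPipeline(d, seed = 5L))
  expect_equal(nrow(res$cascade$binders), 0)
  expect_equal(nrow(res$cascade$strict), 0)
})

test_that("full expression removes nothing at the expression stage", {
  d <- file.path(tempdir(), "fx-allexpr")
  gt <- generateFixture(FixtureSpec(nProteins = 40L, nVariantsPerClass = 3L,
                                    expressedFraction = 1, seed = 33L), d)
  expect_identical(gt$expected$expressed, gt$expected$binders)
  suppressMessages(res <- runPipeline(d, seed = 33L))
  expect_equal(nrow(res$cascade$expressed), nrow(res$cascade$binders))
})

test_that("survivor counts respond monotonically to detection fractions", {
  base <- list(nProteins = 40L, nVariantsPerClass = 3L, seed = 27L)
  n_ms <- vapply(c(0, 0.5, 1), function(fr) {
    d <- file.path(tempdir(), sprintf("fx-ms-%d", round(100 * fr)))
    gt <- generateFixture(FixtureSpec(nProteins = base$nProteins,
                                      nVariantsPerClass = base$nVariantsPerClass,
                                      msDetectedFraction = fr,
                                      seed = base$seed), d)
    length(gt$expected$ms_supported)
  }, numeric(1))
  expect_true(all(diff(n_ms) >= 0))
  expect_equal(n_ms[1], 0)

  n_ex <- vapply(c(0, 0.6, 1), function(fr) {
    d <- file.path(tempdir(), sprintf("fx-ex-%d", round(100 * fr)))
    gt <- generateFixture(FixtureSpec(nProteins = base$nProteins,
                                      nVariantsPerClass = base$nVariantsPerClass,
                                      expressedFraction = fr,
                                      seed = base$seed), d)
    length(gt$expected$expressed)
  }, numeric(1))
  expect_true(all(diff(n_ex) >= 0))
})

test_that("checkFixture passes on a fresh fixture and flags corruption", {
  d <- file.path(tempdir(), "fx-check")
  generateFixture(FixtureSpec(nProteins = 40L, nVariantsPerClass = 3L,
                              seed = 41L), d)
  suppressMessages(ck <- checkFixture(d))
  expect_true(ck$ok)
  expect_length(ck$problems, 0)

  # corrupt one reference residue in the variant table
  d2 <- file.path(tempdir(), "fx-corrupt")
  unlink(d2, recursive = TRUE)
  dir.create(d2)
  file.copy(file.path(d, fixture_files), d2)
  vt <- readLines(file.path(d2, "variants.tsv"))
  i <- grep("^mis01\t", vt)
  f <- strsplit(vt[i], "\t")[[1]]
  pc <- f[6]   # p.<Ref><Pos><Alt>
  ref <- substr(pc, 3, 3)
  wrong <- setdiff(c("W", "C"), c(ref, substr(pc, nchar(pc), nchar(pc))))[1]
  f[6] <- sub(paste0("^p\\.", ref), paste0("p.", wrong), pc)
  vt[i] <- paste(f, collapse = "\t")
  writeLines(vt, file.path(d2, "variants.tsv"))
  suppressMessages(ck2 <- checkFixture(d2))
  expect_false(ck2$ok)
  expect_true(any(grepl("mis01", ck2$problems)))

  # a missing input is a hard error
  unlink(file.path(d2, "expression.tsv"))
  expect_error(checkFixture(d2), "missing input")
})
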