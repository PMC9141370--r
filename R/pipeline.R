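# End-to-end driver over a fixture-layout input directory.

#' Run the whole pipeline on an input directory
#'
#' Expects the fixture file layout (`proteome.fasta`, `cds.fasta`,
#' `variants.tsv`, `fusions.tsv`, `expression.tsv`, `ms_peptides.tsv`,
#' `neodb.fasta`). Binding predictions come from `binding_I.tsv` /
#' `binding_II.tsv` (generic_long dialect) when present, otherwise from the
#' deterministic mock predictor — in that case `seed` is required and the
#' allele sets are taken from `alleles_I` / `alleles_II` (defaulting to the
#' published five class I and two class II alleles).
#'
#' Class I candidates go through the full cascade; class II candidates stop
#' after the MS-evidence stage, since the database-similarity and strict
#' screens are defined for class I restricted candidates only.
#'
#' @param dir input directory.
#' @param config a [FilterConfig-class].
#' @param seed integer seed for the mock predictor (ignored when binding
#'   tables are present).
#' @param alleles_I,alleles_II allele names for the mock predictor.
#' @param out_dir optional: write per-mutation-class result files here.
#' @return list with `mutants`, `candidates` (`$I`, `$II`), `binding`
#'   (`$I`, `$II`), `cascade` (stage tables pooled over both classes, the
#'   class I matching ratios, `summary`), `final` (annotated MS survivors)
#'   and `report` (a [FilterReport-class]).
#' @export
runPipeline <- function(dir, config = FilterConfig(), seed = NULL,
                        alleles_I = c("HLA-A*03:01", "HLA-B*07:02",
                                      "HLA-B*35:03", "HLA-C*07:02",
                                      "HLA-C*04:01"),
                        alleles_II = c("DRB4*01:03", "DRB4*01:01"),
                        out_dir = NULL) {
  proteome <- readProteome(file.path(dir, "proteome.fasta"))
  cds_path <- file.path(dir, "cds.fasta")
  cds <- if (file.exists(cds_path)) readCDS(cds_path) else NULL
  parsed <- parseVariantTable(file.path(dir, "variants.tsv"), dialect = "simple")
  fus_path <- file.path(dir, "fusions.tsv")
  fusions <- if (file.exists(fus_path)) parseFusionTable(fus_path)$records else list()
  expression <- parseExpression(file.path(dir, "expression.tsv"))
  ms <- parseMSEvidence(file.path(dir, "ms_peptides.tsv"))
  neodb <- loadNeoDB(file.path(dir, "neodb.fasta"))

  built <- mutantProteins(parsed$records, proteome, cds, fusions)
  mutants <- built$mutants
  cand_I <- extractAllWindows(mutants, mhc_class = "I")
  cand_II <- extractAllWindows(mutants, mhc_class = "II")
  if (config@dropWildtype) {
    cand_I <- dropWildtypeWindows(cand_I, proteome)
    cand_II <- dropWildtypeWindows(cand_II, proteome)
  }

  read_or_mock <- function(file, cand, alleles, mhc) {
    path <- file.path(dir, file)
    if (file.exists(path)) {
      parseBindingTable(path, dialect = "generic_long", candidates = cand)
    } else {
      if (is.null(seed)) {
        stop(sprintf("no %s and no seed for the mock predictor", file),
             call. = FALSE)
      }
      mockPredict(cand, alleles, seed, mhc_class = mhc)
    }
  }
  bind_I <- read_or_mock("binding_I.tsv", cand_I, alleles_I, "I")
  bind_II <- read_or_mock("binding_II.tsv", cand_II, alleles_II, "II")

  casc_I <- runCascade(cand_I, bind_I, expression, ms, mutants,
                       parsed$records, neodb, config)
  cfg_II <- config
  cfg_II@doNeoDB <- FALSE
  cfg_II@doStrict <- FALSE
  casc_II <- runCascade(cand_II, bind_II, expression, ms, mutants,
                        parsed$records, NULL, cfg_II)

  pool <- function(stage) {
    out <- rbind(casc_I[[stage]], casc_II[[stage]])
    rownames(out) <- NULL
    out
  }
  cascade <- list(binders = pool("binders"), expressed = pool("expressed"),
                  ms_supported = pool("ms_supported"),
                  db_matched = casc_I$db_matched, strict = casc_I$strict,
                  matching_ratios = casc_I$matching_ratios,
                  summary = rbind(cbind(mhc_class = "I", casc_I$summary),
                                  cbind(mhc_class = "II", casc_II$summary)))

  # final annotated table: MS survivors with similarity + locus columns
  final <- cascade$ms_supported
  if (nrow(final) > 0) {
    pp <- casc_I$db_per_peptide
    if (!is.null(pp)) {
      idx <- match(final$peptide, pp$peptide)
      final$best_similarity <- pp$best_similarity[idx]
      final$best_subject <- pp$best_subject[idx]
      final$best_tier <- pp$best_tier[idx]
    }
    locus <- vapply(parsed$records, function(v)
      ifelse(is.na(v@genomicLocus), "", v@genomicLocus), character(1))
    names(locus) <- vapply(parsed$records, function(v) v@variantId, character(1))
    final$genomic_locus <- ifelse(final$variant_id %in% names(locus),
                                  locus[final$variant_id], "")
  }
  report <- aggregateReport(
    list(binders = cascade$binders, expressed = cascade$expressed,
         ms_supported = cascade$ms_supported, db_matched = cascade$db_matched,
         strict = cascade$strict),
    matchingRatios = cascade$matching_ratios)
  if (!is.null(out_dir)) writeResults(final, out_dir)
  list(mutants = mutants, candidates = list(I = cand_I, II = cand_II),
       binding = list(I = bind_I, II = bind_II), cascade = cascade,
       final = final, report = report)
}
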