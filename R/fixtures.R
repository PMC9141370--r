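# Synthetic input generator: a complete, internally consistent toy input
# set (proteome, CDS, variants, fusions, expression, MS evidence, curated
# peptide database) plus a ground-truth record of which candidates must
# survive each filter stage, so the whole cascade is testable offline.

CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), C = c("TGT", "TGC"),
  D = c("GAT", "GAC"), E = c("GAA", "GAG"), F = c("TTT", "TTC"),
  G = c("GGT", "GGC", "GGA", "GGG"), H = c("CAT", "CAC"),
  I = c("ATT", "ATC", "ATA"), K = c("AAA", "AAG"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), M = "ATG",
  N = c("AAT", "AAC"), P = c("CCT", "CCC", "CCA", "CCG"),
  Q = c("CAA", "CAG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), V = c("GTT", "GTC", "GTA", "GTG"),
  W = "TGG", Y = c("TAT", "TAC"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
random_aa <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# Reverse-translate with uniformly sampled synonymous codons; the CDS
# translates back to exactly the input protein.
#' @noRd
reverse_translate <- function(protein) {
  codons <- vapply(strsplit(protein, "")[[1]], function(aa) {
    opts <- CODON_TABLE[[aa]]
    opts[sample.int(length(opts), 1)]
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1))
}

#' Generate a synthetic fixture
#'
#' Writes a full input set under `out_dir`: `proteome.fasta` (first residue
#' always M), `cds.fasta` (reverse-translated, consistent with the
#' proteome), `variants.tsv` (simple dialect, all four non-fusion classes,
#' reference residues guaranteed correct), `fusions.tsv`, `expression.tsv`
#' (expressed transcripts log-uniform in 1-1000 TPM, the rest 0; fusion
#' partner genes included as rows), `ms_peptides.tsv` (fragments of the
#' true mutant proteins spanning every mutation-anchored window of detected
#' variants, plus wild-type decoy fragments from untouched proteins),
#' `neodb.fasta` (exact copies of some class I candidate windows planted as
#' high-confidence entries, plus random decoy peptides), and
#' `ground_truth.json`.
#'
#' Each variant sits on its own protein, so MS evidence for one variant can
#' never support another. The ground truth lists, per cascade stage, the
#' exact `variant|peptide|allele` keys that must survive, derived by direct
#' threshold arithmetic on the deterministic mock binding table — except
#' the database-similarity stage, where only the planted exact copies are
#' knowable and recorded as guaranteed matches.
#'
#' Identical spec and seed produce byte-identical file sets; the caller's
#' RNG state is left untouched.
#'
#' @param spec a [FixtureSpec-class].
#' @param out_dir output directory (created).
#' @return invisibly, the ground-truth list.
#' @export
generateFixture <- function(spec, out_dir) {
  stopifnot(is(spec, "FixtureSpec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec@seed)

  nP <- spec@nProteins
  nV <- spec@nVariantsPerClass
  need <- 4L * nV + 2L * nV   # one protein per variant + two per fusion
  if (nP < need + 2L) {
    stop(sprintf("need at least %d proteins for %d variants/class", need + 2L, nV),
         call. = FALSE)
  }
  lens <- sample(seq(spec@proteinLengthRange[1], spec@proteinLengthRange[2]),
                 nP, replace = TRUE)
  prots <- vapply(lens, function(L) paste0("M", random_aa(L - 1L)), character(1))
  pid <- sprintf("PROT%03d", seq_len(nP))
  gene <- sprintf("GENE%03d", seq_len(nP))
  tx <- sprintf("TX%03d", seq_len(nP))
  names(prots) <- pid
  cds <- vapply(prots, reverse_translate, character(1))
  names(cds) <- tx

  # assign each variant its own protein
  pool <- sample.int(nP)
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }

  variants <- list()
  margin <- 16L
  for (i in seq_len(nV)) {   # missense
    p <- take(1)
    L <- nchar(prots[p])
    pos <- sample(seq(margin, L - margin), 1)
    ref <- substr(prots[p], pos, pos)
    alt <- sample(setdiff(AA_STANDARD, ref), 1)
    variants[[length(variants) + 1L]] <- VariantRecord(
      sprintf("mis%02d", i), gene[p], tx[p], pid[p], "missense",
      proteinPos = pos, refAA = ref, altAA = alt,
      genomicLocus = sprintf("chr1:%d:A:G", 1000L * p + pos))
  }
  for (i in seq_len(nV)) {   # in-frame insertion
    p <- take(1)
    L <- nchar(prots[p])
    pos <- sample(seq(margin, L - margin), 1)
    ins <- random_aa(sample(1:3, 1))
    variants[[length(variants) + 1L]] <- VariantRecord(
      sprintf("ins%02d", i), gene[p], tx[p], pid[p], "inframe_ins",
      proteinPos = pos, proteinEnd = pos + 1L,
      refAA = paste0(substr(prots[p], pos, pos),
                     substr(prots[p], pos + 1L, pos + 1L)),
      altAA = ins)
  }
  for (i in seq_len(nV)) {   # in-frame deletion
    p <- take(1)
    L <- nchar(prots[p])
    pos <- sample(seq(margin, L - margin - 3L), 1)
    dlen <- sample(1:3, 1)
    e <- pos + dlen - 1L
    variants[[length(variants) + 1L]] <- VariantRecord(
      sprintf("del%02d", i), gene[p], tx[p], pid[p], "inframe_del",
      proteinPos = pos, proteinEnd = e,
      refAA = if (dlen == 1L) substr(prots[p], pos, pos) else
        paste0(substr(prots[p], pos, pos), substr(prots[p], e, e)))
  }
  for (i in seq_len(nV)) {   # frameshift
    p <- take(1)
    L <- nchar(prots[p])
    codon <- sample(seq(margin, L - 40L), 1)
    base <- 3L * (codon - 1L) + 2L
    if (i %% 2L == 1L) {
      chg <- sprintf("c.%d_%dins%s", base, base + 1L,
                     paste(sample(c("A", "C", "G", "T"), 1), collapse = ""))
    } else {
      chg <- sprintf("c.%d_%ddel", base, base + 1L)
    }
    variants[[length(variants) + 1L]] <- VariantRecord(
      sprintf("fs%02d", i), gene[p], tx[p], pid[p], "frameshift",
      proteinPos = codon, cdnaChange = chg)
  }
  fusions <- list()
  for (i in seq_len(nV)) {
    pq <- take(2)
    j <- sample(20:30, 1)
    in_frame <- i %% 2L == 1L
    left <- substr(prots[pq[1]], 1, j)
    right <- if (in_frame) substr(prots[pq[2]], 50, 50 + sample(20:30, 1)) else
      random_aa(sample(20:30, 1))
    fusions[[length(fusions) + 1L]] <- FusionRecord(
      sprintf("fus%02d", i), gene[pq[1]], gene[pq[2]],
      paste0(left, right), j,
      if (in_frame) "in_frame" else "frameshift_3prime")
  }

  # expression: a seeded coin per variant decides expressed/unexpressed
  all_tx_tpm <- stats::setNames(rep(0, nP), tx)
  var_expressed <- logical(length(variants) + length(fusions))
  ids <- c(vapply(variants, function(v) v@variantId, character(1)),
           vapply(fusions, function(f) f@fusionId, character(1)))
  names(var_expressed) <- ids
  for (v in variants) {
    expressed <- stats::runif(1) < spec@expressedFraction
    var_expressed[v@variantId] <- expressed
    all_tx_tpm[v@transcriptId] <- if (expressed) 10^stats::runif(1, 0, 3) else 0
  }
  # background expression on transcripts no variant sits on
  var_tx <- vapply(variants, function(v) v@transcriptId, character(1))
  for (t in setdiff(names(all_tx_tpm), var_tx)) {
    if (stats::runif(1) < spec@expressedFraction) {
      all_tx_tpm[t] <- 10^stats::runif(1, 0, 3)
    }
  }
  gene_rows <- stats::setNames(numeric(0), character(0))
  for (f in fusions) {
    expressed <- stats::runif(1) < spec@expressedFraction
    var_expressed[f@fusionId] <- expressed
    t5 <- 10^stats::runif(1, 0, 3)
    gene_rows[f@gene5] <- if (expressed) t5 else 0
    gene_rows[f@gene3] <- 0   # partner 3' silent; max() rule uses the 5' gene
  }
  expr_df <- data.frame(
    target_id = c(names(all_tx_tpm), names(gene_rows)),
    length = 3L * c(nchar(prots), rep(150L, length(gene_rows))),
    tpm = sprintf("%.6f", c(unname(all_tx_tpm), unname(gene_rows))),
    stringsAsFactors = FALSE)

  # mutant proteins (construction is exercised separately by its own tests)
  built <- mutantProteins(variants, new("ReferenceProteome", sequences = prots,
                                        geneToProtein = split(pid, gene)),
                          cds = cds, fusions = fusions)
  stopifnot(nrow(built$failures) == 0)
  mutants <- built$mutants

  # MS evidence: one mutant-protein fragment per detected variant, covering
  # every mutation-anchored window (region padded by the widest window), so
  # by construction each candidate of a detected variant has support
  var_ms <- stats::setNames(stats::runif(length(ids)) < spec@msDetectedFraction, ids)
  frags <- character(0)
  for (m in mutants) {
    if (!var_ms[m@sourceVariant]) next
    L <- nchar(m@sequence)
    frags <- c(frags, substr(m@sequence, max(1L, m@mutStart - 30L),
                             min(L, m@mutEnd + 30L)))
  }
  decoy_from <- pool   # proteins no variant touches
  n_decoys <- min(5L, length(decoy_from))
  for (p in decoy_from[seq_len(n_decoys)]) {
    L <- nchar(prots[p])
    s <- sample(seq(1L, L - 15L), 1)
    frags <- c(frags, substr(prots[p], s, s + sample(9:19, 1)))
  }

  # candidate windows (needed for the mock binding table and the planted
  # database entries)
  cand_I <- extractAllWindows(mutants, mhc_class = "I")
  cand_II <- extractAllWindows(mutants, mhc_class = "II")
  bind_I <- mockPredict(cand_I, spec@allelesI, spec@seed, mhc_class = "I")
  bind_II <- mockPredict(cand_II, spec@allelesII, spec@seed, mhc_class = "II")

  # neoantigen database: planted exact copies of class I windows + decoys
  plant_n <- min(8L, length(unique(cand_I$peptide)))
  planted <- sample(unique(cand_I$peptide), plant_n)
  decoys <- character(0)
  while (length(decoys) < spec@neodbSize) {
    d <- random_aa(sample(9:11, 1))
    if (!(d %in% cand_I$peptide) && !(d %in% cand_II$peptide)) {
      decoys <- c(decoys, d)
    }
  }
  db_pep <- c(planted, decoys)
  db_tier <- c(rep("high", plant_n),
               sample(c("high", "medium"), length(decoys), replace = TRUE))

  # ground truth by direct threshold arithmetic on the mock table
  key_of <- function(cand, bind, weak_max) {
    hit <- bind[bind$rank_pct <= weak_max, c("peptide", "allele"), drop = FALSE]
    mg <- merge(cand[, c("variant_id", "peptide")], hit, by = "peptide")
    sprintf("%s|%s|%s", mg$variant_id, mg$peptide, mg$allele)
  }
  binder_keys <- c(key_of(cand_I, bind_I, 2), key_of(cand_II, bind_II, 10))
  var_of_key <- sub("\\|.*$", "", binder_keys)
  expressed_keys <- binder_keys[var_expressed[var_of_key]]
  ms_keys <- expressed_keys[var_ms[sub("\\|.*$", "", expressed_keys)]]
  # strict: class I only, mock IC50 <= 34 nM and variant TPM >= 33
  tpm_of_var <- stats::setNames(numeric(length(ids)), ids)
  for (v in variants) tpm_of_var[v@variantId] <- all_tx_tpm[v@transcriptId]
  for (f in fusions) tpm_of_var[f@fusionId] <- max(gene_rows[f@gene5], gene_rows[f@gene3])
  ic50_of <- stats::setNames(bind_I$ic50_nM, paste(bind_I$peptide, bind_I$allele, sep = "|"))
  strict_keys <- ms_keys[vapply(strsplit(ms_keys, "|", fixed = TRUE), function(kk) {
    if (!(kk[2] %in% cand_I$peptide)) return(FALSE)
    ic <- ic50_of[paste(kk[2], kk[3], sep = "|")]
    !is.na(ic) && ic <= 34 && tpm_of_var[kk[1]] >= 33
  }, logical(1))]

  # write files
  pfa <- Biostrings::AAStringSet(unname(prots))
  names(pfa) <- sprintf("%s GN=%s", pid, gene)
  Biostrings::writeXStringSet(pfa, file.path(out_dir, "proteome.fasta"), width = 60L)
  cfa <- Biostrings::DNAStringSet(unname(cds))
  names(cfa) <- tx
  Biostrings::writeXStringSet(cfa, file.path(out_dir, "cds.fasta"), width = 60L)
  writeVariantTable(variants, file.path(out_dir, "variants.tsv"))
  writeFusionTable(fusions, file.path(out_dir, "fusions.tsv"))
  write_tsv_atomic(expr_df, file.path(out_dir, "expression.tsv"))
  write_tsv_atomic(data.frame(Sequence = frags, stringsAsFactors = FALSE),
                   file.path(out_dir, "ms_peptides.tsv"))
  dbfa <- Biostrings::AAStringSet(db_pep)
  names(dbfa) <- sprintf("neo%03d tier=%s", seq_along(db_pep), db_tier)
  Biostrings::writeXStringSet(dbfa, file.path(out_dir, "neodb.fasta"), width = 60L)

  gt <- list(
    seed = spec@seed,
    alleles_I = spec@allelesI,
    alleles_II = spec@allelesII,
    variants = data.frame(
      id = ids,
      expressed = unname(var_expressed[ids]),
      ms_detected = unname(var_ms[ids]),
      tpm = unname(tpm_of_var[ids]),
      stringsAsFactors = FALSE),
    planted_peptides = planted,
    expected = list(binders = sort(binder_keys),
                    expressed = sort(expressed_keys),
                    ms_supported = sort(ms_keys),
                    strict = sort(strict_keys)))
  jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(gt)
}

#' Validate a fixture directory
#'
#' Re-reads a generated fixture and checks (i) every CDS translates exactly
#' to its protein, (ii) every variant's reference residues match the
#' proteome (mutant construction succeeds for all records), and (iii) the
#' pipeline, run with the mock predictor under the recorded seed,
#' reproduces the ground-truth survivor keys at the binder, expression, MS
#' and strict stages exactly, and matches every planted database peptide
#' that reaches the similarity screen.
#'
#' @param dir fixture directory from [generateFixture()].
#' @return list with `ok` (logical) and `problems` (character vector of
#'   offending records; empty when `ok`).
#' @export
checkFixture <- function(dir) {
  problems <- character(0)
  need <- c("proteome.fasta", "cds.fasta", "variants.tsv", "fusions.tsv",
            "expression.tsv", "ms_peptides.tsv", "neodb.fasta",
            "ground_truth.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    stop(sprintf("fixture is missing input file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  proteome <- readProteome(file.path(dir, "proteome.fasta"))
  cds <- readCDS(file.path(dir, "cds.fasta"))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)

  # CDS <-> protein consistency
  for (i in seq_along(cds)) {
    tr <- translate_to_stop(cds[[i]])
    prot_id <- sub("^TX", "PROT", names(cds)[i])
    ref <- proteomeSeq(proteome, prot_id)
    if (is.na(ref) || tr$seq != ref) {
      problems <- c(problems, sprintf("CDS %s does not translate to %s",
                                      names(cds)[i], prot_id))
    }
  }
  parsed <- parseVariantTable(file.path(dir, "variants.tsv"), dialect = "simple")
  if (nrow(parsed$rejects) > 0) {
    problems <- c(problems, sprintf("variant row %d rejected: %s",
                                    parsed$rejects$row, parsed$rejects$reason))
  }
  fus <- parseFusionTable(file.path(dir, "fusions.tsv"))
  built <- mutantProteins(parsed$records, proteome, cds, fus$records)
  if (nrow(built$failures) > 0) {
    problems <- c(problems, sprintf("mutant construction failed for %s: %s",
                                    built$failures$variant_id,
                                    built$failures$reason))
  }
  if (length(problems) > 0) return(list(ok = FALSE, problems = problems))

  res <- runPipeline(dir, seed = gt$seed)
  key <- function(df) sort(sprintf("%s|%s|%s", df$variant_id, df$peptide, df$allele))
  cmp <- function(stage_name, got, want) {
    got <- as.character(got)
    want <- as.character(unlist(want))
    if (!identical(sort(got), sort(want))) {
      problems <<- c(problems, sprintf(
        "stage '%s': %d survivor(s) found, %d expected; sets differ",
        stage_name, length(got), length(unlist(want))))
    }
  }
  cmp("binders", key(res$cascade$binders), gt$expected$binders)
  cmp("expressed", key(res$cascade$expressed), gt$expected$expressed)
  cmp("ms_supported", key(res$cascade$ms_supported), gt$expected$ms_supported)
  cmp("strict", key(res$cascade$strict), gt$expected$strict)
  planted_reachable <- intersect(unlist(gt$planted_peptides),
                                 res$cascade$ms_supported$peptide)
  not_matched <- setdiff(planted_reachable, res$cascade$db_matched$peptide)
  if (length(not_matched) > 0) {
    problems <- c(problems, sprintf("planted peptide %s not matched by the similarity screen",
                                    not_matched))
  }
  list(ok = length(problems) == 0, problems = problems)
}
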