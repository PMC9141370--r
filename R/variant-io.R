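# Parsing of annotated variant tables, expression tables, MS evidence,
# fusion records and the curated neoantigen database.

# --- HGVS-like grammars ----------------------------------------------------

# cDNA edit grammar (frameshifts): c.6_7insC | c.6insC | c.6delA | c.6del |
# c.6_8del | c.6_8delAAT. Returns type, 1-based start/end on the CDS, the
# inserted/deleted bases (may be "" for bare del ranges) and the indel length.
#' @noRd
parse_cdna_change <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^c\\.([0-9]+)(?:_([0-9]+))?ins([ACGTacgt]+)$", x))[[1]]
  if (length(m) > 0) {
    start <- as.integer(m[2])
    return(list(type = "ins", start = start, end = start,
                seq = toupper(m[4]), indel_len = nchar(m[4])))
  }
  m <- regmatches(x, regexec("^c\\.([0-9]+)(?:_([0-9]+))?del([ACGTacgt]*)$", x))[[1]]
  if (length(m) > 0) {
    start <- as.integer(m[2])
    end <- if (nzchar(m[3])) as.integer(m[3]) else start
    if (end < start) stop(sprintf("bad cDNA range in '%s'", x), call. = FALSE)
    seq <- toupper(m[4])
    len <- end - start + 1L
    if (nzchar(seq) && nchar(seq) != len) {
      stop(sprintf("cDNA deletion '%s': range length %d != %d deleted bases",
                   x, len, nchar(seq)), call. = FALSE)
    }
    return(list(type = "del", start = start, end = end, seq = seq,
                indel_len = len))
  }
  stop(sprintf("unparseable cDNA change '%s'", x), call. = FALSE)
}

# Protein change grammar: p.Y5F | p.A4_Y5del | p.M1del | p.K3_T4insQQ.
# Anything else raises, and the caller routes the row to the rejects list.
#' @noRd
parse_protein_change <- function(x) {
  x <- trimws(x)
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)_([A-Z])([0-9]+)ins([A-Z]+)$", x))[[1]]
  if (length(m) > 0) {
    pos <- as.integer(m[3]); end <- as.integer(m[5])
    if (end != pos + 1L) stop(sprintf("insertion anchors must be adjacent in '%s'", x),
                              call. = FALSE)
    return(list(varClass = "inframe_ins", pos = pos, end = end,
                refAA = paste0(m[2], m[4]), altAA = m[6]))
  }
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)_([A-Z])([0-9]+)del$", x))[[1]]
  if (length(m) > 0) {
    pos <- as.integer(m[3]); end <- as.integer(m[5])
    if (end < pos) stop(sprintf("reversed deletion range in '%s'", x), call. = FALSE)
    return(list(varClass = "inframe_del", pos = pos, end = end,
                refAA = paste0(m[2], m[4]), altAA = ""))
  }
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)del$", x))[[1]]
  if (length(m) > 0) {
    pos <- as.integer(m[3])
    return(list(varClass = "inframe_del", pos = pos, end = pos,
                refAA = m[2], altAA = ""))
  }
  m <- regmatches(x, regexec("^p\\.([A-Z])([0-9]+)([A-Z])$", x))[[1]]
  if (length(m) > 0) {
    return(list(varClass = "missense", pos = as.integer(m[3]), end = NA_integer_,
                refAA = m[2], altAA = m[4]))
  }
  stop(sprintf("unparseable protein change '%s'", x), call. = FALSE)
}

#' @noRd
format_protein_change <- function(rec) {
  switch(rec@varClass,
    missense = sprintf("p.%s%d%s", rec@refAA, rec@proteinPos, rec@altAA),
    inframe_del = if (!is.na(rec@proteinEnd) && rec@proteinEnd > rec@proteinPos) {
      sprintf("p.%s%d_%s%ddel", substr(rec@refAA, 1, 1), rec@proteinPos,
              substr(rec@refAA, nchar(rec@refAA), nchar(rec@refAA)), rec@proteinEnd)
    } else {
      sprintf("p.%s%ddel", rec@refAA, rec@proteinPos)
    },
    inframe_ins = sprintf("p.%s%d_%s%dins%s", substr(rec@refAA, 1, 1),
                          rec@proteinPos, substr(rec@refAA, 2, 2),
                          rec@proteinEnd, rec@altAA),
    "")
}

# ExonicFunc vocabulary: mapped classes, silently-skipped annotation classes,
# everything else is an unknown token and the row is rejected.
ANNOVAR_CLASS_MAP <- c(
  "nonsynonymous SNV" = "missense",
  "nonframeshift insertion" = "inframe_ins",
  "nonframeshift deletion" = "inframe_del",
  "frameshift insertion" = "frameshift",
  "frameshift deletion" = "frameshift"
)
ANNOVAR_SKIP <- c("synonymous SNV", "intronic", "intergenic", "UTR3", "UTR5",
                  "upstream", "downstream", "splicing", "ncRNA_exonic",
                  "ncRNA_intronic")

# --- Variant table parsing -------------------------------------------------

#' Parse an annotated somatic variant table
#'
#' Reads a tab-separated variant annotation table and returns typed
#' [VariantRecord-class] objects. Two dialects are understood:
#'
#' * `"annovar"`: columns `Gene`, `Transcript`, `ExonicFunc`, `AAChange`.
#'   `AAChange` is either a bare protein change (`"p.Y5F"`) or one or more
#'   comma-separated ANNOVAR annotation strings
#'   (`"GENE:NM_1:exon2:c.A15T:p.Y5F"`); multi-transcript annotations yield
#'   one record per transcript. Frameshift rows take their cDNA edit from the
#'   `c.` token (or an optional `CDSChange` column).
#' * `"simple"`: columns `variant_id`, `gene`, `transcript_id`, `protein_id`,
#'   `var_class`, `protein_change`, `cdna_change` (optional `genomic_locus`).
#'
#' Synonymous/non-exonic rows are skipped with a count; rows whose class
#' token or change string does not parse go to a rejects table, never
#' silently dropped.
#'
#' @param path tab-separated input file.
#' @param dialect `"annovar"` or `"simple"`.
#' @return list with `records` (list of [VariantRecord-class]), `rejects`
#'   (data.frame `row`, `reason`), and `skipped` (integer count).
#' @export
parseVariantTable <- function(path, dialect = c("annovar", "simple")) {
  dialect <- match.arg(dialect)
  records <- list()
  rejects <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skipped <- 0L
  push_reject <- function(i, reason) {
    rejects[nrow(rejects) + 1L, ] <<- list(i, reason)
  }

  if (dialect == "simple") {
    df <- read_tsv_checked(path, required = c("variant_id", "gene",
                                              "transcript_id", "protein_id",
                                              "var_class", "protein_change",
                                              "cdna_change"),
                           what = "variant table")
    for (i in seq_len(nrow(df))) {
      vc <- df$var_class[i]
      if (!vc %in% VAR_CLASSES) {
        push_reject(i, sprintf("unknown var_class '%s'", vc))
        next
      }
      locus <- if ("genomic_locus" %in% colnames(df) && nzchar(df$genomic_locus[i]))
        df$genomic_locus[i] else NA_character_
      rec <- tryCatch({
        if (vc == "frameshift") {
          ed <- parse_cdna_change(df$cdna_change[i])
          VariantRecord(df$variant_id[i], df$gene[i], df$transcript_id[i],
                        df$protein_id[i], "frameshift",
                        proteinPos = (ed$start - 1L) %/% 3L + 1L,
                        cdnaChange = df$cdna_change[i], genomicLocus = locus)
        } else {
          pc <- parse_protein_change(df$protein_change[i])
          if (pc$varClass != vc) {
            stop(sprintf("protein change '%s' parses as %s, row says %s",
                         df$protein_change[i], pc$varClass, vc), call. = FALSE)
          }
          VariantRecord(df$variant_id[i], df$gene[i], df$transcript_id[i],
                        df$protein_id[i], vc, proteinPos = pc$pos,
                        proteinEnd = pc$end, refAA = pc$refAA, altAA = pc$altAA,
                        cdnaChange = if (nzchar(df$cdna_change[i]))
                          df$cdna_change[i] else NA_character_,
                        genomicLocus = locus)
        }
      }, error = function(e) conditionMessage(e))
      if (is.character(rec)) push_reject(i, rec) else records[[length(records) + 1L]] <- rec
    }
  } else {
    df <- read_tsv_checked(path, required = c("Gene", "Transcript",
                                              "ExonicFunc", "AAChange"),
                           what = "variant table")
    for (i in seq_len(nrow(df))) {
      func <- df$ExonicFunc[i]
      if (func %in% ANNOVAR_SKIP) { skipped <- skipped + 1L; next }
      if (!func %in% names(ANNOVAR_CLASS_MAP)) {
        push_reject(i, sprintf("unknown ExonicFunc '%s'", func))
        next
      }
      vc <- ANNOVAR_CLASS_MAP[[func]]
      # one annotation token per transcript
      tokens <- trimws(strsplit(df$AAChange[i], ",", fixed = TRUE)[[1]])
      tokens <- tokens[nzchar(tokens)]
      if (length(tokens) == 0) { push_reject(i, "empty AAChange"); next }
      for (tok in tokens) {
        parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
        tx <- df$Transcript[i]
        cdna <- if ("CDSChange" %in% colnames(df) && nzchar(df$CDSChange[i]))
          df$CDSChange[i] else NA_character_
        pchg <- tok
        if (length(parts) > 1) {
          tx <- parts[2]
          ctok <- grep("^c\\.", parts, value = TRUE)
          if (length(ctok) > 0 && is.na(cdna)) cdna <- ctok[1]
          ptok <- grep("^p\\.", parts, value = TRUE)
          pchg <- if (length(ptok) > 0) ptok[1] else ""
        }
        vid <- sprintf("%s_%d_%s", df$Gene[i], i, tx)
        rec <- tryCatch({
          if (vc == "frameshift") {
            if (is.na(cdna)) stop("frameshift row lacks a cDNA change", call. = FALSE)
            ed <- parse_cdna_change(cdna)
            VariantRecord(vid, df$Gene[i], tx, NA_character_, "frameshift",
                          proteinPos = (ed$start - 1L) %/% 3L + 1L,
                          cdnaChange = cdna)
          } else {
            pc <- parse_protein_change(pchg)
            if (pc$varClass != vc) {
              stop(sprintf("'%s' parses as %s but ExonicFunc says %s",
                           pchg, pc$varClass, vc), call. = FALSE)
            }
            VariantRecord(vid, df$Gene[i], tx, NA_character_, vc,
                          proteinPos = pc$pos, proteinEnd = pc$end,
                          refAA = pc$refAA, altAA = pc$altAA, cdnaChange = cdna)
          }
        }, error = function(e) conditionMessage(e))
        if (is.character(rec)) push_reject(i, rec) else records[[length(records) + 1L]] <- rec
      }
    }
  }
  if (skipped > 0) message(sprintf("parseVariantTable: skipped %d non-protein-altering row(s)", skipped))
  list(records = records, rejects = rejects, skipped = skipped)
}

#' Serialize VariantRecords to the simple TSV dialect
#'
#' Inverse of `parseVariantTable(..., dialect = "simple")`: re-parsing the
#' written file yields identical records.
#'
#' @param records list of [VariantRecord-class].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeVariantTable <- function(records, path) {
  df <- data.frame(
    variant_id = vapply(records, function(r) r@variantId, character(1)),
    gene = vapply(records, function(r) r@gene, character(1)),
    transcript_id = vapply(records, function(r) r@transcriptId, character(1)),
    protein_id = vapply(records, function(r) r@proteinId, character(1)),
    var_class = vapply(records, function(r) r@varClass, character(1)),
    protein_change = vapply(records, format_protein_change, character(1)),
    cdna_change = vapply(records, function(r)
      ifelse(is.na(r@cdnaChange), "", r@cdnaChange), character(1)),
    genomic_locus = vapply(records, function(r)
      ifelse(is.na(r@genomicLocus), "", r@genomicLocus), character(1)),
    stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

# --- Expression ------------------------------------------------------------

#' Parse a transcript expression table (Kallisto abundance style)
#'
#' @param path TSV with header columns `target_id` and `tpm` (extra columns
#'   such as `length` or `est_counts` are ignored).
#' @return named numeric vector of TPM keyed by id. Duplicate ids keep the
#'   maximum TPM (with a message). Negative TPM aborts: the file is corrupt.
#' @export
parseExpression <- function(path) {
  df <- read_tsv_checked(path, required = c("target_id", "tpm"),
                         what = "expression table")
  tpm <- suppressWarnings(as.numeric(df$tpm))
  if (anyNA(tpm)) stop("non-numeric tpm values in expression table", call. = FALSE)
  if (any(tpm < 0)) stop("negative TPM in expression table; input is corrupt", call. = FALSE)
  ids <- df$target_id
  if (anyDuplicated(ids)) {
    message(sprintf("parseExpression: %d duplicate id(s), keeping max TPM",
                    sum(duplicated(ids))))
    tpm <- tapply(tpm, ids, max)
    out <- as.numeric(tpm)
    names(out) <- names(tpm)
    return(out)
  }
  names(tpm) <- ids
  tpm
}

# --- MS evidence -----------------------------------------------------------

#' Parse an identified-peptide list (MaxQuant peptides.txt style)
#'
#' @param path TSV with a `Sequence` column.
#' @param min_length minimum peptide length retained (default 7, the search
#'   engine's configured minimum).
#' @return character vector of unique uppercase peptide sequences.
#' @export
parseMSEvidence <- function(path, min_length = 7L) {
  df <- read_tsv_checked(path, required = "Sequence", what = "MS peptide table")
  peps <- toupper(trimws(df$Sequence))
  peps <- peps[nzchar(peps)]
  short <- nchar(peps) < min_length
  if (any(short)) {
    message(sprintf("parseMSEvidence: dropped %d peptide(s) shorter than %d",
                    sum(short), min_length))
    peps <- peps[!short]
  }
  bad <- has_nonstandard_aa(peps)
  if (any(bad)) {
    warning(sprintf("parseMSEvidence: dropped %d peptide(s) with non-standard residues",
                    sum(bad)), call. = FALSE)
    peps <- peps[!bad]
  }
  unique(peps)
}

# --- Neoantigen reference database ----------------------------------------

#' Load a curated neoantigen peptide database
#'
#' Accepts either a FASTA file whose headers carry `tier=high` or
#' `tier=medium`, or a two-column TSV `peptide<TAB>tier`. Entries with
#' non-amino-acid characters are rejected with a warning; duplicates on
#' (peptide, tier) are collapsed. The same peptide may legitimately appear
#' in both tiers.
#'
#' @param path FASTA or TSV file.
#' @return data.frame with columns `peptide`, `tier`.
#' @export
loadNeoDB <- function(path) {
  if (!file.exists(path)) stop(sprintf("neoantigen DB not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) > 0 && startsWith(first, ">")) {
    ss <- Biostrings::readBStringSet(path)
    peps <- toupper(as.character(ss))
    tiers <- ifelse(grepl("tier=medium", names(ss), fixed = TRUE), "medium",
                    ifelse(grepl("tier=high", names(ss), fixed = TRUE), "high", NA))
    if (anyNA(tiers)) {
      warning(sprintf("loadNeoDB: %d entr(ies) without tier= tag treated as medium",
                      sum(is.na(tiers))), call. = FALSE)
      tiers[is.na(tiers)] <- "medium"
    }
  } else {
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE,
                            col.names = c("peptide", "tier"))
    peps <- toupper(trimws(df$peptide))
    tiers <- trimws(df$tier)
  }
  ok_tier <- tiers %in% c("high", "medium")
  ok_seq <- is_standard_aa(peps)
  bad <- !(ok_tier & ok_seq)
  if (any(bad)) {
    warning(sprintf("loadNeoDB: rejected %d entr(ies) with invalid residues or tier",
                    sum(bad)), call. = FALSE)
  }
  out <- unique(data.frame(peptide = peps[!bad], tier = tiers[!bad],
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# --- Fusions ---------------------------------------------------------------

#' Parse fusion coding-effect records
#'
#' Expects a TSV with columns `fusion_id`, `gene5`, `gene3`,
#' `junction_protein_seq`, `junction_index`, `frame_status` (coding-effect
#' style: the junction product is already translated).
#'
#' @param path TSV path.
#' @return list with `records` (list of [FusionRecord-class]) and `rejects`
#'   (data.frame `row`, `reason`).
#' @export
parseFusionTable <- function(path) {
  df <- read_tsv_checked(path, required = c("fusion_id", "gene5", "gene3",
                                            "junction_protein_seq",
                                            "junction_index", "frame_status"),
                         what = "fusion table")
  records <- list()
  rejects <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      FusionRecord(df$fusion_id[i], df$gene5[i], df$gene3[i],
                   df$junction_protein_seq[i],
                   as.integer(df$junction_index[i]), df$frame_status[i]),
      error = function(e) conditionMessage(e))
    if (is.character(rec)) {
      rejects[nrow(rejects) + 1L, ] <- list(i, rec)
    } else {
      records[[length(records) + 1L]] <- rec
    }
  }
  list(records = records, rejects = rejects)
}

#' @noRd
writeFusionTable <- function(records, path) {
  df <- data.frame(
    fusion_id = vapply(records, function(r) r@fusionId, character(1)),
    gene5 = vapply(records, function(r) r@gene5, character(1)),
    gene3 = vapply(records, function(r) r@gene3, character(1)),
    junction_protein_seq = vapply(records, function(r) r@junctionSeq, character(1)),
    junction_index = vapply(records, function(r) r@junctionIndex, integer(1)),
    frame_status = vapply(records, function(r) r@frameStatus, character(1)),
    stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}
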