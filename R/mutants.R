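# Construction of mutant protein sequences from variant records, and
# assembly of the customized proteogenomic search database.

#' @noRd
ref_mismatch <- function(pos, expected, observed) {
  stop(structure(class = c("neoforge_ref_mismatch", "error", "condition"),
                 list(message = sprintf(
                   "reference mismatch at position %d: expected '%s', observed '%s'",
                   pos, expected, observed),
                   call = NULL, pos = pos, expected = expected,
                   observed = observed)))
}

#' @noRd
invalid_variant <- function(msg) {
  stop(structure(class = c("neoforge_invalid_variant", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Apply a missense substitution
#'
#' @param ref_seq reference protein sequence.
#' @param pos 1-based substituted position.
#' @param ref_aa,alt_aa single residues; `ref_aa` must match the reference.
#' @param variantId,gene provenance carried into the result.
#' @return A [MutantProtein-class] with `mutRegion == c(pos, pos)`.
#'   A reference mismatch raises a condition of class
#'   `neoforge_ref_mismatch` carrying the expected/observed residues.
#' @examples
#' applyMissense("MKTAYIAK", 5, "Y", "F")
#' @export
applyMissense <- function(ref_seq, pos, ref_aa, alt_aa,
                          variantId = "", gene = "") {
  L <- nchar(ref_seq)
  if (pos < 1L || pos > L) invalid_variant(sprintf("position %d outside 1..%d", pos, L))
  obs <- substr(ref_seq, pos, pos)
  if (obs != ref_aa) ref_mismatch(pos, ref_aa, obs)
  mut <- paste0(substr(ref_seq, 1, pos - 1), alt_aa,
                substr(ref_seq, pos + 1, L))
  MutantProtein(variantId, gene, "missense", mut, pos, pos)
}

#' Apply an in-frame insertion or deletion
#'
#' For insertions the altered region covers the inserted residues; for
#' deletions it covers the two residues flanking the junction in mutant
#' coordinates (clamped at the termini): the novelty of a deletion is the
#' new adjacency, not any changed residue.
#'
#' @param ref_seq reference protein sequence.
#' @param variant a [VariantRecord-class] of class `inframe_ins` or
#'   `inframe_del`.
#' @return A [MutantProtein-class].
#' @examples
#' v <- VariantRecord("d1", "G", varClass = "inframe_del",
#'                    proteinPos = 4, proteinEnd = 5, refAA = "AY")
#' applyInframeIndel("MKTAYIAK", v)   # MKTIAK, region [3,4]
#' @export
applyInframeIndel <- function(ref_seq, variant) {
  stopifnot(is(variant, "VariantRecord"))
  L <- nchar(ref_seq)
  p <- variant@proteinPos
  vc <- variant@varClass
  if (vc == "inframe_ins") {
    e <- if (is.na(variant@proteinEnd)) p + 1L else variant@proteinEnd
    if (p < 1L || e > L) invalid_variant(sprintf("insertion anchors %d_%d outside 1..%d", p, e, L))
    flanks <- variant@refAA
    if (nchar(flanks) == 2) {
      if (substr(ref_seq, p, p) != substr(flanks, 1, 1))
        ref_mismatch(p, substr(flanks, 1, 1), substr(ref_seq, p, p))
      if (substr(ref_seq, e, e) != substr(flanks, 2, 2))
        ref_mismatch(e, substr(flanks, 2, 2), substr(ref_seq, e, e))
    }
    ins <- variant@altAA
    mut <- paste0(substr(ref_seq, 1, p), ins, substr(ref_seq, p + 1, L))
    MutantProtein(variant@variantId, variant@gene, "inframe_ins", mut,
                  p + 1L, p + nchar(ins))
  } else if (vc == "inframe_del") {
    e <- if (is.na(variant@proteinEnd)) p else variant@proteinEnd
    if (p < 1L || e > L) invalid_variant(sprintf("deletion range %d_%d outside 1..%d", p, e, L))
    if (e - p + 1L >= L) invalid_variant("deletion removes the entire sequence")
    flanks <- variant@refAA
    first <- substr(flanks, 1, 1)
    last <- substr(flanks, nchar(flanks), nchar(flanks))
    if (substr(ref_seq, p, p) != first) ref_mismatch(p, first, substr(ref_seq, p, p))
    if (substr(ref_seq, e, e) != last) ref_mismatch(e, last, substr(ref_seq, e, e))
    mut <- paste0(substr(ref_seq, 1, p - 1), substr(ref_seq, e + 1, L))
    Lm <- nchar(mut)
    a <- max(1L, p - 1L)
    b <- min(Lm, p)
    if (a > b) a <- b
    MutantProtein(variant@variantId, variant@gene, "inframe_del", mut, a, b)
  } else {
    invalid_variant(sprintf("applyInframeIndel cannot handle class '%s'", vc))
  }
}

# Codon-by-codon translation up to the first stop codon. Trailing partial
# codons are ignored; stop reports whether a stop codon terminated it.
#' @noRd
translate_to_stop <- function(nt) {
  n3 <- nchar(nt) - nchar(nt) %% 3L
  if (n3 == 0L) return(list(seq = "", stop = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n3)), no.init.codon = TRUE))
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0) {
    list(seq = substr(aa, 1, star - 1L), stop = TRUE)
  } else {
    list(seq = aa, stop = FALSE)
  }
}

#' Translate a frameshifted coding sequence
#'
#' Applies a frame-disrupting nucleotide edit (parsed from an HGVS-like
#' string such as `"c.6_7insC"` or `"c.10del"`) to the CDS, translates
#' codon-by-codon from the start, and truncates at the first stop codon.
#' `stopFound` records whether a stop was reached; products running off the
#' end of the CDS are kept and flagged rather than discarded. The altered
#' region runs from the first residue that differs from the reference
#' translation through the end of the mutant protein.
#'
#' @param cds coding nucleotide sequence (ATG..stop).
#' @param cdna_change HGVS-like cDNA edit whose indel length is not a
#'   multiple of 3.
#' @param variantId,gene provenance.
#' @return A [MutantProtein-class] with `stopFound` set.
#' @examples
#' translateFrameshift("ATGGCCAAAGAATGGTAA", "c.6_7insC")  # MAQRMV, [3,6]
#' @export
translateFrameshift <- function(cds, cdna_change, variantId = "", gene = "") {
  ed <- parse_cdna_change(cdna_change)
  n <- nchar(cds)
  if (ed$type == "ins") {
    if (ed$start > n) invalid_variant(sprintf("edit offset %d beyond CDS length %d", ed$start, n))
    if (ed$indel_len %% 3L == 0L)
      invalid_variant("indel length divisible by 3: not a frameshift")
    mut_cds <- paste0(substr(cds, 1, ed$start), ed$seq, substr(cds, ed$start + 1, n))
  } else {
    if (ed$end > n) invalid_variant(sprintf("edit end %d beyond CDS length %d", ed$end, n))
    if (ed$indel_len %% 3L == 0L)
      invalid_variant("indel length divisible by 3: not a frameshift")
    if (nzchar(ed$seq)) {
      obs <- substr(cds, ed$start, ed$end)
      if (obs != ed$seq) {
        invalid_variant(sprintf("cDNA deletion mismatch at %d: expected '%s', observed '%s'",
                                ed$start, ed$seq, obs))
      }
    }
    mut_cds <- paste0(substr(cds, 1, ed$start - 1), substr(cds, ed$end + 1, n))
  }
  ref_tr <- translate_to_stop(cds)
  mut_tr <- translate_to_stop(mut_cds)
  if (!nzchar(mut_tr$seq)) invalid_variant("frameshift translation is empty")
  Lm <- nchar(mut_tr$seq)
  Lr <- nchar(ref_tr$seq)
  a <- NA_integer_
  for (i in seq_len(min(Lm, Lr))) {
    if (substr(mut_tr$seq, i, i) != substr(ref_tr$seq, i, i)) { a <- i; break }
  }
  if (is.na(a)) a <- min(Lm, min(Lm, Lr) + 1L)  # pure truncation/extension
  MutantProtein(variantId, gene, "frameshift", mut_tr$seq, a, Lm,
                stopFound = mut_tr$stop)
}

#' Convert a fusion record to a mutant protein
#'
#' The sequence is the translated junction product. For in-frame fusions
#' the altered region is the residue pair spanning the junction; when the
#' 3' partner is out of frame everything from the junction onward is novel.
#'
#' @param fusion a [FusionRecord-class].
#' @return A [MutantProtein-class].
#' @export
fusionToMutant <- function(fusion) {
  stopifnot(is(fusion, "FusionRecord"))
  ji <- fusion@junctionIndex
  L <- nchar(fusion@junctionSeq)
  if (ji < 1L || ji >= L) invalid_variant("junctionIndex out of range")
  b <- if (fusion@frameStatus == "in_frame") ji + 1L else L
  MutantProtein(fusion@fusionId, paste0(fusion@gene5, "::", fusion@gene3),
                "fusion", fusion@junctionSeq, ji, b)
}

#' Build all mutant proteins for a variant set
#'
#' Dispatches each [VariantRecord-class] to the class-appropriate
#' constructor, resolving reference sequences by protein id first and gene
#' symbol second, and frameshift CDS by transcript id. Failures (reference
#' mismatches, missing sequences, invalid edits) are collected, not thrown.
#'
#' @param variants list of [VariantRecord-class].
#' @param proteome a [ReferenceProteome-class].
#' @param cds named CDS vector from [readCDS()] (needed for frameshifts).
#' @param fusions optional list of [FusionRecord-class].
#' @return list with `mutants` (list of [MutantProtein-class]) and
#'   `failures` (data.frame `variant_id`, `reason`).
#' @export
mutantProteins <- function(variants, proteome, cds = NULL, fusions = list()) {
  mutants <- list()
  failures <- data.frame(variant_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  fail <- function(id, reason) {
    failures[nrow(failures) + 1L, ] <<- list(id, reason)
  }
  for (v in variants) {
    ref <- if (!is.na(v@proteinId)) proteomeSeq(proteome, v@proteinId) else NA
    if (is.na(ref)) ref <- proteomeSeq(proteome, v@gene)
    mp <- tryCatch({
      switch(v@varClass,
        missense = {
          if (is.na(ref)) invalid_variant("no reference protein for gene")
          applyMissense(ref, v@proteinPos, v@refAA, v@altAA, v@variantId, v@gene)
        },
        inframe_ins = ,
        inframe_del = {
          if (is.na(ref)) invalid_variant("no reference protein for gene")
          applyInframeIndel(ref, v)
        },
        frameshift = {
          if (is.null(cds) || !(v@transcriptId %in% names(cds)))
            invalid_variant("no CDS for transcript")
          translateFrameshift(cds[[v@transcriptId]], v@cdnaChange,
                              v@variantId, v@gene)
        },
        invalid_variant(sprintf("unhandled class '%s'", v@varClass)))
    }, error = function(e) conditionMessage(e))
    if (is.character(mp)) fail(v@variantId, mp) else mutants[[length(mutants) + 1L]] <- mp
  }
  for (f in fusions) {
    mp <- tryCatch(fusionToMutant(f), error = function(e) conditionMessage(e))
    if (is.character(mp)) fail(f@fusionId, mp) else mutants[[length(mutants) + 1L]] <- mp
  }
  if (nrow(failures) > 0) {
    message(sprintf("mutantProteins: %d variant(s) failed construction", nrow(failures)))
  }
  list(mutants = mutants, failures = failures)
}

#' Assemble the customized proteogenomic search database
#'
#' Writes a single FASTA holding the reference proteome verbatim,
#' contaminant entries prefixed `CON__`, and mutant entries with structured
#' headers `MUT|variant_id|gene|class|region=a-b`. Mutant entries with
#' identical sequences are collapsed to the first provenance; the merges are
#' listed in the manifest. Wild-type entries are kept alongside their mutant
#' counterparts (the search engine needs the wild-type context).
#'
#' @param proteome a [ReferenceProteome-class].
#' @param contaminants path to a cRAP-style FASTA, or a named character
#'   vector of sequences; may be `NULL` for none.
#' @param mutants list of [MutantProtein-class].
#' @param out_fasta output FASTA path (wrapped at 60 columns).
#' @param out_manifest output manifest TSV path (default: alongside FASTA).
#' @return invisibly, the manifest data.frame (columns `category`, `n`,
#'   `note`).
#' @export
buildCustomDB <- function(proteome, contaminants, mutants, out_fasta,
                          out_manifest = paste0(out_fasta, ".manifest.tsv")) {
  if (is.character(contaminants) && length(contaminants) == 1 &&
      file.exists(contaminants)) {
    cont <- toupper(as.character(Biostrings::readAAStringSet(contaminants)))
    names(cont) <- vapply(strsplit(names(Biostrings::readAAStringSet(contaminants)),
                                   "\\s+"), `[`, character(1), 1)
  } else if (is.null(contaminants)) {
    cont <- character(0)
  } else {
    cont <- contaminants
  }
  if (length(mutants) == 0) {
    warning("buildCustomDB: empty mutant set; database is normal + contaminants only",
            call. = FALSE)
  }
  mseqs <- vapply(mutants, function(m) m@sequence, character(1))
  dup <- duplicated(mseqs)
  merged_note <- ""
  if (any(dup)) {
    kept_id <- vapply(mutants[match(mseqs[dup], mseqs)], function(m)
      m@sourceVariant, character(1))
    merged_note <- paste(sprintf("%s->%s",
                                 vapply(mutants[dup], function(m) m@sourceVariant,
                                        character(1)), kept_id),
                         collapse = ";")
  }
  keep <- mutants[!dup]
  headers <- c(names(proteome@sequences),
               paste0("CON__", names(cont)),
               vapply(keep, function(m)
                 sprintf("MUT|%s|%s|%s|region=%d-%d", m@sourceVariant, m@gene,
                         m@varClass, m@mutStart, m@mutEnd), character(1)))
  seqs <- c(unname(proteome@sequences), unname(cont),
            vapply(keep, function(m) m@sequence, character(1)))
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, out_fasta, width = 60L)
  manifest <- data.frame(
    category = c("normal", "contaminant", "mutant", "mutant_merged"),
    n = c(length(proteome@sequences), length(cont), length(keep), sum(dup)),
    note = c("", "", "", merged_note),
    stringsAsFactors = FALSE)
  write_tsv_atomic(manifest, out_manifest)
  invisible(manifest)
}
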