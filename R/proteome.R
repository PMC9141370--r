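# Reference proteome and transcript CDS containers.

#' ReferenceProteome: protein sequences with a gene index
#'
#' @slot sequences named character vector, protein_id -> amino-acid sequence.
#' @slot geneToProtein list, gene symbol -> character vector of protein_ids.
#' @exportClass ReferenceProteome
setClass("ReferenceProteome", representation(
  sequences = "character", geneToProtein = "list"
))

setMethod("show", "ReferenceProteome", function(object) {
  cat(sprintf("ReferenceProteome: %d protein(s), %d gene(s)\n",
              length(object@sequences), length(object@geneToProtein)))
})

#' Read a reference proteome FASTA
#'
#' Headers are expected to carry the protein id as the first word; the gene
#' symbol is taken from a `GN=SYMBOL` tag when present (UniProt convention),
#' otherwise from the second word, otherwise the protein id itself.
#' Sequences are uppercased; non-standard residues (X, U, ...) are tolerated
#' and flagged with a message — downstream window extraction drops windows
#' overlapping them.
#'
#' @param path FASTA file.
#' @return A [ReferenceProteome-class] object.
#' @export
readProteome <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(ss))
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1)
  genes <- character(length(headers))
  gn <- regmatches(headers, regexec("GN=([^ ]+)", headers))
  for (i in seq_along(headers)) {
    if (length(gn[[i]]) == 2) {
      genes[i] <- gn[[i]][2]
    } else {
      words <- strsplit(headers[i], "\\s+")[[1]]
      genes[i] <- if (length(words) >= 2) words[2] else ids[i]
    }
  }
  names(seqs) <- ids
  odd <- has_nonstandard_aa(seqs)
  if (any(odd)) {
    message(sprintf("readProteome: %d sequence(s) contain non-standard residues",
                    sum(odd)))
  }
  g2p <- split(ids, genes)
  new("ReferenceProteome", sequences = seqs, geneToProtein = g2p)
}

#' @rdname readProteome
#' @param x a `ReferenceProteome`.
#' @param id protein id or gene symbol.
#' @return `proteomeSeq()` returns the sequence for a protein id, or the
#'   first sequence of a gene when `id` is a gene symbol; `NA` if unknown.
#' @export
proteomeSeq <- function(x, id) {
  stopifnot(is(x, "ReferenceProteome"))
  if (id %in% names(x@sequences)) return(x@sequences[[id]])
  if (id %in% names(x@geneToProtein)) {
    return(x@sequences[[x@geneToProtein[[id]][1]]])
  }
  NA_character_
}

#' Read transcript coding sequences
#'
#' A FASTA of CDS nucleotide sequences (ATG..stop), keyed by the first word
#' of each header. Lengths not divisible by 3 or sequences not starting with
#' ATG produce warnings but are kept: frameshift translation proceeds
#' codon-by-codon from the start regardless.
#'
#' @param path FASTA file.
#' @return named character vector transcript_id -> CDS.
#' @export
readCDS <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  if (any(nchar(seqs) %% 3 != 0)) {
    warning(sprintf("readCDS: %d CDS length(s) not divisible by 3",
                    sum(nchar(seqs) %% 3 != 0)), call. = FALSE)
  }
  if (any(substr(seqs, 1, 3) != "ATG")) {
    warning(sprintf("readCDS: %d CDS do not start with ATG",
                    sum(substr(seqs, 1, 3) != "ATG")), call. = FALSE)
  }
  seqs
}
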