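# Peptide similarity against the curated neoantigen database.
#
# The similarity of a candidate to a database peptide is defined as
#   100 * (positive-scoring aligned pairs) / (query length)
# under the best BLOSUM62 local alignment with gap open 11 / extend 1
# (protein-BLAST defaults). An identical peptide scores exactly 100 (every
# BLOSUM62 diagonal entry is positive) and the value is bounded on [0, 100].
# Among co-optimal alignments the one with the most positive pairs defines
# the value, so it is independent of traceback order.

#' @noRd
.blosum62_env <- new.env(parent = emptyenv())

#' @noRd
get_blosum62 <- function() {
  if (is.null(.blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA_STANDARD, AA_STANDARD]
    storage.mode(m) <- "integer"
    .blosum62_env$mat <- m
  }
  .blosum62_env$mat
}

#' @noRd
encode_peptide <- function(x) {
  idx <- match(strsplit(x, "")[[1]], AA_STANDARD)
  if (anyNA(idx)) {
    stop(sprintf("peptide '%s' contains non-standard residues", x), call. = FALSE)
  }
  idx - 1L
}

#' Score one peptide pair
#'
#' Low-level entry point around the alignment kernel; [similaritySearch()]
#' is the user-facing operation.
#'
#' @param query,subject peptide strings (standard residues only).
#' @param gap_open,gap_ext affine gap penalties (defaults 11 / 1).
#' @return list with `score` (raw alignment score), `positives`,
#'   `similarity` (0-100) and the 1-based aligned spans `q_start`, `q_end`,
#'   `s_start`, `s_end` (all 0 when no positive-scoring alignment exists).
#' @export
alignSimilarity <- function(query, subject, gap_open = 11L, gap_ext = 1L) {
  q <- encode_peptide(toupper(query))
  s <- encode_peptide(toupper(subject))
  res <- .sw_align(q, s, get_blosum62(), as.integer(gap_open), as.integer(gap_ext))
  res$similarity <- 100 * res$positives / length(q)
  res
}

#' Search a peptide against the neoantigen database
#'
#' Aligns the query locally against every database peptide and reports one
#' similarity hit per entry, sorted by similarity (descending, score as
#' tie-break).
#'
#' @param query peptide string; non-standard residues are an error.
#' @param db data.frame from [loadNeoDB()] (columns `peptide`, `tier`).
#' @param gap_open,gap_ext affine gap penalties.
#' @return data.frame `subject`, `tier`, `score`, `positives`, `similarity`,
#'   `q_start`, `q_end`, `s_start`, `s_end`.
#' @examples
#' db <- data.frame(peptide = c("KTAFIAKLQ", "WWWWWWWWW"),
#'                  tier = c("high", "medium"))
#' similaritySearch("KTAFIAKLQ", db)[1, "similarity"]   # 100
#' @export
similaritySearch <- function(query, db, gap_open = 11L, gap_ext = 1L) {
  if (nrow(db) == 0) stop("neoantigen database is empty", call. = FALSE)
  q <- encode_peptide(toupper(query))
  mat <- get_blosum62()
  hits <- lapply(seq_len(nrow(db)), function(i) {
    s <- encode_peptide(db$peptide[i])
    r <- .sw_align(q, s, mat, as.integer(gap_open), as.integer(gap_ext))
    data.frame(subject = db$peptide[i], tier = db$tier[i], score = r$score,
               positives = r$positives,
               similarity = 100 * r$positives / length(q),
               q_start = r$q_start, q_end = r$q_end,
               s_start = r$s_start, s_end = r$s_end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  out <- out[order(-out$similarity, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
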