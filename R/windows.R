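# Mutation-anchored k-mer window extraction.
#
# For an altered region [a, b] on a mutant protein of length L and a window
# length k, valid starts are s in [max(1, a-k+1), min(b, L-k+1)]: exactly the
# substrings of length k whose interval [s, s+k-1] intersects [a, b]. The
# stride is fixed at 1.

#' Extract mutation-containing peptide windows
#'
#' Enumerates, for each window length `k` in `[k_min, k_max]`, every
#' substring of the mutant protein that covers at least one altered-region
#' residue. MHC class I uses 8-11-mers, class II 15-30-mers. Windows
#' containing non-standard residues (X, U, ...) are dropped and counted;
#' duplicate (sequence, k) pairs within one variant are collapsed to the
#' first (leftmost) start.
#'
#' @param mutant a [MutantProtein-class].
#' @param k_min,k_max inclusive window length range. Defaults follow
#'   `mhc_class`: 8-11 for `"I"`, 15-30 for `"II"`.
#' @param mhc_class `"I"` or `"II"`.
#' @return data.frame with columns `peptide`, `k`, `start` (1-based in the
#'   mutant protein), `mut_positions` (comma-joined window-relative 1-based
#'   positions falling in the altered region), `variant_id`, `gene`,
#'   `var_class`, `mhc_class`. Attribute `n_dropped_nonstandard` counts
#'   windows removed for non-standard residues. A protein shorter than
#'   `k_min` yields an empty table, not an error.
#' @examples
#' mp <- applyMissense(strrep("A", 30), 15, "A", "W", "v1", "G1")
#' nrow(extractWindows(mp, mhc_class = "I"))   # 38 windows
#' @export
extractWindows <- function(mutant, k_min = NULL, k_max = NULL,
                           mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  if (is.null(k_min)) k_min <- if (mhc_class == "I") 8L else 15L
  if (is.null(k_max)) k_max <- if (mhc_class == "I") 11L else 30L
  stopifnot(k_min <= k_max, k_min >= 1L)
  sq <- mutant@sequence
  L <- nchar(sq)
  a <- mutant@mutStart
  b <- mutant@mutEnd
  out <- empty_candidate_table()
  dropped <- 0L
  if (L < k_min) return(`attr<-`(out, "n_dropped_nonstandard", 0L))
  rows <- vector("list", 0)
  for (k in seq(k_min, min(k_max, L))) {
    s_lo <- max(1L, a - k + 1L)
    s_hi <- min(b, L - k + 1L)
    if (s_lo > s_hi) next
    starts <- seq.int(s_lo, s_hi)
    peps <- substring(sq, starts, starts + k - 1L)
    bad <- has_nonstandard_aa(peps)
    dropped <- dropped + sum(bad)
    starts <- starts[!bad]
    peps <- peps[!bad]
    if (length(starts) == 0) next
    mut_pos <- lapply(starts, function(s) {
      p <- seq.int(max(a, s), min(b, s + k - 1L)) - s + 1L
      p
    })
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = peps, k = as.integer(k), start = as.integer(starts),
      mut_positions = encode_positions(mut_pos),
      variant_id = mutant@sourceVariant, gene = mutant@gene,
      var_class = mutant@varClass, mhc_class = mhc_class,
      stringsAsFactors = FALSE)
  }
  if (length(rows) > 0) {
    out <- do.call(rbind, rows)
    # per-variant dedup on (peptide, k); substring() emits leftmost first
    out <- out[!duplicated(out[, c("peptide", "k")]), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_dropped_nonstandard") <- dropped
  out
}

#' Extract windows for many mutants
#'
#' Convenience wrapper binding [extractWindows()] output over a list of
#' mutants. Cross-variant duplicate peptides are kept (provenance matters
#' until report-level deduplication).
#'
#' @param mutants list of [MutantProtein-class].
#' @inheritParams extractWindows
#' @return combined candidate data.frame.
#' @export
extractAllWindows <- function(mutants, k_min = NULL, k_max = NULL,
                              mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  tabs <- lapply(mutants, extractWindows, k_min = k_min, k_max = k_max,
                 mhc_class = mhc_class)
  out <- do.call(rbind, c(list(empty_candidate_table()), tabs))
  rownames(out) <- NULL
  out
}

#' Remove candidate windows present in the reference proteome
#'
#' Deletion-junction and fusion windows can coincide with reference
#' substrings even though they cover the altered region; with `enabled =
#' TRUE` any candidate whose sequence occurs verbatim anywhere in the
#' reference proteome is removed.
#'
#' @param candidates candidate data.frame from [extractWindows()].
#' @param proteome a [ReferenceProteome-class].
#' @param enabled flag; `FALSE` returns the input unchanged.
#' @return filtered data.frame; attribute `n_removed_wildtype` counts
#'   removals.
#' @export
dropWildtypeWindows <- function(candidates, proteome, enabled = TRUE) {
  if (!enabled || nrow(candidates) == 0) {
    attr(candidates, "n_removed_wildtype") <- 0L
    return(candidates)
  }
  subject <- Biostrings::AAStringSet(unname(proteome@sequences))
  hit <- vapply(unique(candidates$peptide), function(p) {
    sum(Biostrings::vcountPattern(p, subject)) > 0
  }, logical(1))
  in_ref <- hit[candidates$peptide]
  out <- candidates[!in_ref, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed_wildtype") <- sum(in_ref)
  out
}

#' Write candidate peptides as FASTA
#'
#' Headers are `variant_id|k|start`, one record per candidate row; this is
#' the file an external binding predictor would consume.
#'
#' @param candidates candidate data.frame.
#' @param path output FASTA.
#' @return the path, invisibly.
#' @export
writePeptideFasta <- function(candidates, path) {
  ss <- Biostrings::AAStringSet(candidates$peptide)
  names(ss) <- sprintf("%s|%d|%d", candidates$variant_id, candidates$k,
                       candidates$start)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
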