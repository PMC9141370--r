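# The four-stage candidate-neoantigen filter cascade:
#   (a) transcript expression, (b) MS evidence, and then, in parallel,
#   (c) similarity to the curated neoantigen database and (d) the strict
#   affinity/abundance screen (class I only).

#' @noRd
abs_mut_positions <- function(candidates) {
  rel <- decode_positions(candidates$mut_positions)
  Map(function(s, r) s + r - 1L, candidates$start, rel)
}

#' Expression filter
#'
#' Removes candidates whose source variant maps to an unexpressed
#' transcript. TPM is looked up by transcript id first, then by gene
#' symbol; fusion candidates (gene recorded as `G5::G3`) use the maximum
#' over the two partner genes. Variants absent from the table are treated
#' as unexpressed and counted separately. Survivors carry their TPM.
#'
#' @param candidates candidate data.frame.
#' @param expression named TPM vector from [parseExpression()].
#' @param variants list of [VariantRecord-class] used for the
#'   variant -> transcript mapping (optional; gene lookup still works
#'   without it).
#' @param config a [FilterConfig-class]; candidates kept iff
#'   `TPM > tpmMinExclusive`.
#' @return surviving rows with a `tpm` column; attributes
#'   `n_removed_unexpressed` and `n_removed_no_data`.
#' @export
filterExpression <- function(candidates, expression, variants = list(),
                             config = FilterConfig()) {
  if (nrow(candidates) == 0) {
    candidates$tpm <- numeric(0)
    attr(candidates, "n_removed_unexpressed") <- 0L
    attr(candidates, "n_removed_no_data") <- 0L
    return(candidates)
  }
  tx_of <- vapply(variants, function(v) v@transcriptId, character(1))
  names(tx_of) <- vapply(variants, function(v) v@variantId, character(1))
  lookup <- function(variant_id, gene) {
    tx <- tx_of[variant_id]
    if (!is.na(tx) && tx %in% names(expression)) return(expression[[tx]])
    if (grepl("::", gene, fixed = TRUE)) {
      parts <- strsplit(gene, "::", fixed = TRUE)[[1]]
      vals <- expression[parts[parts %in% names(expression)]]
      return(if (length(vals)) max(vals) else NA_real_)
    }
    if (gene %in% names(expression)) return(expression[[gene]])
    NA_real_
  }
  key <- paste(candidates$variant_id, candidates$gene, sep = "\r")
  uk <- !duplicated(key)
  tpm_by_key <- vapply(which(uk), function(i)
    lookup(candidates$variant_id[i], candidates$gene[i]), numeric(1))
  names(tpm_by_key) <- key[uk]
  tpm <- unname(tpm_by_key[key])
  no_data <- is.na(tpm)
  keep <- !no_data & tpm > config@tpmMinExclusive
  out <- candidates[keep, , drop = FALSE]
  out$tpm <- tpm[keep]
  rownames(out) <- NULL
  attr(out, "n_removed_unexpressed") <- sum(!keep & !no_data)
  attr(out, "n_removed_no_data") <- sum(no_data)
  out
}

#' MS-evidence filter
#'
#' A candidate survives iff some identified peptide P supports it:
#' the candidate is a substring of P, or P is a substring of the candidate,
#' or P and the candidate overlap by at least `msMinOverlap` residues when
#' both are located on the same mutant protein — and in every case the
#' shared residues must include at least one altered-region position.
#' Survivors record their supporting peptide(s).
#'
#' @param candidates candidate data.frame.
#' @param ms character vector of identified peptides
#'   ([parseMSEvidence()]).
#' @param mutants list of [MutantProtein-class] (needed for the co-located
#'   overlap clause; optional).
#' @param config a [FilterConfig-class].
#' @return surviving rows with an `ms_support` column (comma-joined
#'   supporting peptides).
#' @export
filterMS <- function(candidates, ms, mutants = list(), config = FilterConfig()) {
  if (nrow(candidates) == 0) {
    candidates$ms_support <- character(0)
    return(candidates)
  }
  mut_seq <- vapply(mutants, function(m) m@sequence, character(1))
  names(mut_seq) <- vapply(mutants, function(m) m@sourceVariant, character(1))
  min_ov <- config@msMinOverlap
  abs_pos <- abs_mut_positions(candidates)
  rel_pos <- decode_positions(candidates$mut_positions)

  support <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates$peptide[i]
    kc <- nchar(cand)
    c_start <- candidates$start[i]
    c_end <- c_start + kc - 1L
    sup <- character(0)
    for (P in ms) {
      ok <- FALSE
      if (nchar(P) >= kc && grepl(cand, P, fixed = TRUE)) {
        # candidate inside P: shared residues = whole candidate, which by
        # construction covers an altered position
        ok <- TRUE
      } else if (nchar(P) < kc) {
        occ <- gregexpr(P, cand, fixed = TRUE)[[1]]
        if (occ[1] != -1) {
          for (o in occ) {
            shared <- seq.int(o, o + nchar(P) - 1L)
            if (any(rel_pos[[i]] %in% shared)) { ok <- TRUE; break }
          }
        }
      }
      if (!ok && candidates$variant_id[i] %in% names(mut_seq)) {
        mseq <- mut_seq[[candidates$variant_id[i]]]
        occ <- gregexpr(P, mseq, fixed = TRUE)[[1]]
        if (occ[1] != -1) {
          for (o in occ) {
            p_end <- o + nchar(P) - 1L
            ov_lo <- max(o, c_start)
            ov_hi <- min(p_end, c_end)
            if (ov_hi - ov_lo + 1L >= min_ov &&
                any(abs_pos[[i]] >= ov_lo & abs_pos[[i]] <= ov_hi)) {
              ok <- TRUE
              break
            }
          }
        }
      }
      if (ok) sup <- c(sup, P)
    }
    support[[i]] <- sup
  }
  keep <- lengths(support) > 0
  out <- candidates[keep, , drop = FALSE]
  out$ms_support <- vapply(support[keep], paste, character(1), collapse = ",")
  rownames(out) <- NULL
  out
}

#' Neoantigen-database similarity filter
#'
#' Scores every unique candidate peptide against the curated database
#' ([similaritySearch()]) and counts a candidate as matched when its best
#' similarity falls inside `[simThresholdLow, simThresholdHigh]`. The
#' matching ratio is the percentage of compared peptides that matched
#' (2 decimals); an empty candidate set gives `NA`, not 0.
#'
#' @param candidates candidate data.frame.
#' @param db neoantigen database ([loadNeoDB()]); both confidence tiers are
#'   searched and the best hit's tier is recorded.
#' @param config a [FilterConfig-class].
#' @return list with `candidates` (matched rows, plus `best_similarity`,
#'   `best_subject`, `best_tier`), `matching_ratio` (percentage), and
#'   `per_peptide` (one row per compared peptide).
#' @export
filterNeoDB <- function(candidates, db, config = FilterConfig()) {
  if (nrow(candidates) == 0) {
    return(list(candidates = candidates, matching_ratio = NA_real_,
                per_peptide = data.frame(peptide = character(0),
                                         best_similarity = numeric(0),
                                         best_subject = character(0),
                                         best_tier = character(0),
                                         matched = logical(0))))
  }
  peps <- unique(candidates$peptide)
  per <- do.call(rbind, lapply(peps, function(p) {
    hits <- similaritySearch(p, db)
    data.frame(peptide = p, best_similarity = hits$similarity[1],
               best_subject = hits$subject[1], best_tier = hits$tier[1],
               stringsAsFactors = FALSE)
  }))
  per$matched <- per$best_similarity >= config@simThresholdLow &
    per$best_similarity <= config@simThresholdHigh
  ratio <- matchingRatio(sum(per$matched), nrow(per))
  idx <- match(candidates$peptide, per$peptide)
  out <- candidates
  out$best_similarity <- per$best_similarity[idx]
  out$best_subject <- per$best_subject[idx]
  out$best_tier <- per$best_tier[idx]
  out <- out[per$matched[idx], , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out, matching_ratio = ratio, per_peptide = per)
}

#' Strict affinity/abundance filter (class I)
#'
#' Keeps candidates with predicted `IC50 <= strictIc50MaxNM` (34 nM by
#' default) and transcript abundance `TPM >= strictTpmMin` (33 by default),
#' both boundaries inclusive. The screen is defined for HLA class I
#' restricted candidates only; class II rows are skipped with a warning.
#'
#' @param candidates candidate data.frame carrying `ic50_nM` and `tpm`.
#' @param config a [FilterConfig-class].
#' @return surviving class I rows.
#' @export
filterStrict <- function(candidates, config = FilterConfig()) {
  if (nrow(candidates) == 0) return(candidates)
  if (!all(c("ic50_nM", "tpm") %in% colnames(candidates))) {
    stop("filterStrict needs ic50_nM and tpm columns (run binder selection and the expression filter first)",
         call. = FALSE)
  }
  is2 <- candidates$mhc_class == "II"
  if (any(is2)) {
    warning(sprintf("filterStrict: skipping %d class II candidate(s); the strict screen is class I only",
                    sum(is2)), call. = FALSE)
    candidates <- candidates[!is2, , drop = FALSE]
  }
  keep <- candidates$ic50_nM <= config@strictIc50MaxNM &
    candidates$tpm >= config@strictTpmMin
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full filter cascade
#'
#' Binder selection by %Rank, then expression, then MS evidence, then the
#' two terminal screens (database similarity and the strict class-I
#' thresholds) applied in parallel to the MS survivors. Matching ratios are
#' computed for the MS survivors, the strict survivors and the unfiltered
#' binder set.
#'
#' @param candidates candidate data.frame ([extractAllWindows()]).
#' @param binding binding data.frame.
#' @param expression named TPM vector.
#' @param ms identified-peptide vector.
#' @param mutants list of [MutantProtein-class].
#' @param variants list of [VariantRecord-class].
#' @param neodb neoantigen database data.frame (or `NULL` to skip).
#' @param config a [FilterConfig-class].
#' @return list of stage outputs: `binders`, `expressed`, `ms_supported`,
#'   `db_matched`, `strict`, `matching_ratios` (named numeric), and
#'   `summary` (data.frame stage/in/out).
#' @export
runCascade <- function(candidates, binding, expression, ms, mutants,
                       variants = list(), neodb = NULL,
                       config = FilterConfig()) {
  summary_rows <- list()
  note <- function(stage, n_in, n_out) {
    summary_rows[[length(summary_rows) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_out = n_out,
                 stringsAsFactors = FALSE)
  }
  binders <- selectBinders(candidates, binding)
  note("binder_selection", nrow(candidates), nrow(binders))

  expressed <- if (config@doExpression) {
    filterExpression(binders, expression, variants, config)
  } else {
    b <- binders
    b$tpm <- NA_real_
    b
  }
  note("expression", nrow(binders), nrow(expressed))

  ms_supported <- if (config@doMS) filterMS(expressed, ms, mutants, config)
                  else expressed
  note("ms_evidence", nrow(expressed), nrow(ms_supported))

  ratios <- c()
  db_matched <- ms_supported[0, , drop = FALSE]
  db_per_peptide <- NULL
  if (config@doNeoDB && !is.null(neodb)) {
    res <- filterNeoDB(ms_supported, neodb, config)
    db_matched <- res$candidates
    db_per_peptide <- res$per_peptide
    ratios["ms_filtered"] <- res$matching_ratio
  }
  note("db_similarity", nrow(ms_supported), nrow(db_matched))

  strict <- if (config@doStrict) {
    filterStrict(ms_supported[ms_supported$mhc_class == "I", , drop = FALSE],
                 config)
  } else {
    ms_supported[0, , drop = FALSE]
  }
  note("strict_thresholds", sum(ms_supported$mhc_class == "I"), nrow(strict))
  if (config@doNeoDB && !is.null(neodb) && nrow(strict) > 0) {
    res_s <- filterNeoDB(strict, neodb, config)
    ratios["strict_filtered"] <- res_s$matching_ratio
  }
  if (config@doNeoDB && !is.null(neodb) && nrow(binders) > 0) {
    res_u <- filterNeoDB(binders[binders$mhc_class == "I", , drop = FALSE],
                         neodb, config)
    ratios["unfiltered"] <- res_u$matching_ratio
  }
  list(binders = binders, expressed = expressed, ms_supported = ms_supported,
       db_matched = db_matched, db_per_peptide = db_per_peptide,
       strict = strict, matching_ratios = ratios,
       summary = do.call(rbind, summary_rows))
}
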