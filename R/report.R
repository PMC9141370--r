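# Aggregation, matching-ratio / version-comparison arithmetic, and result
# file output.

#' Matching ratio
#'
#' Percentage of compared candidate peptides with a similarity hit in the
#' curated neoantigen database, rounded to 2 decimals. An empty comparison
#' is undefined and returns `NA`, not 0.
#'
#' @param matched number matched.
#' @param compared number compared.
#' @return percentage (2 decimals) or `NA_real_`.
#' @examples
#' matchingRatio(122, 636)   # 19.18
#' matchingRatio(4, 19)      # 21.05
#' @export
matchingRatio <- function(matched, compared) {
  if (is.na(compared) || compared == 0) return(NA_real_)
  if (matched < 0 || matched > compared) {
    stop("matched must lie in [0, compared]", call. = FALSE)
  }
  round(100 * matched / compared, 2)
}

#' Percent increase between two counts
#'
#' @param old_count baseline count (> 0; 0 gives `NA`).
#' @param new_count new count.
#' @return `100 * (new - old) / old`, rounded to 1 decimal.
#' @examples
#' percentIncrease(36835, 52514)   # 42.6
#' @export
percentIncrease <- function(old_count, new_count) {
  if (is.na(old_count) || old_count == 0) return(NA_real_)
  round(100 * (new_count - old_count) / old_count, 1)
}

#' Aggregate cascade outputs into a FilterReport
#'
#' Counts candidates per stage, mutation class and MHC class, candidates
#' per allele (unique peptides per allele, since one peptide can bind
#' several alleles), and strong/weak binder totals. Internal sum identities
#' (per-class counts adding up to each stage total; strong + weak equalling
#' the selected-binder total) hold by construction and are asserted.
#'
#' @param stages named list of candidate data.frames (e.g. the stage
#'   outputs of [runCascade()]).
#' @param matchingRatios named numeric vector of matching ratios.
#' @return A [FilterReport-class].
#' @export
aggregateReport <- function(stages, matchingRatios = numeric(0)) {
  counts <- do.call(rbind, lapply(names(stages), function(nm) {
    df <- stages[[nm]]
    if (nrow(df) == 0) {
      return(data.frame(stage = character(0), var_class = character(0),
                        mhc_class = character(0), n = integer(0)))
    }
    agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                            by = list(var_class = df$var_class,
                                      mhc_class = df$mhc_class), FUN = sum)
    data.frame(stage = nm, agg, stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  for (nm in names(stages)) {
    stopifnot(sum(counts$n[counts$stage == nm]) == nrow(stages[[nm]]))
  }
  binder_stage <- if ("binders" %in% names(stages)) stages[["binders"]] else NULL
  per_allele <- integer(0)
  strong_weak <- data.frame(mhc_class = character(0), category = character(0),
                            n = integer(0), stringsAsFactors = FALSE)
  if (!is.null(binder_stage) && nrow(binder_stage) > 0 &&
      "allele" %in% colnames(binder_stage)) {
    pa <- tapply(binder_stage$peptide, binder_stage$allele,
                 function(p) length(unique(p)))
    per_allele <- as.integer(pa)
    names(per_allele) <- names(pa)
    sw <- stats::aggregate(list(n = rep(1L, nrow(binder_stage))),
                           by = list(mhc_class = binder_stage$mhc_class,
                                     category = binder_stage$category),
                           FUN = sum)
    strong_weak <- sw
    for (mc in unique(strong_weak$mhc_class)) {
      stopifnot(sum(strong_weak$n[strong_weak$mhc_class == mc]) ==
                  sum(binder_stage$mhc_class == mc))
    }
  }
  new("FilterReport", counts = counts, perAllele = per_allele,
      matchingRatios = matchingRatios, strongWeak = strong_weak)
}

#' Write per-mutation-class result files
#'
#' One TSV per mutation class present (plus header-only files for classes
#' with no survivors when `all_classes = TRUE`), and a `summary.tsv` with
#' per-class counts. Files are written atomically (write-then-rename), so
#' reruns into the same directory replace files without ever exposing a
#' partial write.
#'
#' @param candidates final annotated candidate data.frame.
#' @param out_dir output directory (created if needed).
#' @param all_classes also write header-only files for absent classes.
#' @return invisibly, the vector of files written.
#' @export
writeResults <- function(candidates, out_dir, all_classes = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- if (all_classes) VAR_CLASSES else unique(candidates$var_class)
  files <- character(0)
  for (cl in classes) {
    df <- candidates[candidates$var_class == cl, , drop = FALSE]
    path <- file.path(out_dir, paste0(cl, ".tsv"))
    write_tsv_atomic(df, path)
    files <- c(files, path)
  }
  summary <- data.frame(var_class = classes,
                        n = vapply(classes, function(cl)
                          sum(candidates$var_class == cl), integer(1)),
                        stringsAsFactors = FALSE)
  spath <- file.path(out_dir, "summary.tsv")
  write_tsv_atomic(summary, spath)
  invisible(c(files, spath))
}

#' Re-read per-class result files
#'
#' Inverse of [writeResults()]: binds the per-mutation-class TSVs back into
#' one candidate table (numeric columns restored), so a report regenerated
#' from disk equals the report of the table that was written.
#'
#' @param out_dir directory written by [writeResults()].
#' @return combined candidate data.frame.
#' @export
readResults <- function(out_dir) {
  files <- file.path(out_dir, paste0(VAR_CLASSES, ".tsv"))
  files <- files[file.exists(files)]
  tabs <- lapply(files, function(f) {
    df <- utils::read.delim(f, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character", na.strings = "NA")
    df
  })
  tabs <- tabs[vapply(tabs, nrow, integer(1)) > 0]
  if (length(tabs) == 0) return(empty_candidate_table())
  out <- do.call(rbind, tabs)
  for (col in intersect(c("k", "start"), colnames(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in intersect(c("ic50_nM", "rank_pct", "tpm", "best_similarity"),
                        colnames(out))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  rownames(out) <- NULL
  out
}
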