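# Peptide-HLA binding records: %Rank classification, affinity table
# parsing, allele-name normalization, and a deterministic mock predictor.

#' Classify a binder from its percentile rank
#'
#' Class I: strong when `%Rank <= 0.5`, weak when `0.5 < %Rank <= 2`,
#' otherwise non-binder. Class II: strong when `%Rank <= 2`, weak when
#' `2 < %Rank <= 10`, otherwise non-binder. All boundaries inclusive.
#'
#' @param mhc_class `"I"` or `"II"` (recycled against `rank_pct`).
#' @param rank_pct positive percentile rank(s).
#' @return character vector: `"strong"`, `"weak"` or `"non"`.
#' @examples
#' classifyBinder("I", c(0.5, 2, 2.01))   # strong weak non
#' classifyBinder("II", c(2, 10, 10.5))   # strong weak non
#' @export
classifyBinder <- function(mhc_class, rank_pct) {
  if (any(is.na(rank_pct)) || any(rank_pct <= 0)) {
    stop("rank_pct must be positive", call. = FALSE)
  }
  n <- max(length(mhc_class), length(rank_pct))
  mhc_class <- rep_len(mhc_class, n)
  rank_pct <- rep_len(rank_pct, n)
  if (!all(mhc_class %in% c("I", "II"))) {
    stop("mhc_class must be 'I' or 'II'", call. = FALSE)
  }
  strong_max <- ifelse(mhc_class == "I", 0.5, 2)
  weak_max <- ifelse(mhc_class == "I", 2, 10)
  ifelse(rank_pct <= strong_max, "strong",
         ifelse(rank_pct <= weak_max, "weak", "non"))
}

#' Normalize an HLA allele name
#'
#' Accepts the notation mixtures that typing tools and binding predictors
#' emit and maps them to one canonical form:
#' `"HLA-A*03:01"`, `"HLA-A03:01"`, `"HLA-A_03_01"` all become
#' `"HLA-A*03:01"`; class II `"DRB4_0103"` becomes `"DRB4*01:03"`.
#' Names already canonical pass through; unrecognized names are returned
#' verbatim (NetMHCIIpan heterodimer names are accepted as-is).
#'
#' @param allele character vector of allele names.
#' @return normalized character vector.
#' @export
normalizeAllele <- function(allele) {
  vapply(allele, function(x) {
    x <- trimws(x)
    # DRB4_0103 -> DRB4*01:03
    m <- regmatches(x, regexec("^([A-Z]+[0-9]*)_([0-9]{2})([0-9]{2})$", x))[[1]]
    if (length(m) == 4) return(sprintf("%s*%s:%s", m[2], m[3], m[4]))
    # HLA-A_03_01 -> HLA-A*03:01
    m <- regmatches(x, regexec("^(HLA-[A-Z]+[0-9]*)_([0-9]+)_([0-9]+)$", x))[[1]]
    if (length(m) == 4) return(sprintf("%s*%s:%s", m[2], m[3], m[4]))
    # HLA-A03:01 -> HLA-A*03:01
    m <- regmatches(x, regexec("^(HLA-[A-Z]+)([0-9]+:[0-9]+)$", x))[[1]]
    if (length(m) == 3) return(sprintf("%s*%s", m[2], m[3]))
    # HLA-A*0301 -> HLA-A*03:01
    m <- regmatches(x, regexec("^(HLA-[A-Z]+[0-9]*\\*)([0-9]{2})([0-9]{2})$", x))[[1]]
    if (length(m) == 4) return(sprintf("%s%s:%s", m[2], m[3], m[4]))
    x
  }, character(1), USE.NAMES = FALSE)
}

#' @noRd
infer_mhc_class <- function(allele) {
  bare <- sub("^HLA-", "", allele)
  ifelse(grepl("^D", bare), "II", "I")
}

#' Parse a peptide-HLA affinity table
#'
#' Two dialects:
#' * `"generic_long"`: TSV with header columns `peptide`, `allele`,
#'   `mhc_class`, `ic50_nM`, `rank_pct` — one row per peptide x allele.
#' * `"netmhcpan_xls"`: the predictor's `-xls` tab layout — first line
#'   carries allele names over column blocks, second line the per-block
#'   `nM` / `Rank` headers, then one row per peptide.
#'
#' The strong/weak/non category is computed on ingest from the percentile
#' rank. Rows whose numeric fields do not parse are rejected and counted;
#' a missing rank column is fatal. When `candidates` is given, peptides not
#' among them are retained but flagged `known = FALSE`.
#'
#' @param path input file.
#' @param dialect `"generic_long"` or `"netmhcpan_xls"`.
#' @param mhc_class for `netmhcpan_xls` (which does not state it): `"I"`,
#'   `"II"`, or `NULL` to infer from the allele names.
#' @param candidates optional candidate data.frame used to flag foreign
#'   peptides.
#' @return data.frame `peptide`, `allele`, `mhc_class`, `ic50_nM`,
#'   `rank_pct`, `category` (+ `known`); attribute `n_rejected`.
#' @export
parseBindingTable <- function(path, dialect = c("generic_long", "netmhcpan_xls"),
                              mhc_class = NULL, candidates = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "generic_long") {
    df <- read_tsv_checked(path, required = c("peptide", "allele", "mhc_class",
                                              "ic50_nM", "rank_pct"),
                           what = "binding table")
    ic50 <- suppressWarnings(as.numeric(df$ic50_nM))
    rank <- suppressWarnings(as.numeric(df$rank_pct))
    ok <- !is.na(ic50) & !is.na(rank) & rank > 0 & ic50 > 0 &
      df$mhc_class %in% c("I", "II")
    n_rej <- sum(!ok)
    out <- data.frame(peptide = toupper(df$peptide[ok]),
                      allele = normalizeAllele(df$allele[ok]),
                      mhc_class = df$mhc_class[ok],
                      ic50_nM = ic50[ok], rank_pct = rank[ok],
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    if (length(lines) < 2) stop("netmhcpan_xls file too short", call. = FALSE)
    head1 <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    head2 <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
    allele_at <- which(nzchar(trimws(head1)))
    if (length(allele_at) == 0) stop("no allele names in header", call. = FALSE)
    pep_col <- which(head2 == "Peptide")[1]
    if (is.na(pep_col)) stop("no Peptide column", call. = FALSE)
    blocks <- lapply(seq_along(allele_at), function(i) {
      from <- allele_at[i]
      to <- if (i < length(allele_at)) allele_at[i + 1] - 1L else length(head2)
      nm_col <- from - 1L + which(head2[from:to] == "nM")[1]
      rk_col <- from - 1L + which(head2[from:to] == "Rank")[1]
      if (is.na(rk_col)) stop(sprintf("allele block '%s' lacks a Rank column",
                                      head1[from]), call. = FALSE)
      list(allele = trimws(head1[from]), nm = nm_col, rank = rk_col)
    })
    rows <- lapply(lines[-(1:2)], function(ln) strsplit(ln, "\t", fixed = TRUE)[[1]])
    rows <- rows[vapply(rows, length, integer(1)) >= pep_col]
    n_rej <- 0L
    recs <- list()
    for (r in rows) {
      pep <- toupper(r[pep_col])
      for (b in blocks) {
        rk <- suppressWarnings(as.numeric(r[b$rank]))
        nm <- if (!is.na(b$nm)) suppressWarnings(as.numeric(r[b$nm])) else NA_real_
        if (is.na(rk) || rk <= 0) { n_rej <- n_rej + 1L; next }
        recs[[length(recs) + 1L]] <- data.frame(
          peptide = pep, allele = normalizeAllele(b$allele),
          ic50_nM = nm, rank_pct = rk, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, c(list(data.frame(peptide = character(0),
                                            allele = character(0),
                                            ic50_nM = numeric(0),
                                            rank_pct = numeric(0))), recs))
    out$mhc_class <- if (is.null(mhc_class)) infer_mhc_class(out$allele)
                     else rep_len(mhc_class, nrow(out))
    out <- out[, c("peptide", "allele", "mhc_class", "ic50_nM", "rank_pct")]
  }
  if (n_rej > 0) message(sprintf("parseBindingTable: rejected %d row(s)", n_rej))
  out$category <- if (nrow(out)) classifyBinder(out$mhc_class, out$rank_pct)
                  else character(0)
  if (!is.null(candidates)) {
    out$known <- out$peptide %in% candidates$peptide
    if (any(!out$known)) {
      message(sprintf("parseBindingTable: %d record(s) for peptides outside the candidate set",
                      sum(!out$known)))
    }
  }
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write a binding table in the generic_long dialect
#'
#' Numeric fields are written with full precision so that
#' parse -> write -> parse is lossless.
#'
#' @param binding binding data.frame.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
writeBindingTable <- function(binding, path) {
  df <- data.frame(peptide = binding$peptide, allele = binding$allele,
                   mhc_class = binding$mhc_class,
                   ic50_nM = sprintf("%.17g", binding$ic50_nM),
                   rank_pct = sprintf("%.17g", binding$rank_pct),
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' Deterministic mock binding predictor
#'
#' An offline stand-in for an external peptide-HLA binding predictor, used
#' by the test fixtures. Percentile ranks are drawn approximately uniformly
#' on (0, 100] and IC50 log-uniformly on (1, 50000] nM from a seeded
#' polynomial hash of (peptide, allele): identical inputs and seed give
#' byte-identical tables on any platform, and no RNG state is consumed.
#'
#' @param candidates candidate data.frame (or character vector of peptides).
#' @param alleles allele names (normalized on output).
#' @param seed integer seed.
#' @param mhc_class `"I"` or `"II"`; default taken from `candidates`.
#' @return binding data.frame as from [parseBindingTable()].
#' @export
mockPredict <- function(candidates, alleles, seed, mhc_class = NULL) {
  if (missing(seed)) stop("mockPredict requires a seed", call. = FALSE)
  if (is.character(candidates)) {
    peptides <- unique(candidates)
    if (is.null(mhc_class)) stop("mhc_class required with a peptide vector", call. = FALSE)
  } else {
    peptides <- unique(candidates$peptide)
    if (is.null(mhc_class)) {
      mc <- unique(candidates$mhc_class)
      if (length(mc) != 1) stop("candidates span several MHC classes; pass mhc_class",
                                call. = FALSE)
      mhc_class <- mc
    }
  }
  alleles <- normalizeAllele(alleles)
  if (length(peptides) == 0 || length(alleles) == 0) {
    out <- data.frame(peptide = character(0), allele = character(0),
                      mhc_class = character(0), ic50_nM = numeric(0),
                      rank_pct = numeric(0), category = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  u_rank <- vapply(seq_len(nrow(grid)), function(i) {
    (hash31(paste0(grid$peptide[i], "|", grid$allele[i], "|rank"), seed) + 1) / 2147483647
  }, numeric(1))
  u_ic50 <- vapply(seq_len(nrow(grid)), function(i) {
    (hash31(paste0(grid$peptide[i], "|", grid$allele[i], "|ic50"), seed) + 1) / 2147483647
  }, numeric(1))
  out <- data.frame(peptide = grid$peptide, allele = grid$allele,
                    mhc_class = mhc_class,
                    ic50_nM = 10^(u_ic50 * log10(50000)),
                    rank_pct = u_rank * 100,
                    stringsAsFactors = FALSE)
  out$category <- classifyBinder(out$mhc_class, out$rank_pct)
  out
}

#' Select candidate binders by %Rank category
#'
#' Joins a candidate table with its binding records and keeps the
#' peptide x allele pairs classified strong or weak; candidate selection is
#' by percentile rank only, IC50 is carried through untouched for the
#' strict filter.
#'
#' @param candidates candidate data.frame.
#' @param binding binding data.frame.
#' @return candidate table expanded per allele, with `allele`, `ic50_nM`,
#'   `rank_pct`, `category` columns; non-binders excluded.
#' @export
selectBinders <- function(candidates, binding) {
  if (nrow(candidates) == 0 || nrow(binding) == 0) {
    out <- cbind(empty_candidate_table(),
                 data.frame(allele = character(0), ic50_nM = numeric(0),
                            rank_pct = numeric(0), category = character(0)))
    return(out)
  }
  hits <- binding[binding$category %in% c("strong", "weak") &
                  binding$mhc_class %in% unique(candidates$mhc_class), , drop = FALSE]
  out <- merge(candidates, hits[, c("peptide", "allele", "ic50_nM", "rank_pct",
                                    "category")],
               by = "peptide", sort = FALSE)
  out <- out[order(out$variant_id, out$k, out$start, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}
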