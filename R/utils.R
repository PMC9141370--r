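# Internal helpers shared across modules.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
is_standard_aa <- function(x) {
  vapply(strsplit(x, ""), function(ch) length(ch) > 0 && all(ch %in% AA_STANDARD),
         logical(1))
}

#' @noRd
has_nonstandard_aa <- function(x) {
  !vapply(strsplit(x, ""), function(ch) all(ch %in% AA_STANDARD), logical(1))
}

#' @noRd
read_tsv_checked <- function(path, required = character(0), what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing mandatory column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

# Write-then-rename so a crashed run never leaves a truncated file behind.
#' @noRd
write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp.", Sys.getpid())
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

# Positions are carried through candidate tables as comma-joined strings so
# every table serializes to plain TSV and round-trips losslessly.
#' @noRd
encode_positions <- function(pos_list) {
  vapply(pos_list, function(p) paste(p, collapse = ","), character(1))
}

#' @noRd
decode_positions <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(p) as.integer(p[nzchar(p)]))
}

# 31-bit polynomial string hash; pure arithmetic, identical on every platform.
# Doubles hold intermediates exactly because h*31 + c < 2^36 << 2^53.
#' @noRd
hash31 <- function(s, salt = 0) {
  h <- (salt %% 2147483647) + 1
  codes <- utf8ToInt(s)
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  h
}

#' @noRd
empty_candidate_table <- function() {
  data.frame(peptide = character(0), k = integer(0), start = integer(0),
             mut_positions = character(0), variant_id = character(0),
             gene = character(0), var_class = character(0),
             mhc_class = character(0), stringsAsFactors = FALSE)
}

VAR_CLASSES <- c("missense", "inframe_ins", "inframe_del", "frameshift", "fusion")
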