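# Independent oracles used by the property-style tests. Each one is a
# deliberately different formulation from the implementation it checks.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_pep <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# --- hand-rolled genetic code (independent of Biostrings::translate) -------

GENETIC_CODE_ORACLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# translate codon-by-codon up to (not including) the first stop
oracle_translate <- function(nt) {
  n3 <- nchar(nt) - nchar(nt) %% 3L
  aas <- character(0)
  stopped <- FALSE
  if (n3 >= 3) {
    for (i in seq(1, n3 - 2, by = 3)) {
      aa <- GENETIC_CODE_ORACLE[[substr(nt, i, i + 2)]]
      if (aa == "*") { stopped <- TRUE; break }
      aas <- c(aas, aa)
    }
  }
  list(seq = paste(aas, collapse = ""), stop = stopped)
}

# apply a cDNA edit by plain string surgery
oracle_apply_edit <- function(cds, type, start, end = start, seq = "") {
  n <- nchar(cds)
  if (type == "ins") {
    paste0(substr(cds, 1, start), seq, substr(cds, start + 1, n))
  } else {
    paste0(substr(cds, 1, start - 1), substr(cds, end + 1, n))
  }
}

# --- brute-force window enumeration ---------------------------------------

# every substring of every length in [k_min, k_max] whose interval
# intersects [a, b], deduplicated on (sequence, k) keeping the first start
oracle_windows <- function(sq, a, b, k_min, k_max) {
  L <- nchar(sq)
  rows <- list()
  for (k in seq(k_min, k_max)) {
    if (k > L) next
    for (s in seq_len(L - k + 1)) {
      e <- s + k - 1
      if (e >= a && s <= b) {
        pep <- substr(sq, s, e)
        if (all(strsplit(pep, "")[[1]] %in% AA20)) {
          rows[[length(rows) + 1]] <- data.frame(peptide = pep, k = k,
                                                 start = s)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peptide = character(0), k = integer(0),
                      start = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("peptide", "k")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- suffix-recursion local alignment oracle -------------------------------

# Lexicographic (score, positives) optimum over ALL local alignments, by a
# backward recursion over aligned-pair successors: an alignment is a chain
# of aligned pairs (i1,j1) < (i2,j2) < ..., each consecutive gap charged
# open + len * ext per gapped sequence. Structurally unlike the forward
# three-state kernel it checks.
oracle_sw <- function(query, subject, mat, open = 11, ext = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  sub <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) sub[i, j] <- mat[q[i], s[j]]
  bs <- matrix(-Inf, n, m)  # best score of an alignment starting at (i, j)
  bp <- matrix(0L, n, m)    # positives on that best-scoring chain
  for (i in n:1) {
    for (j in m:1) {
      best_s <- sub[i, j]
      best_p <- as.integer(sub[i, j] > 0)
      if (i < n && j < m) {
        for (i2 in (i + 1):n) {
          for (j2 in (j + 1):m) {
            di <- i2 - i - 1L; dj <- j2 - j - 1L
            gap <- (di > 0) * (open + ext * di) + (dj > 0) * (open + ext * dj)
            cand_s <- sub[i, j] - gap + bs[i2, j2]
            cand_p <- as.integer(sub[i, j] > 0) + bp[i2, j2]
            if (cand_s > best_s || (cand_s == best_s && cand_p > best_p)) {
              best_s <- cand_s; best_p <- cand_p
            }
          }
        }
      }
      bs[i, j] <- best_s; bp[i, j] <- best_p
    }
  }
  best <- c(score = 0, positives = 0)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (bs[i, j] > best["score"] ||
        (bs[i, j] == best["score"] && bp[i, j] > best["positives"])) {
      best <- c(score = bs[i, j], positives = bp[i, j])
    }
  }
  best
}

blosum62_oracle <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# --- misc ------------------------------------------------------------------

mk_mutant <- function(seq, a, b, id = "v1", gene = "G1", class = "missense") {
  MutantProtein(id, gene, class, seq, a, b)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
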