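#' @import methods
NULL

# ---------------------------------------------------------------------------
# VariantRecord
# ---------------------------------------------------------------------------

#' VariantRecord: one protein-altering somatic event
#'
#' A typed record of a single annotated somatic variant at the protein level.
#' Five classes are supported: `missense`, `inframe_ins`, `inframe_del`,
#' `frameshift` and `fusion`. Coordinates are 1-based inclusive (HGVS
#' convention) everywhere in the package.
#'
#' @slot variantId opaque identifier.
#' @slot gene gene symbol.
#' @slot transcriptId transcript accession (used for expression lookup).
#' @slot proteinId protein accession in the reference proteome.
#' @slot varClass one of `missense`, `inframe_ins`, `inframe_del`,
#'   `frameshift`, `fusion`.
#' @slot proteinPos 1-based position of the first affected residue
#'   (`NA` for fusions).
#' @slot proteinEnd 1-based end of the affected reference range (deletion
#'   ranges and insertion anchor pairs; `NA` elsewhere).
#' @slot refAA reference residues (may be `""` for a pure insertion).
#' @slot altAA alternate residues (may be `""` for a pure deletion).
#' @slot cdnaChange HGVS-like cDNA edit, required for frameshifts
#'   (e.g. `"c.6_7insC"`).
#' @slot genomicLocus optional `chrom:pos:ref:alt` string for traceability.
#'
#' @exportClass VariantRecord
setClass("VariantRecord", representation(
  variantId = "character",
  gene = "character",
  transcriptId = "character",
  proteinId = "character",
  varClass = "character",
  proteinPos = "integer",
  proteinEnd = "integer",
  refAA = "character",
  altAA = "character",
  cdnaChange = "character",
  genomicLocus = "character"
))

setValidity("VariantRecord", function(object) {
  msgs <- character(0)
  vc <- object@varClass
  if (length(vc) != 1 || !vc %in% VAR_CLASSES) {
    return(sprintf("varClass must be one of: %s", paste(VAR_CLASSES, collapse = ", ")))
  }
  pos <- object@proteinPos
  if (vc != "fusion") {
    if (vc != "frameshift" && (is.na(pos) || pos < 1L)) {
      msgs <- c(msgs, "proteinPos must be >= 1 for non-fusion classes")
    }
    if (vc == "frameshift" && !is.na(pos) && pos < 1L) {
      msgs <- c(msgs, "proteinPos must be >= 1 when given")
    }
  }
  if (vc == "missense") {
    if (nchar(object@refAA) != 1L || nchar(object@altAA) != 1L) {
      msgs <- c(msgs, "missense requires single-residue refAA and altAA")
    } else if (object@refAA == object@altAA) {
      msgs <- c(msgs, "missense requires refAA != altAA")
    }
  }
  if (vc == "inframe_ins" && nchar(object@altAA) == 0L) {
    msgs <- c(msgs, "inframe_ins requires non-empty altAA")
  }
  if (vc == "inframe_del" && nchar(object@refAA) == 0L) {
    msgs <- c(msgs, "inframe_del requires non-empty refAA")
  }
  if (!is.na(object@proteinEnd) && !is.na(pos) && object@proteinEnd < pos) {
    msgs <- c(msgs, "proteinEnd must be >= proteinPos")
  }
  if (vc == "frameshift") {
    if (is.na(object@cdnaChange) || !nzchar(object@cdnaChange)) {
      msgs <- c(msgs, "frameshift requires cdnaChange")
    } else {
      ed <- tryCatch(parse_cdna_change(object@cdnaChange), error = function(e) NULL)
      if (is.null(ed)) {
        msgs <- c(msgs, sprintf("unparseable cdnaChange '%s'", object@cdnaChange))
      } else if (ed$indel_len %% 3L == 0L) {
        msgs <- c(msgs, "frameshift indel length must not be divisible by 3")
      }
    }
  }
  for (aa in c(object@refAA, object@altAA)) {
    if (nzchar(aa) && !is.na(aa) && has_nonstandard_aa(aa)) {
      msgs <- c(msgs, sprintf("non-standard residues in '%s'", aa))
    }
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Construct a VariantRecord
#'
#' @param variantId,gene,transcriptId,proteinId identifier strings.
#' @param varClass variant class (see [VariantRecord-class]).
#' @param proteinPos 1-based first affected residue; `NA` for fusions.
#' @param proteinEnd 1-based end of the affected range (`NA` unless the
#'   change spans a range).
#' @param refAA,altAA reference / alternate residues.
#' @param cdnaChange cDNA edit string (frameshifts).
#' @param genomicLocus optional locus string.
#' @return A validated [VariantRecord-class] object.
#' @examples
#' VariantRecord("v1", "GENE1", "NM_1", "P_1", "missense",
#'               proteinPos = 5, refAA = "Y", altAA = "F")
#' @export
VariantRecord <- function(variantId, gene, transcriptId = NA_character_,
                          proteinId = NA_character_, varClass,
                          proteinPos = NA_integer_, proteinEnd = NA_integer_,
                          refAA = "", altAA = "",
                          cdnaChange = NA_character_,
                          genomicLocus = NA_character_) {
  new("VariantRecord", variantId = as.character(variantId),
      gene = as.character(gene), transcriptId = as.character(transcriptId),
      proteinId = as.character(proteinId), varClass = varClass,
      proteinPos = as.integer(proteinPos), proteinEnd = as.integer(proteinEnd),
      refAA = refAA, altAA = altAA,
      cdnaChange = as.character(cdnaChange),
      genomicLocus = as.character(genomicLocus))
}

# ---------------------------------------------------------------------------
# FusionRecord
# ---------------------------------------------------------------------------

#' FusionRecord: a translated gene-fusion junction product
#'
#' Fusions arrive as already-translated junction protein sequences
#' (coding-effect style), not genomic breakpoints. `junctionIndex` is the
#' 1-based index of the last residue encoded entirely by the 5' partner.
#'
#' @slot fusionId identifier.
#' @slot gene5,gene3 5' and 3' partner gene symbols.
#' @slot junctionSeq amino-acid sequence of the fusion product.
#' @slot junctionIndex last residue from the 5' partner (1-based).
#' @slot frameStatus `"in_frame"` or `"frameshift_3prime"`.
#' @exportClass FusionRecord
setClass("FusionRecord", representation(
  fusionId = "character", gene5 = "character", gene3 = "character",
  junctionSeq = "character", junctionIndex = "integer",
  frameStatus = "character"
))

setValidity("FusionRecord", function(object) {
  msgs <- character(0)
  if (!object@frameStatus %in% c("in_frame", "frameshift_3prime")) {
    msgs <- c(msgs, "frameStatus must be 'in_frame' or 'frameshift_3prime'")
  }
  ji <- object@junctionIndex
  L <- nchar(object@junctionSeq)
  if (is.na(ji) || ji < 1L || ji >= L) {
    msgs <- c(msgs, "junctionIndex must satisfy 1 <= junctionIndex < length(junctionSeq)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname FusionRecord-class
#' @param fusionId,gene5,gene3 identifier strings.
#' @param junctionSeq junction protein sequence.
#' @param junctionIndex last 5'-encoded residue (1-based).
#' @param frameStatus `"in_frame"` or `"frameshift_3prime"`.
#' @export
FusionRecord <- function(fusionId, gene5, gene3, junctionSeq, junctionIndex,
                         frameStatus = c("in_frame", "frameshift_3prime")) {
  frameStatus <- match.arg(frameStatus)
  new("FusionRecord", fusionId = as.character(fusionId), gene5 = gene5,
      gene3 = gene3, junctionSeq = toupper(junctionSeq),
      junctionIndex = as.integer(junctionIndex), frameStatus = frameStatus)
}

# ---------------------------------------------------------------------------
# MutantProtein
# ---------------------------------------------------------------------------

#' MutantProtein: a mutant protein sequence with its novel region
#'
#' The altered-region interval `[mutStart, mutEnd]` is 1-based inclusive in
#' MUTANT coordinates and marks the residues considered novel: the substituted
#' residue(s) for missense/insertions, the two junction-flanking residues for
#' deletions and in-frame fusions, and the first altered residue through the
#' sequence end for frameshifts (and 3'-frameshifted fusions).
#'
#' @slot sourceVariant variant (or fusion) identifier.
#' @slot gene gene symbol.
#' @slot varClass variant class.
#' @slot sequence mutant amino-acid sequence.
#' @slot mutStart,mutEnd altered-region interval (1-based inclusive).
#' @slot stopFound frameshift only: whether translation hit a stop codon
#'   (`NA` otherwise).
#' @exportClass MutantProtein
setClass("MutantProtein", representation(
  sourceVariant = "character", gene = "character", varClass = "character",
  sequence = "character", mutStart = "integer", mutEnd = "integer",
  stopFound = "logical"
))

setValidity("MutantProtein", function(object) {
  L <- nchar(object@sequence)
  a <- object@mutStart
  b <- object@mutEnd
  if (is.na(a) || is.na(b) || a < 1L || b < a || b > L) {
    return(sprintf("mut region [%s,%s] invalid for sequence of length %d", a, b, L))
  }
  TRUE
})

#' @rdname MutantProtein-class
#' @param sourceVariant,gene,varClass provenance fields.
#' @param sequence mutant protein sequence.
#' @param mutStart,mutEnd altered-region bounds (1-based inclusive).
#' @param stopFound logical; frameshifts only.
#' @export
MutantProtein <- function(sourceVariant, gene, varClass, sequence,
                          mutStart, mutEnd, stopFound = NA) {
  new("MutantProtein", sourceVariant = as.character(sourceVariant),
      gene = as.character(gene), varClass = varClass,
      sequence = toupper(sequence), mutStart = as.integer(mutStart),
      mutEnd = as.integer(mutEnd), stopFound = as.logical(stopFound))
}

# ---------------------------------------------------------------------------
# FilterConfig
# ---------------------------------------------------------------------------

#' FilterConfig: thresholds and toggles of the filter cascade
#'
#' Defaults follow the published screen: candidates from unexpressed
#' transcripts (TPM not strictly positive) are removed; the strict class-I
#' screen keeps peptides with predicted IC50 <= 34 nM and transcript
#' abundance >= 33 TPM (both boundaries inclusive); the neoantigen-database
#' screen counts a candidate as matched when its best similarity lies in
#' `[20, 100]`; MS evidence must share at least 7 residues with a candidate
#' when matched by co-located overlap.
#'
#' @slot tpmMinExclusive candidates kept iff TPM strictly greater (default 0).
#' @slot strictIc50MaxNM strict-filter IC50 ceiling, nM (default 34).
#' @slot strictTpmMin strict-filter TPM floor (default 33).
#' @slot simThresholdLow,simThresholdHigh similarity window for a database
#'   match, on the 0-100 scale (defaults 20 and 100).
#' @slot msMinOverlap minimum shared residues for overlap-style MS support
#'   (default 7, the MS search engine's minimum peptide length).
#' @slot doExpression,doMS,doNeoDB,doStrict stage toggles.
#' @slot dropWildtype drop candidate windows that occur verbatim in the
#'   reference proteome (default FALSE).
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
  tpmMinExclusive = "numeric", strictIc50MaxNM = "numeric",
  strictTpmMin = "numeric", simThresholdLow = "numeric",
  simThresholdHigh = "numeric", msMinOverlap = "integer",
  doExpression = "logical", doMS = "logical", doNeoDB = "logical",
  doStrict = "logical", dropWildtype = "logical"
))

setValidity("FilterConfig", function(object) {
  msgs <- character(0)
  if (object@simThresholdLow < 0 || object@simThresholdHigh > 100 ||
      object@simThresholdLow > object@simThresholdHigh) {
    msgs <- c(msgs, "similarity thresholds must satisfy 0 <= low <= high <= 100")
  }
  if (object@strictIc50MaxNM <= 0 || object@strictTpmMin < 0) {
    msgs <- c(msgs, "strict thresholds must be positive")
  }
  if (object@msMinOverlap < 1L) msgs <- c(msgs, "msMinOverlap must be >= 1")
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname FilterConfig-class
#' @param tpmMinExclusive,strictIc50MaxNM,strictTpmMin,simThresholdLow,simThresholdHigh,msMinOverlap
#'   thresholds (see slots).
#' @param doExpression,doMS,doNeoDB,doStrict,dropWildtype stage toggles.
#' @export
FilterConfig <- function(tpmMinExclusive = 0, strictIc50MaxNM = 34,
                         strictTpmMin = 33, simThresholdLow = 20,
                         simThresholdHigh = 100, msMinOverlap = 7L,
                         doExpression = TRUE, doMS = TRUE, doNeoDB = TRUE,
                         doStrict = TRUE, dropWildtype = FALSE) {
  new("FilterConfig", tpmMinExclusive = tpmMinExclusive,
      strictIc50MaxNM = strictIc50MaxNM, strictTpmMin = strictTpmMin,
      simThresholdLow = simThresholdLow, simThresholdHigh = simThresholdHigh,
      msMinOverlap = as.integer(msMinOverlap), doExpression = doExpression,
      doMS = doMS, doNeoDB = doNeoDB, doStrict = doStrict,
      dropWildtype = dropWildtype)
}

# ---------------------------------------------------------------------------
# FilterReport
# ---------------------------------------------------------------------------

#' FilterReport: cascade stage counts and matching ratios
#'
#' @slot counts data.frame with columns `stage`, `var_class`, `mhc_class`, `n`.
#' @slot perAllele named integer vector of candidate counts per allele.
#' @slot matchingRatios named numeric vector (percentages, 2 decimals).
#' @slot strongWeak data.frame with columns `mhc_class`, `category`, `n`.
#' @exportClass FilterReport
setClass("FilterReport", representation(
  counts = "data.frame", perAllele = "integer", matchingRatios = "numeric",
  strongWeak = "data.frame"
))

# ---------------------------------------------------------------------------
# FixtureSpec
# ---------------------------------------------------------------------------

#' FixtureSpec: parameters of the synthetic input generator
#'
#' Defaults emulate the study conditions at toy scale: 50 reference proteins
#' of ~300 residues, 5 variants per class, the five published HLA class I
#' alleles and two class II alleles, 70% of transcripts expressed and half
#' the mutant proteins detectable by MS.
#'
#' @slot nProteins number of reference proteins.
#' @slot proteinLengthRange min/max reference protein length (residues).
#' @slot nVariantsPerClass variants generated per mutation class.
#' @slot allelesI,allelesII HLA allele names used by the mock predictor.
#' @slot expressedFraction fraction of transcripts with positive TPM.
#' @slot msDetectedFraction fraction of mutant proteins with MS evidence.
#' @slot neodbSize number of random decoy entries in the neoantigen database
#'   (planted exact-copy entries are added on top).
#' @slot seed mandatory integer seed driving every random choice.
#' @exportClass FixtureSpec
setClass("FixtureSpec", representation(
  nProteins = "integer", proteinLengthRange = "integer",
  nVariantsPerClass = "integer", allelesI = "character",
  allelesII = "character", expressedFraction = "numeric",
  msDetectedFraction = "numeric", neodbSize = "integer", seed = "integer"
))

setValidity("FixtureSpec", function(object) {
  msgs <- character(0)
  if (any(c(object@nProteins, object@nVariantsPerClass, object@neodbSize) < 0L)) {
    msgs <- c(msgs, "counts must be >= 0")
  }
  fr <- c(object@expressedFraction, object@msDetectedFraction)
  if (any(fr < 0 | fr > 1)) msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (length(object@seed) != 1L || is.na(object@seed)) {
    msgs <- c(msgs, "seed is mandatory")
  }
  if (length(object@proteinLengthRange) != 2L ||
      object@proteinLengthRange[1] < 30L ||
      object@proteinLengthRange[1] > object@proteinLengthRange[2]) {
    msgs <- c(msgs, "proteinLengthRange must be c(min >= 30, max >= min)")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' @rdname FixtureSpec-class
#' @param nProteins,proteinLengthRange,nVariantsPerClass,neodbSize sizes.
#' @param allelesI,allelesII HLA allele name vectors.
#' @param expressedFraction,msDetectedFraction fractions in `[0, 1]`.
#' @param seed integer seed (mandatory).
#' @export
FixtureSpec <- function(nProteins = 50L, proteinLengthRange = c(250L, 350L),
                        nVariantsPerClass = 5L,
                        allelesI = c("HLA-A*03:01", "HLA-B*07:02",
                                     "HLA-B*35:03", "HLA-C*07:02",
                                     "HLA-C*04:01"),
                        allelesII = c("DRB4*01:03", "DRB4*01:01"),
                        expressedFraction = 0.7, msDetectedFraction = 0.5,
                        neodbSize = 60L, seed) {
  if (missing(seed)) stop("FixtureSpec requires an explicit seed", call. = FALSE)
  new("FixtureSpec", nProteins = as.integer(nProteins),
      proteinLengthRange = as.integer(proteinLengthRange),
      nVariantsPerClass = as.integer(nVariantsPerClass),
      allelesI = allelesI, allelesII = allelesII,
      expressedFraction = expressedFraction,
      msDetectedFraction = msDetectedFraction,
      neodbSize = as.integer(neodbSize), seed = as.integer(seed))
}
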