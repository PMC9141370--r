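#' Accessors for neoforge S4 objects
#'
#' `variantId()`, `variantClass()`, `proteinSeq()`, `mutRegion()` and
#' `stopFound()` read the corresponding slots of [VariantRecord-class] and
#' [MutantProtein-class] objects without touching slots directly.
#'
#' @param x a neoforge S4 object.
#' @return `variantId()` and `variantClass()` return character scalars;
#'   `proteinSeq()` the sequence string; `mutRegion()` an integer vector
#'   `c(start, end)` (1-based inclusive); `stopFound()` a logical.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @rdname accessors
#' @export
setGeneric("proteinSeq", function(x) standardGeneric("proteinSeq"))

#' @rdname accessors
#' @export
setGeneric("mutRegion", function(x) standardGeneric("mutRegion"))

#' @rdname accessors
#' @export
setGeneric("stopFound", function(x) standardGeneric("stopFound"))

#' @rdname accessors
setMethod("variantId", "VariantRecord", function(x) x@variantId)

#' @rdname accessors
setMethod("variantId", "MutantProtein", function(x) x@sourceVariant)

#' @rdname accessors
setMethod("variantClass", "VariantRecord", function(x) x@varClass)

#' @rdname accessors
setMethod("variantClass", "MutantProtein", function(x) x@varClass)

#' @rdname accessors
setMethod("proteinSeq", "MutantProtein", function(x) x@sequence)

#' @rdname accessors
setMethod("mutRegion", "MutantProtein", function(x) c(x@mutStart, x@mutEnd))

#' @rdname accessors
setMethod("stopFound", "MutantProtein", function(x) x@stopFound)

setMethod("show", "VariantRecord", function(object) {
  pos <- if (is.na(object@proteinPos)) "-" else object@proteinPos
  cat(sprintf("VariantRecord %s | %s %s | class=%s pos=%s %s>%s\n",
              object@variantId, object@gene, object@transcriptId,
              object@varClass, pos,
              ifelse(nzchar(object@refAA), object@refAA, "-"),
              ifelse(nzchar(object@altAA), object@altAA, "-")))
})

setMethod("show", "FusionRecord", function(object) {
  cat(sprintf("FusionRecord %s | %s::%s | junction=%d/%d | %s\n",
              object@fusionId, object@gene5, object@gene3,
              object@junctionIndex, nchar(object@junctionSeq),
              object@frameStatus))
})

setMethod("show", "MutantProtein", function(object) {
  sq <- object@sequence
  shown <- if (nchar(sq) > 40) paste0(substr(sq, 1, 37), "...") else sq
  cat(sprintf("MutantProtein <%s> %s (%s)\n  %d aa, mut region [%d,%d]%s\n  %s\n",
              object@sourceVariant, object@gene, object@varClass,
              nchar(sq), object@mutStart, object@mutEnd,
              if (!is.na(object@stopFound))
                sprintf(", stop %sfound", if (object@stopFound) "" else "not ")
              else "",
              shown))
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n",
      sprintf("  expression: TPM > %g (%s)\n", object@tpmMinExclusive,
              if (object@doExpression) "on" else "off"),
      sprintf("  MS evidence: min overlap %d (%s)\n", object@msMinOverlap,
              if (object@doMS) "on" else "off"),
      sprintf("  neoantigen DB: similarity in [%g, %g] (%s)\n",
              object@simThresholdLow, object@simThresholdHigh,
              if (object@doNeoDB) "on" else "off"),
      sprintf("  strict: IC50 <= %g nM & TPM >= %g (%s)\n",
              object@strictIc50MaxNM, object@strictTpmMin,
              if (object@doStrict) "on" else "off"), sep = "")
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  if (nrow(object@counts)) {
    tot <- stats::aggregate(n ~ stage, data = object@counts, FUN = sum)
    for (i in seq_len(nrow(tot))) {
      cat(sprintf("  %-28s %d\n", tot$stage[i], tot$n[i]))
    }
  }
  if (length(object@matchingRatios)) {
    cat("  matching ratios:\n")
    for (nm in names(object@matchingRatios)) {
      cat(sprintf("    %-24s %.2f%%\n", nm, object@matchingRatios[[nm]]))
    }
  }
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf(paste0("FixtureSpec: %d proteins (%d-%d aa), %d variants/class, ",
                     "%d+%d alleles, expressed %.0f%%, MS %.0f%%, seed %d\n"),
              object@nProteins, object@proteinLengthRange[1],
              object@proteinLengthRange[2], object@nVariantsPerClass,
              length(object@allelesI), length(object@allelesII),
              100 * object@expressedFraction, 100 * object@msDetectedFraction,
              object@seed))
})
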