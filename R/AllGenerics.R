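#' @rdname GenomeLayout-class
#' @param object,x An object.
#' @export
setGeneric("assemblyGaps", function(x) standardGeneric("assemblyGaps"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname ZCRSet-class
#' @export
setGeneric("zcrRanges", function(x) standardGeneric("zcrRanges"))

#' @rdname ZCRSet-class
#' @export
setGeneric("minLength", function(x) standardGeneric("minLength"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("exonRanges", function(x) standardGeneric("exonRanges"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))

#' @rdname GeneCatalog-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneFlagTable-class
#' @export
setGeneric("sampleFlags", function(x) standardGeneric("sampleFlags"))

#' @rdname GeneFlagTable-class
#' @export
setGeneric("combinedFlags", function(x) standardGeneric("combinedFlags"))

#' @rdname VariantTable-class
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @rdname VariantTable-class
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname VariantTable-class
#' @export
setGeneric("genotypeCopies", function(x) standardGeneric("genotypeCopies"))

#' @rdname PresenceAbsenceMatrix-class
#' @export
setGeneric("absenceFraction",
           function(x) standardGeneric("absenceFraction"))

#' @rdname PresenceAbsenceMatrix-class
#' @export
setGeneric("absenceCalls", function(x) standardGeneric("absenceCalls"))
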