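#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `variantCalls()`
#' returns the canonical call data.frame of a cohort, `cohortLabel()` its
#' label, `individuals()` its roster, `inheritanceModel()` the model of a
#' [GeneScoreMatrix], `panelSites()` and `populations()` the contents of a
#' [FrequencyPanel], and `provenance()` the origin label of a [ScoreTable].
#'
#' @param x an object of the documented class
#' @return the slot contents described above
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))
#' @rdname accessors
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))
#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("inheritanceModel", function(x) standardGeneric("inheritanceModel"))
#' @rdname accessors
#' @export
setGeneric("panelSites", function(x) standardGeneric("panelSites"))
#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("variantCalls", "VariantCohort", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("cohortLabel", "VariantCohort", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("individuals", "VariantCohort", function(x) x@individuals)
#' @rdname accessors
#' @export
setMethod("inheritanceModel", "GeneScoreMatrix", function(x) x@model)
#' @rdname accessors
#' @export
setMethod("panelSites", "FrequencyPanel", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("populations", "FrequencyPanel", function(x) x@populations)
#' @rdname accessors
#' @export
setMethod("provenance", "ScoreTable", function(x) x@provenance)
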