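#' @rdname StrainExperiment-accessors
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname StrainExperiment-accessors
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname StrainExperiment-accessors
#' @export
setGeneric("predictionStrain", function(x) standardGeneric("predictionStrain"))

#' @rdname StrainExperiment-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname StrainExperiment-accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname collapseReplicates
#' @export
setGeneric("collapseReplicates",
           function(x, method = "mean") standardGeneric("collapseReplicates"))

#' @rdname TargetSet
#' @export
setGeneric("targetGenes", function(x) standardGeneric("targetGenes"))

#' @rdname predictionValues
#' @export
setGeneric("predictionValues", function(x) standardGeneric("predictionValues"))

#' @rdname evaluationScore
#' @export
setGeneric("evaluationScore", function(x) standardGeneric("evaluationScore"))
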