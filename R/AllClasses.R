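#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor dist pt rnorm runif sd setNames
#' @importFrom utils head read.delim write.table
NULL

setClassUnion("numericOrNULL", members = c("numeric", "NULL"))

#' StrainExperiment: multi-strain time-course expression data
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose columns are
#' (strain, timepoint, replicate) samples, extended with a per-(gene, strain)
#' logical mask marking held-out cells and a designated prediction strain.
#' Column metadata holds `strain` (factor, levels in strain order), `time`
#' (minutes) and `replicate` (integer). Masked cells may only occur in the
#' prediction strain; all unmasked cells must be finite. Expression values
#' are used as provided (log-scale RMA-style values assumed); no
#' re-normalization is applied anywhere in the package.
#'
#' Use [StrainExperiment()] to construct, [readExpressionTable()] to read
#' from TSV, and the accessors [strains()], [timePoints()],
#' [predictionStrain()], [nReplicates()], [maskMatrix()], [strainMatrix()]
#' and [exprProfile()] to query. Direct slot or `assay()` access bypasses
#' the mask and is not part of the supported API.
#'
#' @name StrainExperiment-class
#' @aliases StrainExperiment-class
#' @exportClass StrainExperiment
setClass("StrainExperiment",
  contains = "SummarizedExperiment",
  slots = c(mask = "matrix", predictionStrain = "character")
)

setValidity("StrainExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("strain", "time", "replicate") %in% colnames(cd)))
    return("colData must contain 'strain', 'time' and 'replicate'")
  genes <- rownames(object)
  if (is.null(genes) || anyDuplicated(genes))
    msg <- c(msg, "gene identifiers must be present and unique")
  sl <- levels(cd$strain)
  if (length(object@predictionStrain) != 1L ||
      !(object@predictionStrain %in% sl))
    msg <- c(msg, "predictionStrain must name exactly one strain")
  tp <- sort(unique(cd$time))
  if (any(diff(tp) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  m <- object@mask
  if (!is.logical(m) || nrow(m) != nrow(object) ||
      !identical(colnames(m), sl) || !identical(rownames(m), genes))
    msg <- c(msg, "mask must be a logical gene x strain matrix matching dimnames")
  else {
    other <- setdiff(sl, object@predictionStrain)
    if (length(other) && any(m[, other, drop = FALSE]))
      msg <- c(msg, "masked entries may occur only in the prediction strain")
    v <- SummarizedExperiment::assay(object)
    maskedCols <- m[, as.character(cd$strain), drop = FALSE]
    idx <- cbind(rep(seq_len(nrow(v)), ncol(v)),
                 rep(seq_len(ncol(v)), each = nrow(v)))
    bad <- !is.finite(v[idx]) & !maskedCols[idx]
    if (any(bad))
      msg <- c(msg, "non-finite values in unmasked cells")
  }
  if (length(msg)) msg else TRUE
})

#' TargetSet: genes to predict in the prediction strain
#'
#' A non-empty set of gene identifiers to predict, together with the label
#' of the strain in which their expression is hidden.
#'
#' @name TargetSet-class
#' @exportClass TargetSet
setClass("TargetSet", slots = c(genes = "character", strain = "character"))

setValidity("TargetSet", function(object) {
  msg <- character()
  if (length(object@genes) == 0L)
    msg <- c(msg, "target set must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicated target gene identifiers")
  if (length(object@strain) != 1L)
    msg <- c(msg, "exactly one prediction strain label required")
  if (length(msg)) msg else TRUE
})

#' NeighborGraph: per-target neighbor sets with distances
#'
#' Holds, for each target gene, an ordered vector of neighbor gene ids and
#' the corresponding combined distances, plus the construction method
#' (`"knn"`, `"mutual"` or `"dense"`) and its parameter record.
#'
#' @name NeighborGraph-class
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  slots = c(neighbors = "list", distances = "list",
            method = "character", params = "list")
)

#' PredictionResult: predicted target expression
#'
#' A target-gene x timepoint matrix of predicted expression values for the
#' prediction strain, with the model tag and parameter record attached.
#'
#' @name PredictionResult-class
#' @exportClass PredictionResult
setClass("PredictionResult",
  slots = c(values = "matrix", model = "character", params = "list")
)

setValidity("PredictionResult", function(object) {
  v <- object@values
  if (!is.numeric(v) || any(!is.finite(v)))
    return("prediction values must be finite numerics")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("prediction matrix must carry gene and timepoint dimnames")
  TRUE
})

#' RegressionFit: one per-timepoint linear model
#'
#' Ordinary least squares fit of the prediction-strain expression at one
#' timepoint on the same gene's profiles in the complete strains
#' (intercept + one coefficient per complete-strain timepoint).
#'
#' @name RegressionFit-class
#' @exportClass RegressionFit
setClass("RegressionFit",
  slots = c(timepoint = "numeric", coefficients = "numeric",
            nTrainingGenes = "integer", sigma = "numeric")
)

#' EvalConfig: evaluation variant
#'
#' Selects how predictions are scored: `transform` is `"rank"` (per-timepoint
#' rank transform, rank 1 = highest value) or `"value"` (raw values);
#' `correlation` is `"spearman"` or `"pearson"`. The four combinations are
#' the official challenge evaluation (`rank`/`spearman`) and its three
#' alternatives. `baseline` is an optional named per-gene vector subtracted
#' from predictions and truth before scoring (e.g. each gene's wild-type
#' t = 0 value, to score induction relative to the untreated parent).
#'
#' @name EvalConfig-class
#' @exportClass EvalConfig
setClass("EvalConfig",
  slots = c(transform = "character", correlation = "character",
            baseline = "numericOrNULL")
)

#' EvaluationReport: accuracies, p-values and score
#'
#' Per-timepoint gene-profile accuracies and one-sided p-values,
#' per-gene time-profile accuracies and p-values, their overall
#' aggregates (arithmetic mean of accuracies, geometric mean of
#' p-values) and the significance score `-0.5 * log10(pG * pT)`.
#'
#' @name EvaluationReport-class
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  slots = c(
    geneAccuracies = "numeric", genePValues = "numeric",
    timeAccuracies = "numeric", timePValues = "numeric",
    overallGeneAccuracy = "numeric", overallGenePValue = "numeric",
    overallTimeAccuracy = "numeric", overallTimePValue = "numeric",
    score = "numeric", config = "EvalConfig", pvalueModes = "character"
  )
)

#' HoldoutResult: repeated random-gene holdout accuracies
#'
#' @name HoldoutResult-class
#' @exportClass HoldoutResult
setClass("HoldoutResult",
  slots = c(model = "character", params = "list", accuracies = "numeric",
            seeds = "integer", nHeld = "integer")
)

#' SimConfig: synthetic multi-strain time-course configuration
#'
#' See [simConfig()] for field semantics and defaults.
#'
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(
    nGenes = "integer", nTargets = "integer",
    strains = "character", predictionStrain = "character",
    timepoints = "numeric", nReplicates = "integer",
    moduleSizeRange = "integer", smoothness = "integer",
    strainEffectSd = "numeric", targetBoost = "numeric",
    noiseSd = "numeric", backgroundFraction = "numeric",
    loadingSd = "numeric", offsetSd = "numeric",
    baseline = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nTargets >= object@nGenes)
    msg <- c(msg, "nTargets must be smaller than nGenes")
  if (any(object@moduleSizeRange < 2L))
    msg <- c(msg, "module sizes must be at least 2")
  if (object@noiseSd < 0 || object@strainEffectSd < 0 ||
      object@loadingSd < 0 || object@offsetSd < 0)
    msg <- c(msg, "variances must be non-negative")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    msg <- c(msg, "backgroundFraction must be in [0, 1)")
  if (!(object@predictionStrain %in% object@strains))
    msg <- c(msg, "predictionStrain must be one of the strain labels")
  if (length(msg)) msg else TRUE
})

#' SimTruth: generative ground truth for a simulated dataset
#'
#' Records the module assignment of every gene (0 = background), the latent
#' module profiles per strain, and the gold-standard values of the masked
#' cells (replicate-mean target-gene x timepoint matrix for the prediction
#' strain, exactly equal to the generated values before masking).
#'
#' @name SimTruth-class
#' @exportClass SimTruth
setClass("SimTruth",
  slots = c(modules = "integer", latent = "list", gold = "matrix")
)
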