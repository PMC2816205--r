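.predictWithModel <- function(x, targets, model, params, distances) {
  switch(model,
    "knn" = predictKNN(x, targets, k = params$k %||% 10,
                       distances = distances),
    "knn-star" = predictKNNStar(x, targets, K = params$K %||% 20,
                                fallback = params$fallback %||% 3,
                                distances = distances),
    "dense-subnet" = predictDenseSubnet(x, targets, K = params$K %||% 20,
                                        m = params$m %||% 10,
                                        distances = distances),
    "linreg" = predictRegression(x, targets),
    stop("unknown model: ", model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One random-gene holdout round
#'
#' Samples `nHeld` genes uniformly (without replacement) among genes not
#' already masked, hides their prediction-strain values, predicts them
#' with the requested model, and scores the overall gene-profile accuracy
#' against the held-out truth. Only gene-profile accuracy is computed:
#' time-profile accuracy depends on which genes happen to be drawn and is
#' not used for model selection.
#'
#' @param x a [StrainExperiment-class] (true targets, if any, already
#'   masked; held-out genes never overlap them).
#' @param model `"knn"`, `"knn-star"`, `"dense-subnet"` or `"linreg"`.
#' @param nHeld number of genes to hold out (default 50).
#' @param seed integer seed for the draw.
#' @param params named list of model parameters (`k`, `K`, `fallback`, `m`).
#' @param distances optional precomputed [combinedDistances()] matrix
#'   (it does not depend on masking, so it can be shared across rounds).
#' @param config evaluation variant; default the official rank/Spearman.
#' @return the overall gene-profile accuracy (scalar).
#' @export
holdoutRound <- function(x, model = "knn", nHeld = 50, seed = 1,
                         params = list(), distances = NULL,
                         config = evalConfig()) {
  eligible <- setdiff(rownames(x), maskedGenes(x))
  if (length(eligible) < nHeld)
    stop("only ", length(eligible), " eligible genes for nHeld = ", nHeld)
  set.seed(seed)
  held <- sample(eligible, nHeld)
  truth <- strainMatrix(x, predictionStrain(x), masked = "na")[held, ]
  ts <- TargetSet(held, predictionStrain(x))
  xm <- maskTargets(x, ts)
  pred <- .predictWithModel(xm, ts, model, params, distances)
  rep <- evaluate(pred, truth, config)
  rep@overallGeneAccuracy
}

#' Repeated random-gene holdout
#'
#' Runs [holdoutRound()] `repeats` times with per-repeat seeds
#' `baseSeed + 0:(repeats - 1)` (a simple documented counter scheme) and
#' collects the per-repeat overall gene-profile accuracies. The paper's
#' selection protocol is 50 held-out genes, 10 repeats, mean accuracy.
#'
#' @inheritParams holdoutRound
#' @param repeats number of independent holdout rounds (default 10).
#' @param baseSeed base integer seed.
#' @return a [HoldoutResult-class].
#' @export
repeatHoldout <- function(x, model = "knn", nHeld = 50, repeats = 10,
                          baseSeed = 1, params = list(), distances = NULL,
                          config = evalConfig()) {
  if (is.null(distances) && model != "linreg")
    distances <- combinedDistances(x)
  seeds <- as.integer(baseSeed + seq_len(repeats) - 1L)
  acc <- vapply(seeds, function(s)
    holdoutRound(x, model, nHeld = nHeld, seed = s, params = params,
                 distances = distances, config = config), numeric(1))
  new("HoldoutResult", model = model, params = params,
      accuracies = acc, seeds = seeds, nHeld = as.integer(nHeld))
}

#' @describeIn repeatHoldout mean accuracy of a holdout result.
#' @param result a [HoldoutResult-class].
#' @export
meanAccuracy <- function(result) mean(result@accuracies)

setMethod("show", "HoldoutResult", function(object) {
  cat(sprintf(
    "HoldoutResult (%s): %d repeat(s) x %d held-out genes, mean gene-profile accuracy %.3f (sd %.3f)\n",
    object@model, length(object@accuracies), object@nHeld,
    mean(object@accuracies), sd(object@accuracies)))
})

#' Accuracy-versus-k sweep for the standard KNN model
#'
#' Estimates the holdout gene-profile accuracy of [predictKNN()] for each
#' value of `k`, using a paired design: the same random held-out sets
#' (seeds `baseSeed + 0:(repeats - 1)`) are reused for every `k`, so the
#' curve differences are not confounded by mask sampling noise. For a
#' single `k` the mean equals `meanAccuracy(repeatHoldout(...))` with the
#' same seeds.
#'
#' @inheritParams repeatHoldout
#' @param kValues integer vector of neighborhood sizes to try.
#' @return a `data.frame` with columns `k` and `accuracy` (mean over
#'   repeats), with the per-repeat accuracy matrix in the `"perRepeat"`
#'   attribute and the best k (first maximum) in the `"bestK"` attribute.
#' @export
sweepK <- function(x, kValues, nHeld = 50, repeats = 10, baseSeed = 1,
                   distances = NULL, config = evalConfig()) {
  kValues <- as.integer(kValues)
  if (is.null(distances)) distances <- combinedDistances(x)
  seeds <- as.integer(baseSeed + seq_len(repeats) - 1L)
  acc <- matrix(NA_real_, length(seeds), length(kValues),
                dimnames = list(NULL, paste0("k", kValues)))
  for (r in seq_along(seeds)) {
    for (j in seq_along(kValues)) {
      acc[r, j] <- holdoutRound(x, "knn", nHeld = nHeld, seed = seeds[r],
                                params = list(k = kValues[j]),
                                distances = distances, config = config)
    }
  }
  out <- data.frame(k = kValues, accuracy = colMeans(acc))
  rownames(out) <- NULL
  attr(out, "perRepeat") <- acc
  attr(out, "bestK") <- kValues[which.max(colMeans(acc))]
  out
}
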