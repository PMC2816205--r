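.resolveTargets <- function(x, targets) {
  if (is.null(targets)) {
    g <- maskedGenes(x)
    if (!length(g)) stop("no masked genes; mask targets first")
    return(TargetSet(g, predictionStrain(x)))
  }
  if (!is(targets, "TargetSet"))
    targets <- TargetSet(targets, predictionStrain(x))
  validObject(targets)
  unknown <- setdiff(targets@genes, rownames(x))
  if (length(unknown))
    stop("unknown target gene(s): ", paste(unknown, collapse = ", "))
  notMasked <- targets@genes[!x@mask[targets@genes, predictionStrain(x)]]
  if (length(notMasked))
    stop("target gene(s) not masked in the prediction strain: ",
         paste(head(notMasked, 5), collapse = ", "),
         "; call maskTargets() first")
  targets
}

# average the prediction-strain profiles of each target's neighbors
.averageNeighbors <- function(x, targets, graph, model, params) {
  ps <- predictionStrain(x)
  obs <- strainMatrix(x, ps, masked = "na")
  tg <- targetGenes(targets)
  vals <- t(vapply(tg, function(g) {
    nb <- graph@neighbors[[g]]
    colMeans(obs[nb, , drop = FALSE])
  }, numeric(length(timePoints(x)))))
  if (any(!is.finite(vals)))
    stop("internal error: a masked gene leaked into a neighbor list")
  dimnames(vals) <- list(tg, sprintf("t%g", timePoints(x)))
  new("PredictionResult", values = vals, model = model, params = params)
}

#' Standard KNN prediction
#'
#' Predicts each masked target's prediction-strain profile as the plain
#' average, per timepoint, of the prediction-strain profiles of its k
#' nearest neighbors under the combined distance D over the complete
#' strains. Prediction targets are prohibited from serving as neighbors of
#' other prediction targets.
#'
#' @param x a masked [StrainExperiment-class].
#' @param targets a [TargetSet-class], a character vector of masked gene
#'   ids, or `NULL` to predict every masked gene.
#' @param k number of neighbors (default 10).
#' @param distances optional precomputed [combinedDistances()] matrix.
#' @return a [PredictionResult-class].
#' @examples
#' fx <- makeFixture("tiny")
#' pred <- predictKNN(fx$dataset, fx$targets, k = 5)
#' predictionValues(pred)[1:2, ]
#' @export
predictKNN <- function(x, targets = NULL, k = 10, distances = NULL) {
  targets <- .resolveTargets(x, targets)
  if (is.null(distances)) distances <- combinedDistances(x)
  graph <- buildNeighborGraph(distances, targetGenes(targets),
                              method = "knn", k = k,
                              forbidden = forbiddenUnion(x, targets))
  .averageNeighbors(x, targets, graph, "knn", list(k = k))
}

# all masked genes are forbidden as neighbors, not only the requested
# targets; returns a TargetSet-like construction for graph building
forbiddenUnion <- function(x, targets) {
  union(targetGenes(targets), maskedGenes(x))
}

#' Improved KNN (KNN*) prediction
#'
#' As [predictKNN()], but each target's neighborhood is its mutual
#' nearest neighbor set (two genes are neighbors only if each lies in the
#' other's top-K list) plus a floor of its `fallback` nearest eligible
#' genes, so neighborhood sizes adapt to how many genes a target is
#' co-expressed with.
#'
#' @inheritParams predictKNN
#' @param K top-list size defining mutual membership (default 20).
#' @param fallback minimum neighborhood size (default 3).
#' @return a [PredictionResult-class].
#' @export
predictKNNStar <- function(x, targets = NULL, K = 20, fallback = 3,
                           distances = NULL) {
  targets <- .resolveTargets(x, targets)
  if (is.null(distances)) distances <- combinedDistances(x)
  graph <- buildNeighborGraph(distances, targetGenes(targets),
                              method = "mutual", K = K, fallback = fallback,
                              forbidden = forbiddenUnion(x, targets))
  .averageNeighbors(x, targets, graph, "knn-star",
                    list(K = K, fallback = fallback))
}

#' Dense-subnetwork prediction
#'
#' As [predictKNN()], but each target's neighborhood is the m most densely
#' interconnected genes among its top-K neighbors (degree within the
#' induced subgraph of the global K-NN graph), intended to retain the
#' functional pathway around the target and drop incidentally similar
#' genes.
#'
#' @inheritParams predictKNN
#' @param K candidate pool size (default 20).
#' @param m final neighborhood size (default 10).
#' @return a [PredictionResult-class].
#' @export
predictDenseSubnet <- function(x, targets = NULL, K = 20, m = 10,
                               distances = NULL) {
  targets <- .resolveTargets(x, targets)
  if (is.null(distances)) distances <- combinedDistances(x)
  graph <- buildNeighborGraph(distances, targetGenes(targets),
                              method = "dense", K = K, m = m,
                              forbidden = forbiddenUnion(x, targets))
  .averageNeighbors(x, targets, graph, "dense-subnet", list(K = K, m = m))
}

# design matrix: one row per gene, 1 + (complete strains x timepoints)
.regressionDesign <- function(x) {
  complete <- setdiff(strains(x), predictionStrain(x))
  cols <- do.call(cbind, lapply(complete, function(s) {
    m <- strainMatrix(x, s, masked = "reveal")
    colnames(m) <- sprintf("%s.%s", s, colnames(m))
    m
  }))
  cbind(`(Intercept)` = 1, cols)
}

#' Per-timepoint linear regression fit
#'
#' Ordinary least squares of the prediction-strain expression at timepoint
#' `t` on the same gene's profiles across the complete strains (an
#' intercept plus one coefficient per complete-strain timepoint, 3 x 8 =
#' 24 coefficients in the challenge layout). Trained on all genes that are
#' not masked in the prediction strain.
#'
#' @param x a masked [StrainExperiment-class].
#' @param t one of `timePoints(x)`.
#' @return a [RegressionFit-class].
#' @export
fitTimepointRegression <- function(x, t) {
  tps <- timePoints(x)
  if (!t %in% tps) stop("unknown timepoint: ", t)
  train <- setdiff(rownames(x), maskedGenes(x))
  if (length(train) < 25L)
    stop("need at least 25 training genes, have ", length(train))
  X <- .regressionDesign(x)[train, , drop = FALSE]
  y <- strainMatrix(x, predictionStrain(x),
                    masked = "reveal")[train, sprintf("t%g", t)]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  new("RegressionFit", timepoint = t, coefficients = beta,
      nTrainingGenes = length(train),
      sigma = sqrt(sum(res^2) / (length(y) - ncol(X))))
}

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "RegressionFit at t = %g min: %d coefficient(s) + intercept, %d training genes, residual sd %.4g\n",
    object@timepoint, length(object@coefficients) - 1L,
    object@nTrainingGenes, object@sigma))
})

#' Linear-regression prediction
#'
#' Runs [fitTimepointRegression()] independently for every timepoint and
#' applies the fits to each target's observed complete-strain profiles.
#'
#' @inheritParams predictKNN
#' @return a [PredictionResult-class].
#' @export
predictRegression <- function(x, targets = NULL) {
  targets <- .resolveTargets(x, targets)
  tg <- targetGenes(targets)
  tps <- timePoints(x)
  Xt <- .regressionDesign(x)[tg, , drop = FALSE]
  vals <- vapply(tps, function(t) {
    fit <- fitTimepointRegression(x, t)
    drop(Xt %*% fit@coefficients)
  }, numeric(length(tg)))
  vals <- matrix(vals, nrow = length(tg),
                 dimnames = list(tg, sprintf("t%g", tps)))
  new("PredictionResult", values = vals, model = "linreg", params = list())
}

#' Extract predicted values
#'
#' @param x a [PredictionResult-class].
#' @return the target-gene x timepoint matrix.
#' @rdname predictionValues
#' @export
setMethod("predictionValues", "PredictionResult", function(x) x@values)

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult (%s): %d target(s) x %d timepoint(s)\n",
              object@model, nrow(object@values), ncol(object@values)))
  if (length(object@params))
    cat("  params:", paste(names(object@params), unlist(object@params),
                           sep = " = ", collapse = ", "), "\n")
})
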