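#' Per-timepoint rank transform
#'
#' Ranks each column (timepoint) of a target-gene x timepoint matrix in
#' descending order of value: the gene with the highest induction gets
#' rank 1 and the gene with the strongest repression gets rank `n`. Ties
#' receive average (midrank) ranks.
#'
#' @param values numeric matrix, at least 2 rows.
#' @return matrix of ranks with the same dimnames.
#' @export
rankTransform <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("rank transform needs at least 2 genes")
  apply(values, 2L, function(col) rank(-col, ties.method = "average"))
}

#' Correlation accuracy of one profile
#'
#' Spearman or Pearson correlation between a predicted and an actual
#' profile (a gene profile across targets at one timepoint, or a time
#' profile across timepoints for one gene). A constant (zero-variance)
#' prediction or truth vector has no defined correlation; the accuracy is
#' then 0, with a warning.
#'
#' @param pred,truth equal-length numeric vectors (length >= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @return a correlation in `[-1, 1]`.
#' @export
profileAccuracy <- function(pred, truth, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(pred) != length(truth)) stop("profile length mismatch")
  if (length(pred) < 3L) stop("profiles must have length >= 3")
  if (sd(pred) == 0 || sd(truth) == 0) {
    warning("constant profile: accuracy defined as 0")
    return(0)
  }
  cor(pred, truth, method = method)
}

# cache of exact Spearman null distributions, keyed by n
.nullCache <- new.env(parent = emptyenv())

# all permutations of 1..n, one per row
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- sub
    rest[rest >= i] <- rest[rest >= i] + 1L
    out[rows, -1L] <- rest
  }
  out
}

#' Exact null distribution of the Spearman correlation
#'
#' All `n!` Spearman correlations between the identity ranking `1..n` and
#' every ordering of `n` untied ranks. Cached per `n`; refused for
#' `n > 10` where enumeration blows up.
#'
#' @param n profile length (3..10).
#' @return numeric vector of length `n!`.
#' @export
spearmanNullDist <- function(n) {
  if (n < 3L || n > 10L)
    stop("exact enumeration supported for 3 <= n <= 10")
  key <- as.character(n)
  if (!is.null(.nullCache[[key]])) return(.nullCache[[key]])
  P <- .permutations(n)
  id <- matrix(seq_len(n), nrow(P), n, byrow = TRUE)
  r <- 1 - 6 * rowSums((P - id)^2) / (n * (n^2 - 1))
  .nullCache[[key]] <- r
  r
}

#' One-sided p-value of a profile correlation
#'
#' Upper-tail probability that a random ordering of the profile attains a
#' correlation at least as large as `r`. `mode = "exact"` enumerates all
#' `n!` orderings under the Spearman rank null (defined for
#' `method = "spearman"` and `n <= 10`, as used for the 8-timepoint time
#' profiles). `mode = "asymptotic"` uses the one-sided t approximation
#' with `n - 2` degrees of freedom (used for the 50-gene gene profiles
#' and for Pearson variants).
#'
#' @param r observed correlation.
#' @param n profile length (>= 3).
#' @param method `"spearman"` or `"pearson"`.
#' @param mode `"exact"` or `"asymptotic"`.
#' @return one-sided p-value in `(0, 1]`.
#' @export
profilePValue <- function(r, n, method = c("spearman", "pearson"),
                          mode = c("exact", "asymptotic")) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (n < 3L) stop("p-value needs profile length >= 3")
  if (is.na(r)) return(1)
  if (mode == "exact") {
    if (method != "spearman")
      stop("exact enumeration is defined on the Spearman rank null")
    if (n > 10L)
      stop("exact enumeration refused for n > 10 (combinatorial blow-up)")
    null <- spearmanNullDist(n)
    return(mean(null >= r - 1e-12))
  }
  if (abs(r) >= 1) return(if (r > 0) .Machine$double.xmin else 1)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  max(pt(tstat, df = n - 2, lower.tail = FALSE), .Machine$double.xmin)
}

#' Choose an evaluation variant
#'
#' The official challenge evaluation is `evalConfig("rank", "spearman")`;
#' the three alternatives vary the transform and the correlation.
#'
#' @param transform `"rank"` (per-timepoint rank transform before
#'   scoring) or `"value"` (raw values).
#' @param correlation `"spearman"` or `"pearson"`.
#' @param baseline optional named per-gene numeric vector subtracted from
#'   both prediction and truth before any transform (e.g. wild-type t = 0
#'   values, to score relative induction); default none.
#' @return an [EvalConfig-class].
#' @export
evalConfig <- function(transform = c("rank", "value"),
                       correlation = c("spearman", "pearson"),
                       baseline = NULL) {
  new("EvalConfig", transform = match.arg(transform),
      correlation = match.arg(correlation), baseline = baseline)
}

setMethod("show", "EvalConfig", function(object) {
  cat(sprintf("EvalConfig: %s expression data, %s correlation%s\n",
              object@transform, object@correlation,
              if (is.null(object@baseline)) ""
              else ", per-gene baseline subtracted"))
})

.profileStats <- function(P, Tr, margin, correlation, nMode) {
  idx <- seq_len(dim(P)[margin])
  acc <- numeric(length(idx)); pv <- numeric(length(idx))
  for (ii in idx) {
    p <- if (margin == 1L) P[ii, ] else P[, ii]
    tr <- if (margin == 1L) Tr[ii, ] else Tr[, ii]
    if (sd(p) == 0 || sd(tr) == 0) {
      warning("constant profile encountered: accuracy 0, p-value 1")
      acc[ii] <- 0; pv[ii] <- 1
    } else {
      acc[ii] <- cor(p, tr, method = correlation)
      acc[ii] <- min(1, max(-1, acc[ii]))
      pv[ii] <- profilePValue(acc[ii], length(p), method = correlation,
                              mode = nMode)
    }
  }
  list(acc = acc, p = pv)
}

# geometric mean computed in log space to avoid underflow
.geomMean <- function(p) exp(mean(log(pmax(p, .Machine$double.xmin))))

#' Score predictions against gold-standard values
#'
#' Computes the full challenge report: per-timepoint gene-profile
#' accuracies (correlation across targets at each timepoint) and per-gene
#' time-profile accuracies (correlation across timepoints for each
#' target), their one-sided p-values, overall accuracies (arithmetic
#' means), overall p-values (geometric means, in log space) and the
#' significance score `-0.5 * log10(pG * pT)`.
#'
#' Under `transform = "rank"` both matrices are rank-transformed per
#' timepoint first; time profiles are then rows of the rank matrices, as
#' in the official evaluation. P-value modes: exact enumeration for
#' Spearman profiles of length <= 10, the t approximation otherwise.
#'
#' @param pred a [PredictionResult-class] or target x timepoint matrix.
#' @param truth gold-standard matrix, congruent with `pred`.
#' @param config an [EvalConfig-class]; default the official evaluation.
#' @return an [EvaluationReport-class].
#' @examples
#' fx <- makeFixture("tiny")
#' rep <- evaluate(goldStandard(fx$truth), goldStandard(fx$truth))
#' evaluationScore(rep)  # perfect prediction
#' @export
evaluate <- function(pred, truth, config = evalConfig()) {
  P <- if (is(pred, "PredictionResult")) pred@values else as.matrix(pred)
  Tm <- as.matrix(truth)
  if (!all(dim(P) == dim(Tm)))
    stop("prediction and truth have different shapes")
  if (!is.null(rownames(P)) && !is.null(rownames(Tm)) &&
      !identical(rownames(P), rownames(Tm)))
    stop("prediction and truth gene orders differ")
  if (!is.null(config@baseline)) {
    b <- config@baseline[rownames(P)]
    if (any(is.na(b))) stop("baseline is missing some target genes")
    P <- P - b; Tm <- Tm - b
  }
  if (config@transform == "rank") {
    P <- rankTransform(P)
    Tm <- rankTransform(Tm)
  }
  corM <- config@correlation
  nGene <- nrow(P); nTime <- ncol(P)
  geneMode <- if (corM == "spearman" && nGene <= 10L) "exact" else "asymptotic"
  timeMode <- if (corM == "spearman" && nTime <= 10L) "exact" else "asymptotic"
  gp <- .profileStats(P, Tm, 2L, corM, geneMode)  # across genes, per timepoint
  tp <- .profileStats(P, Tm, 1L, corM, timeMode)  # across timepoints, per gene
  pG <- .geomMean(gp$p); pT <- .geomMean(tp$p)
  new("EvaluationReport",
      geneAccuracies = setNames(gp$acc, colnames(P)),
      genePValues = setNames(gp$p, colnames(P)),
      timeAccuracies = setNames(tp$acc, rownames(P)),
      timePValues = setNames(tp$p, rownames(P)),
      overallGeneAccuracy = mean(gp$acc), overallGenePValue = pG,
      overallTimeAccuracy = mean(tp$acc), overallTimePValue = pT,
      score = -0.5 * log10(pG * pT), config = config,
      pvalueModes = c(gene = geneMode, time = timeMode))
}

#' @rdname evaluationScore
#' @param x an [EvaluationReport-class].
#' @return the overall significance score.
#' @export
setMethod("evaluationScore", "EvaluationReport", function(x) x@score)

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport (", object@config@transform, "/",
      object@config@correlation, ")\n", sep = "")
  cat(sprintf("  gene-profile accuracy: %.3f (p = %.2e, %s)\n",
              object@overallGeneAccuracy, object@overallGenePValue,
              object@pvalueModes["gene"]))
  cat(sprintf("  time-profile accuracy: %.3f (p = %.2e, %s)\n",
              object@overallTimeAccuracy, object@overallTimePValue,
              object@pvalueModes["time"]))
  cat(sprintf("  score: %.2f\n", object@score))
})
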