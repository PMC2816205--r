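#' Euclidean distance between two genes within one strain
#'
#' The per-strain distance d_s(i, j): the Euclidean distance between the
#' replicate-mean timepoint profiles of genes `i` and `j` in strain `s`
#' (or between replicate-concatenated profiles with
#' `replicates = "concat"`). Reading a masked operand is an error.
#'
#' @param x a [StrainExperiment-class].
#' @param i,j gene identifiers.
#' @param strain strain label.
#' @param replicates `"mean"` (default) averages replicates before the
#'   distance; `"concat"` treats replicates as extra profile coordinates.
#' @return a non-negative scalar.
#' @export
strainDistance <- function(x, i, j, strain, replicates = c("mean", "concat")) {
  replicates <- match.arg(replicates)
  for (g in c(i, j)) {
    if (!g %in% rownames(x)) stop("unknown gene: ", g)
    if (x@mask[g, strain])
      stop("gene '", g, "' is masked in strain '", strain, "'")
  }
  m <- .strainProfiles(x, strain, replicates)
  sqrt(sum((m[i, ] - m[j, ])^2))
}

# genes x coordinates profile matrix for one strain (mask not applied)
.strainProfiles <- function(x, strain, replicates = "mean") {
  if (replicates == "mean")
    return(strainMatrix(x, strain, masked = "reveal"))
  cd <- SummarizedExperiment::colData(x)
  sel <- which(as.character(cd$strain) == strain)
  sel <- sel[order(cd$time[sel], cd$replicate[sel])]
  SummarizedExperiment::assay(x)[, sel, drop = FALSE]
}

#' Combined gene-gene distance matrix over the complete strains
#'
#' The matrix D of the prediction method: D[i, j] is the Euclidean distance
#' between the profiles of genes i and j concatenated across all strains
#' with complete data (every strain except the prediction strain).
#' Equivalently, `sqrt(sum_s d_s(i, j)^2)` over the complete strains.
#'
#' Because D only involves the complete strains it is unaffected by
#' masking, and can be computed once and reused across holdout repeats.
#'
#' @param x a [StrainExperiment-class].
#' @param exclude strain left out of the concatenation; defaults to the
#'   prediction strain and must equal it.
#' @param replicates passed to the per-strain profile extraction; `"mean"`
#'   (default) or `"concat"`.
#' @return symmetric gene x gene matrix with zero diagonal and gene ids as
#'   dimnames.
#' @export
combinedDistances <- function(x, exclude = predictionStrain(x),
                              replicates = c("mean", "concat")) {
  replicates <- match.arg(replicates)
  if (!identical(exclude, predictionStrain(x)))
    stop("'exclude' must be the prediction strain ('",
         predictionStrain(x), "')")
  complete <- setdiff(strains(x), exclude)
  if (length(complete) < 1L)
    stop("at least one complete strain is required")
  prof <- do.call(cbind, lapply(complete, .strainProfiles,
                                x = x, replicates = replicates))
  D <- as.matrix(dist(prof, method = "euclidean"))
  dimnames(D) <- list(rownames(x), rownames(x))
  D
}
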