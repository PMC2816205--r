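#' Construct a StrainExperiment
#'
#' Builds the central data container from a 4-dimensional array of
#' expression values indexed (gene, strain, timepoint, replicate).
#' Values are expected to be normalized, log-scale expression (RMA-style);
#' the package never re-normalizes them.
#'
#' @param values numeric array `gene x strain x timepoint x replicate`
#'   (a 3-d array is promoted to one replicate). Dimnames, if present,
#'   are overridden by the explicit arguments below.
#' @param geneIds character vector of unique gene identifiers.
#' @param strains character vector of strain labels.
#' @param timepoints strictly increasing numeric vector, in minutes.
#' @param predictionStrain label of the strain in which targets will be
#'   masked and predicted.
#' @param mask optional logical `gene x strain` matrix of held-out cells
#'   (default: nothing masked). Masked cells are allowed only in the
#'   prediction strain.
#' @return A [StrainExperiment-class] object.
#' @examples
#' vals <- array(rnorm(4 * 2 * 3 * 2), dim = c(4, 2, 3, 2))
#' se <- StrainExperiment(vals, paste0("g", 1:4), c("wt", "mut"),
#'                        c(0, 10, 20), predictionStrain = "mut")
#' strains(se)
#' @export
StrainExperiment <- function(values, geneIds, strains, timepoints,
                             predictionStrain, mask = NULL) {
  if (length(dim(values)) == 3L)
    dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 4L)
  d <- dim(values)
  if (d[1] != length(geneIds) || d[2] != length(strains) ||
      d[3] != length(timepoints))
    stop("dimensions of 'values' do not match geneIds/strains/timepoints")
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifiers: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  nRep <- d[4]
  cd <- expand.grid(replicate = seq_len(nRep), time = timepoints,
                    strain = strains, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  cd <- cd[, c("strain", "time", "replicate")]
  # column order: strain-major, then time, then replicate
  mat <- matrix(aperm(values, c(1L, 4L, 3L, 2L)), nrow = d[1])
  colnames(mat) <- sprintf("%s.t%g.r%d", cd$strain, cd$time, cd$replicate)
  rownames(mat) <- geneIds
  cd$strain <- factor(cd$strain, levels = strains)
  if (is.null(mask)) {
    mask <- matrix(FALSE, d[1], d[2],
                   dimnames = list(geneIds, strains))
  } else {
    mask <- as.matrix(mask)
    dimnames(mask) <- list(geneIds, strains)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(cd, row.names = colnames(mat))
  )
  new("StrainExperiment", se, mask = mask,
      predictionStrain = predictionStrain)
}

#' Accessors for StrainExperiment
#'
#' `strains()` returns the ordered strain labels, `timePoints()` the
#' timepoints in minutes, `predictionStrain()` the strain flagged for
#' prediction, `nReplicates()` the replicate count, and `maskMatrix()`
#' the logical gene x strain matrix of held-out cells.
#'
#' @param x a [StrainExperiment-class].
#' @name StrainExperiment-accessors
#' @aliases strains timePoints predictionStrain nReplicates maskMatrix
NULL

#' @rdname StrainExperiment-accessors
#' @export
setMethod("strains", "StrainExperiment", function(x)
  levels(SummarizedExperiment::colData(x)$strain))

#' @rdname StrainExperiment-accessors
#' @export
setMethod("timePoints", "StrainExperiment", function(x)
  sort(unique(SummarizedExperiment::colData(x)$time)))

#' @rdname StrainExperiment-accessors
#' @export
setMethod("predictionStrain", "StrainExperiment", function(x)
  x@predictionStrain)

#' @rdname StrainExperiment-accessors
#' @export
setMethod("nReplicates", "StrainExperiment", function(x)
  max(SummarizedExperiment::colData(x)$replicate))

#' @rdname StrainExperiment-accessors
#' @export
setMethod("maskMatrix", "StrainExperiment", function(x) x@mask)

setMethod("show", "StrainExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf(
    "StrainExperiment: %d genes x %d strains x %d timepoints x %d replicate(s)\n",
    nrow(object), nlevels(cd$strain), length(unique(cd$time)),
    max(cd$replicate)))
  cat("  strains:", paste(levels(cd$strain), collapse = ", "),
      sprintf(" (prediction strain: %s)\n", object@predictionStrain))
  cat("  timepoints (min):", paste(sort(unique(cd$time)), collapse = ", "),
      "\n")
  nm <- sum(object@mask)
  cat(sprintf("  masked: %d gene(s) in %s\n", nm,
              if (nm) object@predictionStrain else "none"))
})

#' Replicate-mean expression matrix for one strain
#'
#' Returns the gene x timepoint matrix of one strain, averaging replicates.
#' The mask is honored: by default masked genes' rows are `NA`; with
#' `masked = "error"` any masked gene triggers an error; `masked = "reveal"`
#' returns the stored values and exists for scoring held-out truth and for
#' tests only.
#'
#' @param x a [StrainExperiment-class].
#' @param strain strain label.
#' @param masked one of `"na"`, `"error"`, `"reveal"`.
#' @return numeric matrix, genes x timepoints.
#' @export
strainMatrix <- function(x, strain, masked = c("na", "error", "reveal")) {
  masked <- match.arg(masked)
  if (!strain %in% strains(x)) stop("unknown strain: ", strain)
  cd <- SummarizedExperiment::colData(x)
  sel <- which(as.character(cd$strain) == strain)
  v <- SummarizedExperiment::assay(x)[, sel, drop = FALSE]
  tps <- timePoints(x)
  out <- matrix(0, nrow(x), length(tps),
                dimnames = list(rownames(x), sprintf("t%g", tps)))
  tcol <- cd$time[sel]
  for (j in seq_along(tps))
    out[, j] <- rowMeans(v[, tcol == tps[j], drop = FALSE])
  m <- x@mask[, strain]
  if (any(m)) {
    if (masked == "error")
      stop("masked genes in strain '", strain, "': ",
           paste(head(rownames(x)[m], 5), collapse = ", "),
           if (sum(m) > 5) ", ..." else "")
    if (masked == "na") out[m, ] <- NA_real_
  }
  out
}

#' Expression profile of one gene in one strain
#'
#' Replicate-mean timepoint vector. Reading a masked (gene, strain) cell
#' is a contract violation and errors.
#'
#' @param x a [StrainExperiment-class].
#' @param gene gene identifier.
#' @param strain strain label.
#' @return named numeric vector over timepoints.
#' @export
exprProfile <- function(x, gene, strain) {
  if (!gene %in% rownames(x)) stop("unknown gene: ", gene)
  if (!strain %in% strains(x)) stop("unknown strain: ", strain)
  if (x@mask[gene, strain])
    stop("gene '", gene, "' is masked in strain '", strain,
         "': held-out values are not readable")
  strainMatrix(x, strain, masked = "reveal")[gene, ]
}

#' Collapse replicates by averaging
#'
#' Returns a dataset with one replicate, each cell the per-(gene, strain,
#' timepoint) mean of the input replicates. The mask is preserved. This is
#' the default preprocessing before any distance or regression computation;
#' replicates can instead be kept as extra profile coordinates via the
#' `replicates = "concat"` option of [combinedDistances()].
#'
#' @param x a [StrainExperiment-class].
#' @param method only `"mean"` is defined.
#' @return a [StrainExperiment-class] with `nReplicates(x) == 1`.
#' @rdname collapseReplicates
#' @export
setMethod("collapseReplicates", "StrainExperiment", function(x, method = "mean") {
  method <- match.arg(method, "mean")
  if (nReplicates(x) == 1L) return(x)
  arr <- .valuesArray(x)
  m <- apply(arr, c(1L, 2L, 3L), mean)
  dim(m) <- c(dim(arr)[1:3], 1L)
  StrainExperiment(m, rownames(x), strains(x), timePoints(x),
                   predictionStrain = predictionStrain(x), mask = x@mask)
})

# gene x strain x timepoint x replicate array view (mask ignored; internal)
.valuesArray <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  sl <- strains(x); tps <- timePoints(x); nr <- nReplicates(x)
  v <- SummarizedExperiment::assay(x)
  ord <- order(match(as.character(cd$strain), sl),
               match(cd$time, tps), cd$replicate)
  arr <- array(v[, ord, drop = FALSE],
               dim = c(nrow(x), nr, length(tps), length(sl)))
  aperm(arr, c(1L, 4L, 3L, 2L))
}

#' Create a target set
#'
#' @param genes character vector of gene identifiers to predict (non-empty,
#'   no duplicates).
#' @param strain label of the prediction strain.
#' @return a [TargetSet-class].
#' @rdname TargetSet
#' @export
TargetSet <- function(genes, strain) {
  new("TargetSet", genes = as.character(genes), strain = strain)
}

#' @rdname TargetSet
#' @param x a `TargetSet`.
#' @export
setMethod("targetGenes", "TargetSet", function(x) x@genes)

setMethod("show", "TargetSet", function(object) {
  cat(sprintf("TargetSet: %d gene(s) to predict in strain '%s'\n",
              length(object@genes), object@strain))
})

#' Mask target genes in the prediction strain
#'
#' Returns a copy of the dataset whose mask is set for every
#' (target gene, prediction strain) cell. Stored numeric values are not
#' altered, but masked cells become unreadable through [strainMatrix()]
#' (default mode) and [exprProfile()]. Masking is cumulative: cells already
#' masked stay masked.
#'
#' @param x a [StrainExperiment-class].
#' @param targets a [TargetSet-class]; its strain must equal
#'   `predictionStrain(x)`.
#' @return a masked [StrainExperiment-class].
#' @export
maskTargets <- function(x, targets) {
  stopifnot(is(targets, "TargetSet"))
  validObject(targets)
  unknown <- setdiff(targets@genes, rownames(x))
  if (length(unknown))
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  if (!identical(targets@strain, predictionStrain(x)))
    stop("targets designate strain '", targets@strain,
         "' but the prediction strain is '", predictionStrain(x), "'")
  m <- x@mask
  m[targets@genes, targets@strain] <- TRUE
  x@mask <- m
  validObject(x)
  x
}

#' Genes currently masked in the prediction strain
#'
#' @param x a [StrainExperiment-class].
#' @return character vector of gene ids (possibly empty).
#' @export
maskedGenes <- function(x) {
  rownames(x)[x@mask[, predictionStrain(x)]]
}
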