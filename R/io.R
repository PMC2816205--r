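#' Read a multi-strain expression table
#'
#' Reads a tab-delimited expression matrix whose first column holds gene
#' identifiers and whose remaining columns are named `strain.tNN.rK`
#' (strain label, timepoint in minutes, replicate index), e.g.
#' `gat1d.t45.r2`. The strain label may itself contain dots; the `tNN`/`rK`
#' suffixes are parsed from the right. All combinations of
#' strain x timepoint x replicate must be present.
#'
#' Cells that cannot be parsed as numbers raise an error naming the row and
#' column; they are never silently dropped. `NA` cells are rejected unless
#' they cover complete (gene, prediction strain) rows, in which case they
#' are interpreted as the held-out mask.
#'
#' @param path file path.
#' @param predictionStrain label of the prediction strain (must be one of
#'   the strains in the header).
#' @return a validated [StrainExperiment-class].
#' @seealso [writeExpressionTable()]
#' @export
readExpressionTable <- function(path, predictionStrain) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expression table needs a gene column and data columns")
  geneIds <- raw[[1L]]
  dup <- unique(geneIds[duplicated(geneIds)])
  if (length(dup))
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  hdr <- colnames(raw)[-1L]
  m <- regmatches(hdr, regexec("^(.+)\\.t([0-9.]+)\\.r([0-9]+)$", hdr))
  bad <- hdr[lengths(m) == 0L]
  if (length(bad))
    stop("column name(s) not of the form strain.tNN.rK: ",
         paste(bad, collapse = ", "))
  strain <- vapply(m, `[`, "", 2L)
  time <- as.numeric(vapply(m, `[`, "", 3L))
  repl <- as.integer(vapply(m, `[`, "", 4L))
  strains <- unique(strain)
  tps <- sort(unique(time))
  nRep <- max(repl)
  need <- expand.grid(strain = strains, time = tps, rep = seq_len(nRep),
                      stringsAsFactors = FALSE)
  key <- paste(strain, time, repl)
  missing <- !(paste(need$strain, need$time, need$rep) %in% key)
  if (any(missing) || anyDuplicated(key))
    stop("incomplete or duplicated strain/time/replicate columns; missing: ",
         paste(head(paste0(need$strain[missing], ".t", need$time[missing],
                           ".r", need$rep[missing]), 5), collapse = ", "))
  vals <- matrix(NA_real_, length(geneIds), length(hdr))
  for (j in seq_along(hdr)) {
    col <- raw[[j + 1L]]
    isNA <- is.na(col) | col == "NA" | col == ""
    num <- suppressWarnings(as.numeric(col))
    badRow <- which(is.na(num) & !isNA)
    if (length(badRow))
      stop(sprintf("non-numeric cell '%s' at row %d (gene %s), column '%s'",
                   col[badRow[1]], badRow[1], geneIds[badRow[1]], hdr[j]))
    vals[, j] <- num
  }
  arr <- array(NA_real_, dim = c(length(geneIds), length(strains),
                                 length(tps), nRep))
  for (j in seq_along(hdr)) {
    arr[, match(strain[j], strains), match(time[j], tps), repl[j]] <- vals[, j]
  }
  if (!predictionStrain %in% strains)
    stop("prediction strain '", predictionStrain, "' not found; strains: ",
         paste(strains, collapse = ", "))
  # NA cells must form complete (gene, prediction strain) blocks -> mask
  naCell <- apply(is.na(arr), c(1L, 2L), any)
  allNA <- apply(is.na(arr), c(1L, 2L), all)
  if (any(naCell & !allNA))
    stop("missing values outside complete held-out rows; refusing to impute")
  if (any(naCell[, strains != predictionStrain]))
    stop("missing values in a strain other than the prediction strain")
  mask <- allNA
  # keep construction valid: masked cells carry placeholder zeros
  arr[is.na(arr)] <- 0
  StrainExperiment(arr, geneIds, strains, tps,
                   predictionStrain = predictionStrain, mask = mask)
}

#' Write a StrainExperiment as a TSV expression table
#'
#' Inverse of [readExpressionTable()]: writes a tab-delimited table with a
#' `gene` column and one `strain.tNN.rK` column per sample. Masked cells
#' are written as `NA`, so held-out values never leak into the file.
#'
#' @param x a [StrainExperiment-class].
#' @param path output file path.
#' @export
writeExpressionTable <- function(x, path) {
  cd <- SummarizedExperiment::colData(x)
  v <- SummarizedExperiment::assay(x)
  maskedCols <- x@mask[, as.character(cd$strain), drop = FALSE]
  v[maskedCols] <- NA_real_
  ch <- matrix(ifelse(is.na(v), "NA", sprintf("%.17g", v)), nrow(v),
               dimnames = list(NULL, colnames(v)))
  df <- data.frame(gene = rownames(x), ch, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a target-gene list
#'
#' Plain text, one gene identifier per line; blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @param strain prediction strain label for the resulting target set.
#' @return a [TargetSet-class].
#' @export
readTargetList <- function(path, strain) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  TargetSet(lines, strain)
}

#' Write predictions as TSV
#'
#' Tab-delimited table: `gene` column followed by one column per timepoint,
#' headed `t<minutes>`; genes appear in target-set order. Round-trips
#' losslessly with [readPredictions()] at full double precision.
#'
#' @param pred a [PredictionResult-class] or a gene x timepoint matrix with
#'   dimnames.
#' @param path output file path.
#' @export
writePredictions <- function(pred, path) {
  v <- if (is(pred, "PredictionResult")) pred@values else pred
  if (!is.matrix(v) || nrow(v) == 0L || ncol(v) == 0L)
    stop("empty prediction matrix")
  ch <- matrix(sprintf("%.17g", v), nrow(v),
               dimnames = list(NULL, colnames(v)))
  df <- data.frame(gene = rownames(v), ch, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @return `readPredictions` returns the gene x timepoint numeric matrix.
#' @export
readPredictions <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Export a neighbor graph as an edge list
#'
#' Writes one row per (target, neighbor) pair with the combined distance,
#' for inspection in external tools.
#'
#' @param graph a [NeighborGraph-class].
#' @param path output TSV path.
#' @export
writeEdgeList <- function(graph, path) {
  stopifnot(is(graph, "NeighborGraph"))
  rows <- do.call(rbind, lapply(names(graph@neighbors), function(g) {
    nb <- graph@neighbors[[g]]
    if (!length(nb)) return(NULL)
    data.frame(gene_a = g, gene_b = nb, distance = graph@distances[[g]])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
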