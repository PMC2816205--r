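#' k nearest neighbors of a gene
#'
#' Returns the `k` genes with smallest combined distance to `i`, excluding
#' `i` itself and all `forbidden` genes (prediction targets are never used
#' as neighbors of other prediction targets). Neighbors are sorted by
#' ascending distance; equidistant genes are ordered by their position in
#' the dataset's gene order, so results are deterministic.
#'
#' @param D symmetric distance matrix with gene-id dimnames, from
#'   [combinedDistances()].
#' @param i target gene identifier.
#' @param k neighborhood size (default 10, the setting of record for the
#'   standard KNN model).
#' @param forbidden character vector of genes excluded from neighbor
#'   lists (typically all prediction targets).
#' @return character vector of `k` gene ids, with the distances attached
#'   as the `"distances"` attribute.
#' @export
knnNeighbors <- function(D, i, k = 10, forbidden = character()) {
  genes <- rownames(D)
  if (!i %in% genes) stop("unknown gene: ", i)
  if (k < 1L) stop("k must be at least 1")
  elig <- setdiff(genes, c(i, forbidden))
  if (length(elig) < k)
    stop("k = ", k, " exceeds the ", length(elig), " eligible genes")
  d <- D[i, elig]
  ord <- order(d)[seq_len(k)]   # order() is stable: ties keep gene order
  nb <- elig[ord]
  attr(nb, "distances") <- unname(d[ord])
  nb
}

# plain top-K list of each gene (no forbidden filtering, self excluded):
# n x K matrix of gene indices, rows in gene order
.topKMatrix <- function(D, K) {
  n <- nrow(D)
  if (K >= n) stop("K must be smaller than the number of genes")
  t(vapply(seq_len(n), function(i) {
    o <- order(D[i, ])
    o[o != i][seq_len(K)]
  }, integer(K)))
}

#' Mutual nearest neighbors of a target gene
#'
#' Neighborhood of the improved KNN (KNN*) model: the mutual set
#' M_i = \{ j : j is in i's plain top-K list and i is in j's plain top-K
#' list \}, united with the fallback set T_i of i's `fallback` nearest
#' eligible genes (so no target is left without neighbors). Mutual
#' membership is tested on the plain top-K lists over all genes; forbidden
#' genes are removed from the result. Defaults K = 20 with a top-3
#' fallback, the settings of record.
#'
#' @inheritParams knnNeighbors
#' @param K size of the top-K lists defining mutual membership.
#' @param fallback guaranteed number of nearest eligible neighbors.
#' @param topK optional precomputed matrix from the internal plain top-K
#'   construction; used to amortize work across many targets.
#' @return character vector of neighbor gene ids, sorted by ascending
#'   distance to `i`, with distances attached as an attribute.
#' @export
mutualKnnNeighbors <- function(D, i, K = 20, fallback = 3,
                               forbidden = character(), topK = NULL) {
  genes <- rownames(D)
  if (!i %in% genes) stop("unknown gene: ", i)
  if (fallback < 1L || K < fallback)
    stop("need K >= fallback >= 1")
  if (is.null(topK)) topK <- .topKMatrix(D, K)
  ii <- match(i, genes)
  mine <- topK[ii, ]
  mutual <- mine[vapply(mine, function(j) ii %in% topK[j, ], logical(1))]
  mutual <- setdiff(genes[mutual], forbidden)
  fb <- knnNeighbors(D, i, k = fallback, forbidden = forbidden)
  nb <- union(mutual, fb)
  d <- D[i, nb]
  ord <- order(d, match(nb, genes))
  nb <- nb[ord]
  attr(nb, "distances") <- unname(d[ord])
  nb
}

#' Dense-subnetwork neighbors of a target gene
#'
#' Neighborhood of the dense subnet model: build the global K-nearest-
#' neighbor graph over all genes (an undirected edge joins a and b if
#' either lists the other in its plain top-K), take the subgraph induced
#' by i's `K` nearest eligible genes, rank those candidates by their
#' degree within the subgraph (edges to `i` itself are not counted), and
#' keep the `m` best. Degree ties are broken by smaller distance to `i`,
#' then by dataset gene order. Defaults K = 20, m = 10, the settings of
#' record.
#'
#' @inheritParams mutualKnnNeighbors
#' @param m final neighborhood size.
#' @return character vector of `m` gene ids (ordered by decreasing
#'   within-subnet degree under the tie rules), distances attached.
#' @export
denseSubnetNeighbors <- function(D, i, K = 20, m = 10,
                                 forbidden = character(), topK = NULL) {
  genes <- rownames(D)
  if (K < m) stop("need K >= m")
  elig <- setdiff(genes, c(i, forbidden))
  if (length(elig) < m)
    stop("fewer than m = ", m, " eligible candidate genes")
  if (is.null(topK)) topK <- .topKMatrix(D, K)
  cand <- knnNeighbors(D, i, k = min(K, length(elig)), forbidden = forbidden)
  ci <- match(cand, genes)
  # undirected adjacency within the candidate set
  deg <- vapply(seq_along(ci), function(a) {
    sum(vapply(ci[-a], function(b)
      b %in% topK[ci[a], ] || ci[a] %in% topK[b, ], logical(1)))
  }, integer(1))
  d <- D[i, cand]
  ord <- order(-deg, d, match(cand, genes))[seq_len(m)]
  nb <- cand[ord]
  attr(nb, "distances") <- unname(d[ord])
  nb
}

#' Build a NeighborGraph for a set of targets
#'
#' Convenience wrapper running one of the three neighbor constructions for
#' every target gene, with all targets forbidden as neighbors.
#'
#' @param D distance matrix from [combinedDistances()].
#' @param targets a [TargetSet-class] or character vector of gene ids.
#' @param method `"knn"`, `"mutual"` or `"dense"`.
#' @param k,K,fallback,m construction parameters (see the per-construction
#'   functions for defaults and meaning).
#' @param forbidden genes barred from all neighbor lists; defaults to the
#'   targets themselves.
#' @return a [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(D, targets,
                               method = c("knn", "mutual", "dense"),
                               k = 10, K = 20, fallback = 3, m = 10,
                               forbidden = NULL) {
  method <- match.arg(method)
  tg <- if (is(targets, "TargetSet")) targetGenes(targets) else targets
  if (is.null(forbidden)) forbidden <- tg
  topK <- if (method != "knn") .topKMatrix(D, K) else NULL
  nbs <- lapply(tg, function(g) switch(method,
    knn = knnNeighbors(D, g, k = k, forbidden = forbidden),
    mutual = mutualKnnNeighbors(D, g, K = K, fallback = fallback,
                                forbidden = forbidden, topK = topK),
    dense = denseSubnetNeighbors(D, g, K = K, m = m,
                                 forbidden = forbidden, topK = topK)))
  params <- switch(method,
    knn = list(k = k),
    mutual = list(K = K, fallback = fallback),
    dense = list(K = K, m = m))
  new("NeighborGraph",
      neighbors = setNames(lapply(nbs, as.vector), tg),
      distances = setNames(lapply(nbs, attr, "distances"), tg),
      method = method, params = params)
}

setMethod("show", "NeighborGraph", function(object) {
  sizes <- lengths(object@neighbors)
  cat(sprintf("NeighborGraph (%s): %d target(s), neighborhood sizes %d-%d (mean %.1f)\n",
              object@method, length(sizes), min(sizes), max(sizes),
              mean(sizes)))
  cat("  params:", paste(names(object@params), unlist(object@params),
                         sep = " = ", collapse = ", "), "\n")
})
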