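# Independent brute-force reimplementations of every core operation.
# These deliberately use plain loops and first-principles formulas, never
# the package's own code paths, so agreement is a real cross-check.

oracle_strain_distance <- function(a, b) {
  s <- 0
  for (t in seq_along(a)) s <- s + (a[[t]] - b[[t]])^2
  sqrt(s)
}

# profiles: list of gene x coordinate matrices, one per complete strain
oracle_combined_distance <- function(profiles) {
  n <- nrow(profiles[[1]])
  D <- matrix(0, n, n, dimnames = list(rownames(profiles[[1]]),
                                       rownames(profiles[[1]])))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- 0
    for (m in profiles) v <- v + sum((m[i, ] - m[j, ])^2)
    D[i, j] <- sqrt(v)
  }
  D
}

# full sort; ties by gene (column) position
oracle_knn <- function(D, i, k, forbidden = character()) {
  genes <- rownames(D)
  cand <- genes[!(genes %in% c(i, forbidden))]
  d <- D[i, cand]
  ord <- order(d, match(cand, genes))
  cand[ord][seq_len(k)]
}

oracle_plain_topK <- function(D, g, K) {
  genes <- rownames(D)
  cand <- setdiff(genes, g)
  d <- D[g, cand]
  cand[order(d, match(cand, genes))][seq_len(K)]
}

oracle_mutual <- function(D, i, K, fallback, forbidden = character()) {
  genes <- rownames(D)
  mine <- oracle_plain_topK(D, i, K)
  mutual <- character(0)
  for (j in mine) {
    if (i %in% oracle_plain_topK(D, j, K)) mutual <- c(mutual, j)
  }
  mutual <- mutual[!(mutual %in% forbidden)]
  fb <- oracle_knn(D, i, fallback, forbidden)
  nb <- union(mutual, fb)
  nb[order(D[i, nb], match(nb, genes))]
}

oracle_dense <- function(D, i, K, m, forbidden = character()) {
  genes <- rownames(D)
  topK <- lapply(setNames(genes, genes), oracle_plain_topK, D = D, K = K)
  cand <- oracle_knn(D, i, min(K, sum(!(genes %in% c(i, forbidden)))),
                     forbidden)
  deg <- integer(length(cand))
  for (a in seq_along(cand)) for (b in seq_along(cand)) {
    if (a == b) next
    if (cand[b] %in% topK[[cand[a]]] || cand[a] %in% topK[[cand[b]]])
      deg[a] <- deg[a] + 1L
  }
  ord <- order(-deg, D[i, cand], match(cand, genes))
  cand[ord][seq_len(m)]
}

# mean over a neighbor set of the prediction-strain replicate-mean values
oracle_neighbor_average <- function(obs, neighborSets, tg) {
  t(sapply(tg, function(g) colMeans(obs[neighborSets[[g]], , drop = FALSE])))
}

# OLS by normal equations (independent of qr-based fitting)
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

# Monte-Carlo upper-tail permutation p for Spearman, untied null
oracle_mc_pvalue <- function(r, n, draws = 1e5) {
  hits <- 0L
  base <- seq_len(n)
  for (b in seq_len(draws)) {
    rp <- oracle_pearson(base, sample(n))
    if (rp >= r - 1e-12) hits <- hits + 1L
  }
  hits / draws
}

# a small random StrainExperiment with no planted structure
random_dataset <- function(nGenes, nStrains = 3, nT = 4, nRep = 1,
                           seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(nGenes * nStrains * nT * nRep),
               dim = c(nGenes, nStrains, nT, nRep))
  StrainExperiment(arr, sprintf("g%03d", seq_len(nGenes)),
                   paste0("s", seq_len(nStrains)),
                   seq_len(nT) * 10 - 10,
                   predictionStrain = paste0("s", nStrains))
}
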