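test_that("per-strain distance is the Euclidean distance over timepoints", {
  ds <- random_dataset(6, nStrains = 2, nT = 8, seed = 11)
  # identical vectors -> 0
  expect_equal(strainDistance(ds, "g001", "g001", "s1"), 0)
  # constant unit difference over 8 timepoints -> sqrt(8)
  arr <- array(0, dim = c(2, 2, 8, 1)); arr[2, , , ] <- 1
  ds2 <- StrainExperiment(arr, c("a", "b"), c("s1", "s2"),
                          c(0, 10, 20, 30, 45, 60, 90, 120),
                          predictionStrain = "s2")
  expect_equal(strainDistance(ds2, "a", "b", "s1"), sqrt(8))
  # random profiles match the loop-based oracle
  for (pair in list(c("g001", "g002"), c("g003", "g006"))) {
    expect_equal(strainDistance(ds, pair[1], pair[2], "s1"),
                 oracle_strain_distance(exprProfile(ds, pair[1], "s1"),
                                        exprProfile(ds, pair[2], "s1")))
  }
  # masked operand refuses
  dsm <- maskTargets(ds, TargetSet("g001", "s2"))
  expect_error(strainDistance(dsm, "g001", "g002", "s2"), "masked")
})

test_that("combined distance concatenates the complete strains", {
  # two complete strains with per-strain distances 3 and 4 -> combined 5
  arr <- array(0, dim = c(2, 3, 4, 1))
  arr[2, 1, 1, 1] <- 3
  arr[2, 2, 1, 1] <- 4
  ds <- StrainExperiment(arr, c("a", "b"), c("s1", "s2", "s3"),
                         c(0, 10, 20, 30), predictionStrain = "s3")
  expect_equal(strainDistance(ds, "a", "b", "s1"), 3)
  expect_equal(strainDistance(ds, "a", "b", "s2"), 4)
  expect_equal(combinedDistances(ds)["a", "b"], 5)

  # duplicated gene across all complete strains -> D = 0 to its twin
  ds3 <- random_dataset(10, nStrains = 3, nT = 5, seed = 13)
  a <- SummarizedExperiment::assay(ds3)
  cd <- SummarizedExperiment::colData(ds3)
  a["g002", cd$strain != "s3"] <- a["g001", cd$strain != "s3"]
  SummarizedExperiment::assay(ds3) <- a
  expect_equal(combinedDistances(ds3)["g001", "g002"], 0)

  expect_error(combinedDistances(ds3, exclude = "s1"), "prediction strain")
})

test_that("combined distance equals the concatenate-then-norm oracle", {
  ds <- random_dataset(30, nStrains = 4, nT = 6, nRep = 2, seed = 17)
  D <- combinedDistances(ds)
  profiles <- lapply(c("s1", "s2", "s3"), strainMatrix, x = ds)
  expect_lt(max(abs(D - oracle_combined_distance(profiles))), 1e-12)
  # metric axioms
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (l in c(1, 7, 23))
    expect_lte(D[i, j], D[i, l] + D[l, j] + 1e-9)
  # concatenated replicates also match an oracle over 2x-long profiles
  Dc <- combinedDistances(ds, replicates = "concat")
  prof <- lapply(c("s1", "s2", "s3"), function(s)
    coexpred:::.strainProfiles(ds, s, "concat"))
  expect_lt(max(abs(Dc - oracle_combined_distance(prof))), 1e-12)
})

test_that("knn neighbor lists match a full-sort oracle and its contracts", {
  ds <- random_dataset(50, seed = 19)
  D <- combinedDistances(ds)
  # an exact duplicate is the 1-nearest neighbor
  D2 <- D; D2["g003", ] <- D2["g010", ]; D2[, "g003"] <- D2[, "g010"]
  D2["g003", "g010"] <- D2["g010", "g003"] <- 0; diag(D2) <- 0
  expect_identical(as.vector(knnNeighbors(D2, "g010", k = 1)), "g003")
  # forbidding the nearest promotes the second-nearest
  nb2 <- knnNeighbors(D, "g001", k = 2)
  expect_identical(as.vector(knnNeighbors(D, "g001", k = 1,
                                          forbidden = nb2[1])), nb2[2])
  # full agreement with the oracle, order included
  for (g in c("g001", "g025", "g050"))
    expect_identical(as.vector(knnNeighbors(D, g, k = 10)),
                     oracle_knn(D, g, 10))
  # distances attribute is sorted ascending and length k
  nb <- knnNeighbors(D, "g007", k = 10)
  expect_length(nb, 10)
  expect_false(is.unsorted(attr(nb, "distances")))
  expect_error(knnNeighbors(D, "g001", k = 50), "eligible")
})

test_that("mutual knn neighbors match the brute-force mutual-membership oracle", {
  ds <- random_dataset(60, seed = 23)
  D <- combinedDistances(ds)
  forb <- c("g001", "g002", "g003")
  for (g in forb) {
    expect_identical(
      as.vector(mutualKnnNeighbors(D, g, K = 20, fallback = 3,
                                   forbidden = setdiff(forb, g))),
      oracle_mutual(D, g, 20, 3, setdiff(forb, g)))
  }
  # two mutually nearest duplicates contain each other
  D2 <- D
  D2["g010", "g020"] <- D2["g020", "g010"] <- 0
  expect_true("g020" %in% mutualKnnNeighbors(D2, "g010", K = 5))
  expect_true("g010" %in% mutualKnnNeighbors(D2, "g020", K = 5))
  # a gene in nobody's top-K falls back to exactly 3 neighbors
  D3 <- D
  D3["g030", ] <- D3[, "g030"] <- 1e6
  D3["g030", "g030"] <- 0
  # keep its own view asymmetric: it still has ranked neighbors, but no
  # reciprocation is possible
  nb <- mutualKnnNeighbors(D3, "g030", K = 20, fallback = 3)
  expect_length(nb, 3)
  expect_identical(as.vector(nb), oracle_knn(D3, "g030", 3))
})

test_that("dense-subnet neighbors pick the densely connected candidates", {
  # planted structure: 10 candidates form a clique (mutually nearest), the
  # other 10 candidates are near only the target, so they are isolated in
  # the induced subgraph; filler genes keep everyone's top-20 lists away
  # from the loose candidates
  n <- 60
  genes <- sprintf("g%03d", 1:n)
  clique <- genes[2:11]; loose <- genes[12:21]; others <- genes[22:60]
  D <- matrix(200, n, n, dimnames = list(genes, genes))
  D[clique, clique] <- 0.5
  D["g001", c(clique, loose)] <- D[c(clique, loose), "g001"] <- 1
  D[clique, others] <- D[others, clique] <- 10
  D[loose, others] <- D[others, loose] <- 2
  D[others, others] <- 3
  diag(D) <- 0
  nb <- denseSubnetNeighbors(D, "g001", K = 20, m = 10)
  expect_setequal(as.vector(nb), clique)
  # ... and the oracle agrees on random instances
  ds <- random_dataset(80, seed = 31)
  Dr <- combinedDistances(ds)
  for (g in c("g001", "g040", "g080"))
    expect_identical(as.vector(denseSubnetNeighbors(Dr, g, K = 20, m = 10)),
                     oracle_dense(Dr, g, 20, 10))
  # all-equal degrees (candidate set is a 20-clique) fall back to the m
  # nearest by distance, then gene order
  gn <- genes[1:30]; Cset <- gn[2:21]; Fset <- gn[22:30]
  Du <- matrix(5, 30, 30, dimnames = list(gn, gn))
  Du[Cset, Cset] <- 1
  Du[Fset, Fset] <- 1
  Du["g001", Cset] <- Du[Cset, "g001"] <- seq(0.1, 2.0, by = 0.1)
  Du["g001", Fset] <- Du[Fset, "g001"] <- 4
  diag(Du) <- 0
  nbu <- denseSubnetNeighbors(Du, "g001", K = 20, m = 5)
  expect_identical(as.vector(nbu), oracle_knn(Du, "g001", 5))
  expect_error(denseSubnetNeighbors(Dr, "g001", K = 20, m = 10,
                                    forbidden = rownames(Dr)[-(1:5)]),
               "eligible")
})

test_that("neighbor graphs keep targets out and respect size contracts", {
  ds <- random_dataset(70, seed = 37)
  D <- combinedDistances(ds)
  tg <- c("g001", "g010", "g020", "g030")
  for (method in c("knn", "mutual", "dense")) {
    g <- buildNeighborGraph(D, tg, method = method)
    expect_named(g@neighbors, tg)
    for (t in tg)
      expect_length(intersect(g@neighbors[[t]], tg), 0)
    sizes <- lengths(g@neighbors)
    if (method == "knn") expect_true(all(sizes == 10))
    if (method == "mutual") expect_true(all(sizes >= 3 & sizes <= 23))
    if (method == "dense") expect_true(all(sizes == 10))
  }
})

test_that("removing a gene outside every top-(K+1) list leaves neighbor sets unchanged", {
  K <- 8
  found <- FALSE
  for (seed in 41:50) {
    ds <- random_dataset(60, seed = seed)
    D <- combinedDistances(ds)
    inTop <- unique(as.vector(coexpred:::.topKMatrix(D, K + 1)))
    outside <- setdiff(seq_len(nrow(D)), inTop)
    outside <- setdiff(rownames(D)[outside], "g001")
    if (!length(outside)) next
    found <- TRUE
    drop <- outside[1]
    Dr <- D[rownames(D) != drop, colnames(D) != drop]
    for (fun in list(
      function(DD) knnNeighbors(DD, "g001", k = K),
      function(DD) mutualKnnNeighbors(DD, "g001", K = K, fallback = 3),
      function(DD) denseSubnetNeighbors(DD, "g001", K = K, m = 4))) {
      expect_identical(as.vector(fun(D)), as.vector(fun(Dr)))
    }
    break
  }
  expect_true(found)
})
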