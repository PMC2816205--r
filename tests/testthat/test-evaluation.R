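test_that("rank transform follows the induction-first convention with midranks", {
  expect_equal(unname(rankTransform(cbind(c(3.2, 1.1, 2.0)))[, 1]),
               c(1, 3, 2))
  expect_equal(unname(rankTransform(cbind(c(5, 5, 1)))[, 1]),
               c(1.5, 1.5, 3))
  set.seed(65)
  col <- rnorm(50)
  expect_setequal(rankTransform(cbind(col))[, 1], 1:50)
  # each timepoint ranked independently
  m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(unname(rankTransform(m)),
               cbind(c(3, 2, 1), c(1, 2, 3)))
})

test_that("profile accuracy matches textbook correlation formulas", {
  set.seed(67)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(profileAccuracy(x, x), 1.0)
  expect_equal(profileAccuracy(x, rank(-rank(x))), -1.0)
  expect_lt(abs(profileAccuracy(x, y, "pearson") - oracle_pearson(x, y)),
            1e-12)
  expect_lt(abs(profileAccuracy(x, y, "spearman") - oracle_spearman(x, y)),
            1e-12)
  expect_error(profileAccuracy(x, y[1:5]), "mismatch")
  expect_warning(acc <- profileAccuracy(rep(1, 5), y[1:5]), "constant")
  expect_equal(acc, 0)
})

test_that("Spearman equals Pearson on ranks and survives monotone transforms", {
  set.seed(69)
  for (i in 1:20) {
    x <- sample(100, 12); y <- sample(100, 12)  # untied
    expect_equal(profileAccuracy(x, y, "spearman"),
                 profileAccuracy(rank(x), rank(y), "pearson"),
                 tolerance = 1e-12)
    expect_equal(profileAccuracy(exp(x / 20), y, "spearman"),
                 profileAccuracy(x, y, "spearman"), tolerance = 1e-12)
  }
})

test_that("exact permutation p-values hit closed-form anchors", {
  # perfect agreement among 8! orderings: p = 1/40320
  expect_equal(profilePValue(1, 8, "spearman", "exact"), 1 / factorial(8))
  # r = -1: every ordering does at least as well
  expect_equal(profilePValue(-1, 8, "spearman", "exact"), 1.0)
  expect_error(profilePValue(0.5, 12, "spearman", "exact"), "n > 10")
  expect_error(profilePValue(0.5, 8, "pearson", "exact"), "Spearman")
  # null distribution is symmetric and normalized
  null <- spearmanNullDist(6)
  expect_length(null, factorial(6))
  expect_equal(mean(null), 0, tolerance = 1e-12)
})

test_that("exact enumeration agrees with Monte-Carlo permutation sampling", {
  set.seed(71)
  x <- sample(10, 5)
  r <- profileAccuracy(x, seq_len(5), "spearman")
  pExact <- profilePValue(r, 5, "spearman", "exact")
  draws <- 1e5
  pMC <- oracle_mc_pvalue(r, 5, draws)
  se <- sqrt(pExact * (1 - pExact) / draws)
  expect_lt(abs(pMC - pExact), 3 * se)
})

test_that("perfect predictions score accuracy 1 under all four evaluation variants", {
  set.seed(73)
  truth <- matrix(rnorm(50 * 8), 50, 8,
                  dimnames = list(sprintf("g%02d", 1:50), paste0("t", 1:8)))
  for (tr in c("rank", "value")) for (co in c("spearman", "pearson")) {
    rep <- evaluate(truth, truth, evalConfig(tr, co))
    expect_equal(rep@overallGeneAccuracy, 1.0)
    expect_equal(rep@overallTimeAccuracy, 1.0)
    expect_true(all(rep@genePValues <= 1 & rep@genePValues > 0))
    expect_gt(rep@score, 0)
  }
  # official variant: time-profile p at the exact enumeration floor
  repOff <- evaluate(truth, truth, evalConfig("rank", "spearman"))
  expect_equal(unname(repOff@timePValues), rep(1 / factorial(8), 50))
})

test_that("gene-profile accuracy is identical under the three rank-invariant variants", {
  set.seed(75)
  truth <- matrix(rnorm(30 * 8), 30, 8,
                  dimnames = list(sprintf("g%02d", 1:30), paste0("t", 1:8)))
  pred <- truth + matrix(rnorm(30 * 8, sd = 0.7), 30, 8)
  accs <- sapply(list(evalConfig("rank", "spearman"),
                      evalConfig("rank", "pearson"),
                      evalConfig("value", "spearman")),
                 function(cfg) evaluate(pred, truth, cfg)@geneAccuracies)
  expect_equal(accs[, 1], accs[, 2], tolerance = 1e-12)
  expect_equal(accs[, 1], accs[, 3], tolerance = 1e-12)
  # the value/pearson variant is genuinely different
  accP <- evaluate(pred, truth, evalConfig("value", "pearson"))@geneAccuracies
  expect_false(isTRUE(all.equal(accs[, 1], accP)))
})

test_that("the report aggregates exactly as its per-profile entries prescribe", {
  set.seed(77)
  truth <- matrix(rnorm(20 * 8), 20, 8,
                  dimnames = list(sprintf("g%02d", 1:20), paste0("t", 1:8)))
  pred <- truth[, ] + rnorm(160, sd = 1.2)
  rep <- evaluate(pred, truth)
  # recompute everything from primitives
  Pr <- rankTransform(pred); Tr <- rankTransform(truth)
  gAcc <- sapply(1:8, function(j) oracle_pearson(rank(Pr[, j]), rank(Tr[, j])))
  gP <- sapply(1:8, function(j)
    profilePValue(gAcc[j], 20, "spearman", "asymptotic"))
  tAcc <- sapply(1:20, function(i) oracle_pearson(rank(Pr[i, ]), rank(Tr[i, ])))
  tP <- sapply(1:20, function(i)
    profilePValue(tAcc[i], 8, "spearman", "exact"))
  expect_equal(unname(rep@geneAccuracies), gAcc, tolerance = 1e-12)
  expect_equal(unname(rep@genePValues), gP, tolerance = 1e-12)
  expect_equal(unname(rep@timeAccuracies), tAcc, tolerance = 1e-12)
  expect_equal(unname(rep@timePValues), tP, tolerance = 1e-12)
  expect_equal(rep@overallGeneAccuracy, mean(gAcc))
  expect_equal(rep@overallGenePValue, exp(mean(log(gP))))
  expect_equal(rep@score,
               -0.5 * log10(exp(mean(log(gP))) * exp(mean(log(tP)))))
})

test_that("the score decreases monotonically in either overall p-value", {
  score <- function(pG, pT) -0.5 * log10(pG * pT)
  expect_gt(score(1e-6, 1e-2), score(1e-5, 1e-2))
  expect_gt(score(1e-6, 1e-3), score(1e-6, 1e-2))
})

test_that("baseline subtraction re-scores induction relative to the reference", {
  set.seed(79)
  truth <- matrix(rnorm(10 * 8), 10, 8,
                  dimnames = list(sprintf("g%02d", 1:10), paste0("t", 1:8)))
  offset <- setNames(rnorm(10, sd = 5), rownames(truth))
  pred <- truth + matrix(rnorm(80, sd = 0.5), 10, 8)
  based <- suppressWarnings(
    evaluate(pred, truth, evalConfig("rank", "spearman", baseline = offset)))
  manual <- suppressWarnings(
    evaluate(pred - offset, truth - offset, evalConfig("rank", "spearman")))
  expect_equal(based@geneAccuracies, manual@geneAccuracies)
  expect_equal(based@score, manual@score)
  # baseline-subtracted scoring differs from plain scoring on gene profiles
  plain <- suppressWarnings(evaluate(pred, truth, evalConfig("rank", "spearman")))
  expect_false(isTRUE(all.equal(plain@geneAccuracies, based@geneAccuracies)))
  expect_error(evaluate(pred, truth,
                        evalConfig("rank", "spearman",
                                   baseline = offset[1:3])),
               "missing")
})

test_that("degenerate (constant) profiles score 0 with p 1", {
  truth <- matrix(rnorm(40), 5, 8,
                  dimnames = list(paste0("g", 1:5), paste0("t", 1:8)))
  pred <- truth
  pred[2, ] <- 3.14   # constant time profile
  expect_warning(rep <- evaluate(pred, truth, evalConfig("value", "spearman")),
                 "constant")
  expect_equal(unname(rep@timeAccuracies[2]), 0)
  expect_equal(unname(rep@timePValues[2]), 1)
})
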