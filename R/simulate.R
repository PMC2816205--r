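#' Configure the synthetic multi-strain time-course generator
#'
#' The generator emulates the structure of a four-strain yeast
#' perturbation time course: genes organised in co-expression modules
#' whose latent time profiles are smooth random walks, strain-specific
#' scalings/offsets of those profiles (whole-module shifts, as expected
#' when a transcription factor regulating the pathway is deleted),
#' gene-level loadings and offsets, per-replicate additive Gaussian noise
#' on a log-RMA-like scale, and a fraction of background genes with
#' independent profiles. Prediction targets are drawn preferentially from
#' the modules most strongly perturbed in the prediction strain, since
#' challenge targets are the genes most perturbed by the treatment.
#'
#' Latent profiles are scaled to unit standard deviation, so `noiseSd` is
#' the noise level relative to the signal (default 0.1).
#'
#' @param nGenes total gene count.
#' @param nTargets number of prediction targets.
#' @param strains strain labels; first is the wild-type reference.
#' @param predictionStrain strain in which targets are masked.
#' @param timepoints sampling times in minutes (default the challenge's
#'   0, 10, 20, 30, 45, 60, 90, 120).
#' @param nReplicates biological replicates per sample (default 2).
#' @param moduleSizeRange inclusive range of module sizes; each module's
#'   size is drawn uniformly from it (default 10-30, so the optimal KNN
#'   neighborhood lies in the 10-30 region).
#' @param smoothness number of adjacent-averaging passes applied to each
#'   latent random walk (default 2).
#' @param strainEffectSd sd of the per-(module, strain) scale (around 1)
#'   and offset (around 0) effects (default 0.3).
#' @param targetBoost exponent weighting target sampling towards modules
#'   with strong prediction-strain perturbation (default 2; 0 = uniform).
#' @param noiseSd replicate noise sd relative to the unit signal sd
#'   (default 0.1).
#' @param backgroundFraction fraction of genes with independent,
#'   module-free profiles (default 0.15).
#' @param loadingSd sd of per-gene loadings around 1 (default 0.2; 0
#'   makes all module members identical up to offsets).
#' @param offsetSd sd of per-gene baseline offsets (default 0.3).
#' @param baseline global additive constant mimicking log2 RMA intensity
#'   (default 8).
#' @param seed integer seed; every stochastic draw flows from this one
#'   stream.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nGenes = 6000, nTargets = 50,
                      strains = c("wt", "gat1d", "gcn4d", "leu3d"),
                      predictionStrain = "gat1d",
                      timepoints = c(0, 10, 20, 30, 45, 60, 90, 120),
                      nReplicates = 2, moduleSizeRange = c(10, 30),
                      smoothness = 2, strainEffectSd = 0.3,
                      targetBoost = 2, noiseSd = 0.1,
                      backgroundFraction = 0.15, loadingSd = 0.2,
                      offsetSd = 0.3, baseline = 8, seed = 1) {
  new("SimConfig",
      nGenes = as.integer(nGenes), nTargets = as.integer(nTargets),
      strains = strains, predictionStrain = predictionStrain,
      timepoints = as.numeric(timepoints),
      nReplicates = as.integer(nReplicates),
      moduleSizeRange = as.integer(moduleSizeRange),
      smoothness = as.integer(smoothness),
      strainEffectSd = strainEffectSd, targetBoost = targetBoost,
      noiseSd = noiseSd, backgroundFraction = backgroundFraction,
      loadingSd = loadingSd, offsetSd = offsetSd,
      baseline = baseline, seed = as.integer(seed))
}

# smooth unit-sd random-walk time profile
.latentProfile <- function(nT, smoothness) {
  z <- cumsum(rnorm(nT))
  for (s in seq_len(smoothness)) {
    z <- (c(z[1], z[-nT]) + z + c(z[-1], z[nT])) / 3
  }
  s <- sd(z)
  if (s == 0) return(z - mean(z))
  (z - mean(z)) / s
}

#' Generate a synthetic multi-strain dataset
#'
#' Runs the generator described in [simConfig()]. The returned dataset is
#' already masked for the sampled targets; the [SimTruth-class] carries
#' the module assignment, per-strain latent profiles, and the
#' gold-standard values of the masked cells (the replicate-mean generated
#' values, exactly as they were before masking).
#'
#' @param cfg a [SimConfig-class].
#' @return a list with elements `dataset` ([StrainExperiment-class]),
#'   `targets` ([TargetSet-class]) and `truth` ([SimTruth-class]).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 100, nTargets = 5,
#'                                     moduleSizeRange = c(5, 10)))
#' sim$dataset
#' @export
simulateExpression <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  nT <- length(cfg@timepoints)
  nS <- length(cfg@strains)
  nBg <- round(cfg@backgroundFraction * cfg@nGenes)
  nMod <- cfg@nGenes - nBg

  lo <- cfg@moduleSizeRange[1]; hi <- cfg@moduleSizeRange[2]
  sizes <- integer(0)
  while (sum(sizes) < nMod) {
    sizes <- c(sizes, lo + sample.int(hi - lo + 1L, 1L) - 1L)
  }
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - nMod)
  if (sizes[length(sizes)] < 2L) {  # fold a too-small remainder into the previous module
    sizes[length(sizes) - 1L] <- sizes[length(sizes) - 1L] + sizes[length(sizes)]
    sizes <- sizes[-length(sizes)]
  }
  modules <- c(rep(seq_along(sizes), sizes), rep(0L, nBg))

  psIdx <- match(cfg@predictionStrain, cfg@strains)
  # per-module latent profiles: wild type is the base; other strains are
  # scaled/offset versions of it
  latent <- vector("list", length(sizes))
  perturb <- numeric(length(sizes))
  for (m in seq_along(sizes)) {
    base <- .latentProfile(nT, cfg@smoothness)
    prof <- matrix(0, nS, nT, dimnames = list(cfg@strains, NULL))
    prof[1L, ] <- base
    for (s in seq_len(nS)[-1L]) {
      gam <- 1 + rnorm(1, sd = cfg@strainEffectSd)
      del <- rnorm(1, sd = cfg@strainEffectSd)
      prof[s, ] <- gam * base + del
    }
    latent[[m]] <- prof
    perturb[m] <- sqrt(mean((prof[psIdx, ] - prof[1L, ])^2))
  }

  loading <- if (cfg@loadingSd > 0)
    rnorm(cfg@nGenes, 1, cfg@loadingSd) else rep(1, cfg@nGenes)
  offset <- if (cfg@offsetSd > 0)
    rnorm(cfg@nGenes, 0, cfg@offsetSd) else rep(0, cfg@nGenes)

  geneIds <- sprintf("g%04d", seq_len(cfg@nGenes))
  arr <- array(0, dim = c(cfg@nGenes, nS, nT, cfg@nReplicates))
  for (g in seq_len(cfg@nGenes)) {
    if (modules[g] > 0L) {
      prof <- latent[[modules[g]]]
    } else {
      # background: independent base profile, same strain-effect model
      base <- .latentProfile(nT, cfg@smoothness)
      prof <- matrix(0, nS, nT)
      prof[1L, ] <- base
      for (s in seq_len(nS)[-1L]) {
        prof[s, ] <- (1 + rnorm(1, sd = cfg@strainEffectSd)) * base +
          rnorm(1, sd = cfg@strainEffectSd)
      }
    }
    mu <- loading[g] * prof + offset[g] + cfg@baseline
    for (r in seq_len(cfg@nReplicates)) {
      noise <- if (cfg@noiseSd > 0)
        matrix(rnorm(nS * nT, sd = cfg@noiseSd), nS, nT) else 0
      arr[g, , , r] <- mu + noise
    }
  }

  # targets: module genes only, weighted towards perturbed modules
  w <- perturb[modules[modules > 0L]]^cfg@targetBoost
  eligible <- which(modules > 0L)
  if (length(eligible) < cfg@nTargets)
    stop("nTargets exceeds total module membership")
  targetIdx <- sort(sample(eligible, cfg@nTargets,
                           prob = if (cfg@targetBoost > 0) w else NULL))
  targets <- TargetSet(geneIds[targetIdx], cfg@predictionStrain)

  ds <- StrainExperiment(arr, geneIds, cfg@strains, cfg@timepoints,
                         predictionStrain = cfg@predictionStrain)
  gold <- strainMatrix(ds, cfg@predictionStrain,
                       masked = "reveal")[geneIds[targetIdx], , drop = FALSE]
  ds <- maskTargets(ds, targets)
  truth <- new("SimTruth", modules = setNames(modules, geneIds),
               latent = latent, gold = gold)
  list(dataset = ds, targets = targets, truth = truth)
}

#' Gold-standard values of a simulated dataset
#'
#' @param truth a [SimTruth-class].
#' @return target-gene x timepoint matrix of the masked cells' true
#'   (replicate-mean) values.
#' @export
goldStandard <- function(truth) truth@gold

#' Module assignment of a simulated dataset
#'
#' @param truth a [SimTruth-class].
#' @return named integer vector; 0 marks background genes.
#' @export
moduleAssignment <- function(truth) truth@modules

setMethod("show", "SimTruth", function(object) {
  nm <- max(object@modules)
  cat(sprintf(
    "SimTruth: %d gene(s) in %d module(s) (+%d background), %d gold-standard target(s)\n",
    sum(object@modules > 0L), nm, sum(object@modules == 0L),
    nrow(object@gold)))
})

#' Named simulation presets
#'
#' `"tiny"` (30 genes, 3 targets, modules of 5-8 genes) supports fast
#' oracle-style tests; `"dream-like"` (6000 genes, 50 targets, 4 strains,
#' 8 timepoints, 2 replicates, noise sd 0.1) mirrors the scale of the
#' challenge data; `"heterogeneous"` (500 genes, 25 targets, module sizes
#' 3-40, noise sd 0.3) creates the mixed-pathway-size regime in which
#' adaptive neighborhoods should pay off.
#'
#' @param name preset name.
#' @param seed integer seed (default 1).
#' @return as [simulateExpression()].
#' @export
makeFixture <- function(name = c("tiny", "dream-like", "heterogeneous"),
                        seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    "tiny" = simConfig(nGenes = 30, nTargets = 3,
                       moduleSizeRange = c(5, 8),
                       backgroundFraction = 0.1, seed = seed),
    "dream-like" = simConfig(seed = seed),
    "heterogeneous" = simConfig(nGenes = 500, nTargets = 25,
                                moduleSizeRange = c(3, 40),
                                noiseSd = 0.3, seed = seed))
  simulateExpression(cfg)
}
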