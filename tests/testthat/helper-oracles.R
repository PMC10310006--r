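# Independent oracles and small fixture builders shared across tests.

# O(n^2) pair-enumeration concordance oracle: for every uncensored subject
# i and every j observed later, count agreement of the predicted survival
# ordering (f = -risk), per the strict-inequality definition; optional
# half-credit for prediction ties.
bruteForceCIndex <- function(risk, time, event, ties = "strict") {
  num <- 0; den <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    for (j in seq_along(time)) {
      if (time[j] > time[i]) {
        den <- den + 1
        if (-risk[j] > -risk[i]) num <- num + 1
        else if (ties == "half" && risk[j] == risk[i]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no admissible pairs")
  num / den
}

# random censored survival instance for property tests
randomSurvivalInstance <- function(n, tieProb = 0.2) {
  time <- round(rexp(n, 1), digits = if (runif(1) < tieProb) 1 else 4)
  event <- rbinom(n, 1, 0.6)
  risk <- if (runif(1) < tieProb) sample(seq(-1, 1, 0.25), n, TRUE)
          else rnorm(n)
  list(risk = risk, time = time, event = event)
}

# tiny encoder/dalan configs for fast structural tests
tinyEncoderConfig <- function(inputShape = c(8L, 8L, 1L)) {
  encoderConfig("small_cnn", embeddingDim = 8L, inputShape = inputShape,
                channels = c(3L, 4L, 5L))
}

tinyDalanConfig <- function(inputShape = c(8L, 8L, 1L), ...) {
  dalanConfig(encoder = tinyEncoderConfig(inputShape), nHeads = 2L,
              lstmLayers = 2L, mlpHidden = 5L, bagSampleSize = 3L,
              inferenceDraws = 2L, ...)
}

tinyProfile <- function(epochs = 2L) {
  list(stage1 = list(epochs = epochs, lr = 1e-3, weightDecay = 1e-5,
                     batchSize = 16L, lrDecay = 1, clipNorm = 1),
       bag = list(epochs = epochs, lr = 1e-3, weightDecay = 1e-4,
                  batchSize = 8L, lrDecay = 1, clipNorm = 1))
}

# small digit cohort for tests that need real bags
tinyCohort <- function(n = 20, seed = 7, ...) {
  buildSimulation(simulationConfig("two_roi_digit", nPatients = n,
                                   seed = seed, ...))
}

# gradient-check helpers: enumerate leaf paths of a parameter tree and
# perturb single coordinates
leafPaths <- function(tree, prefix = list()) {
  if (!is.list(tree)) return(list(prefix))
  out <- list()
  for (i in seq_along(tree)) {
    key <- if (!is.null(names(tree)) && nzchar(names(tree)[i]))
      names(tree)[i] else i
    out <- c(out, leafPaths(tree[[i]], c(prefix, list(key))))
  }
  out
}

getLeaf <- function(tree, path) {
  for (k in path) tree <- tree[[k]]
  tree
}

perturbLeaf <- function(tree, path, ii, delta) {
  if (length(path) == 1L) {
    tree[[path[[1]]]][ii] <- tree[[path[[1]]]][ii] + delta
    return(tree)
  }
  tree[[path[[1]]]] <- perturbLeaf(tree[[path[[1]]]], path[-1], ii, delta)
  tree
}
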