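#' Named training hyperparameter profiles
#'
#' Each profile bundles the stage-1 (ROI-level fine-tuning) and bag-level
#' training settings: epochs, learning rate, weight decay (decoupled,
#' AdamW), batch size, per-epoch exponential learning-rate decay factor,
#' and the gradient-clipping max norm.
#'
#' * `"sim_digit"`: the full-scale simulation profile (bag stage: 100
#'   epochs, lr 5e-5, weight decay 1e-3, batch 32, decay 0.995).
#' * `"histology"`: the real-slide profile (bag stage: 50 epochs, lr 1e-6,
#'   weight decay 1e-2, batch 32).
#' * `"desk"`: a scaled-down CPU profile for the small backbone on 28 x 28
#'   inputs (bag stage: 30 epochs, lr 1e-3, weight decay 1e-4, batch 32,
#'   decay 0.995; stage 1: 20 epochs, lr 1e-3, batch 64). Used by the test
#'   suite and the bundled experiments.
#'
#' Both simulation-scale profiles share the stage-1 settings of 30 epochs,
#' lr 1e-5, weight decay 1e-6, batch 64.
#'
#' @param name profile name.
#' @return list with elements `stage1` and `bag`, each containing `epochs`,
#'   `lr`, `weightDecay`, `batchSize`, `lrDecay`, `clipNorm`.
#' @export
trainingProfile <- function(name = c("desk", "sim_digit", "histology")) {
  name <- match.arg(name)
  stage1Full <- list(epochs = 30L, lr = 1e-5, weightDecay = 1e-6,
                     batchSize = 64L, lrDecay = 1, clipNorm = 1)
  switch(name,
    sim_digit = list(
      stage1 = stage1Full,
      bag = list(epochs = 100L, lr = 5e-5, weightDecay = 1e-3,
                 batchSize = 32L, lrDecay = 0.995, clipNorm = 1)),
    histology = list(
      stage1 = stage1Full,
      bag = list(epochs = 50L, lr = 1e-6, weightDecay = 1e-2,
                 batchSize = 32L, lrDecay = 1, clipNorm = 1)),
    desk = list(
      stage1 = list(epochs = 20L, lr = 1e-3, weightDecay = 1e-5,
                    batchSize = 64L, lrDecay = 1, clipNorm = 1),
      bag = list(epochs = 30L, lr = 1e-3, weightDecay = 1e-4,
                 batchSize = 32L, lrDecay = 0.995, clipNorm = 1))
  )
}

#' Flatten patient bags into an ROI-level dataset
#'
#' Every ROI inherits its patient's observed time and event indicator (the
#' weak labelling used for stage-1 fine-tuning and for the naive
#' aggregation baselines).
#'
#' @param bagList list of [PatientBag-class].
#' @return list with `images` (list), `time`, `event`, `patientId`.
#' @export
roiDataset <- function(bagList) {
  images <- list(); time <- numeric(); event <- numeric(); pid <- character()
  for (b in bagList) {
    for (img in b@rois) {
      images[[length(images) + 1L]] <- img
      time <- c(time, b@time); event <- c(event, b@event)
      pid <- c(pid, b@patientId)
    }
  }
  list(images = images, time = time, event = event, patientId = pid)
}

#' Fine-tune the encoder on ROI-level survival data
#'
#' Stage 1 of the two-stage protocol: trains the weight-shared encoder
#' plus a temporary scalar Cox head on ROI-level data (each ROI labelled
#' with its patient's time and event), with training-time augmentation and
#' the Cox partial-likelihood loss formed within each minibatch. After
#' training, the front `frozenFraction` of encoder parameter groups is
#' marked frozen for subsequent bag-level training. The same routine
#' (without the freezing semantics) trains the scorer behind the naive
#' aggregation baselines; see [trainRoiCnn()].
#'
#' @param config an [encoderConfig()].
#' @param bagList training bags (list of [PatientBag-class]).
#' @param hyper stage-1 hyperparameters, e.g. `trainingProfile("desk")$stage1`.
#' @param augment apply training-time augmentation (default `TRUE`).
#' @param initParams optional initial parameter list (resume training).
#' @return a [RoiModel-class] with the frozen groups recorded.
#' @export
fineTuneRoiLevel <- function(config, bagList, hyper = trainingProfile()$stage1,
                             augment = TRUE, initParams = NULL) {
  ds <- roiDataset(bagList)
  if (all(ds$event == 0)) stop("all-censored dataset: Cox loss has no events")
  specs <- encoderSpecs(config)
  params <- if (is.null(initParams))
    list(encoder = encoderInit(config, specs),
         head = linearInit(config$embeddingDim, 1L))
    else initParams
  state <- adamWInit(params)
  n <- length(ds$images)
  lr <- hyper$lr
  hist <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = hyper$batchSize)) {
      idx <- ord[start:min(start + hyper$batchSize - 1L, n)]
      if (length(idx) < 2L) next
      ev <- ds$event[idx]
      if (sum(ev) == 0) {
        warning("skipping all-censored minibatch")
        next
      }
      imgs <- ds$images[idx]
      if (augment) imgs <- lapply(imgs, augmentImage)
      X <- stackImages(lapply(imgs, preprocess, config = config))
      fw <- encoderForward(X, params$encoder, specs, config$backbone)
      h <- linearForward(fw$E, params$head)
      tt <- ds$time[idx]
      losses <- c(losses, coxPartialLikelihood(as.vector(h), tt, ev))
      dh <- matrix(coxLossGradient(as.vector(h), tt, ev), ncol = 1L)
      hb <- linearBackward(dh, fw$E, params$head)
      eb <- encoderBackward(hb$dX, fw, params$encoder, specs, config$backbone)
      grads <- clipGradients(list(encoder = eb$grads, head = hb$grads),
                             hyper$clipNorm)$grads
      stepped <- adamWStep(params, grads, state, lr, hyper$weightDecay)
      params <- stepped$params
      state <- stepped$state
    }
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   lr = lr))
    lr <- lr * hyper$lrDecay
  }
  new("RoiModel", config = unclass(config), params = params,
      frozen = frozenGroups(config), history = hist)
}

#' Train the ROI-wise CNN Cox scorer for the aggregation baselines
#'
#' Identical architecture and training budget to stage-1 fine-tuning
#' ([fineTuneRoiLevel()]), so baseline comparisons isolate the aggregation
#' rule.
#'
#' @inheritParams fineTuneRoiLevel
#' @return a [RoiModel-class].
#' @export
trainRoiCnn <- function(config, bagList, hyper = trainingProfile()$stage1,
                        augment = TRUE) {
  fineTuneRoiLevel(config, bagList, hyper, augment = augment)
}

#' Predict ROI-level log-hazards
#'
#' Scores every image with the fitted ROI model (no sampling, no
#' augmentation; deterministic given the weights).
#'
#' @param model a [RoiModel-class].
#' @param images list of raw images.
#' @return numeric vector of log-hazards, one per image.
#' @export
predictRoiRisks <- function(model, images) {
  cfg <- structure(model@config, class = "encoderConfig")
  specs <- encoderSpecs(cfg)
  X <- stackImages(lapply(images, preprocess, config = cfg))
  fw <- encoderForward(X, model@params$encoder, specs, cfg$backbone)
  as.vector(linearForward(fw$E, model@params$head))
}
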