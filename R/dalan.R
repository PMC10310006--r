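#' DALAN model configuration
#'
#' Configures the patient-level aggregation network: a weight-shared CNN
#' encoder, two attention-LSTM blocks, and an MLP Cox head. Block 1 applies
#' multi-head self-attention to the embedding sequence; block 2 applies
#' co-attention whose query is the original CNN embedding sequence and
#' whose keys/values come from block 1's output. Each block feeds its
#' attended sequence through a two-stacked LSTM. The final representation
#' (last hidden state by default, mean pooling as an alternative) passes
#' through an MLP whose last fully-connected layer outputs the log-hazard
#' as a linear combination.
#'
#' @param encoder an [encoderConfig()].
#' @param nHeads attention heads (default 4; must divide the embedding
#'   width).
#' @param lstmLayers stacked LSTM layers per block (default 2).
#' @param mlpHidden hidden width of the Cox head (default 64).
#' @param bagSampleSize ROIs sampled with replacement per bag (default 10).
#' @param inferenceDraws independent ROI samplings averaged at inference
#'   (default 8).
#' @param scaleMode attention score scaling: `"sqrt"` (divide by the square
#'   root of the head width, default) or `"linear"` (divide by the head
#'   width).
#' @param summary `"last"` (final LSTM hidden state, default) or `"mean"`
#'   (mean over the output sequence).
#' @param useAttention,useLstm structural switches for the ablation
#'   variants (attention-only / LSTM-only architectures).
#' @return validated list of class `"dalanConfig"`.
#' @export
dalanConfig <- function(encoder = encoderConfig(),
                        nHeads = 4L, lstmLayers = 2L, mlpHidden = 64L,
                        bagSampleSize = 10L, inferenceDraws = 8L,
                        scaleMode = c("sqrt", "linear"),
                        summary = c("last", "mean"),
                        useAttention = TRUE, useLstm = TRUE) {
  scaleMode <- match.arg(scaleMode)
  summary <- match.arg(summary)
  stopifnot(bagSampleSize >= 1, lstmLayers >= 1, mlpHidden >= 1,
            inferenceDraws >= 1)
  if (useAttention && encoder$embeddingDim %% nHeads != 0L)
    stop("embeddingDim must be divisible by nHeads")
  if (!useAttention && !useLstm)
    stop("at least one of attention and LSTM must be enabled")
  structure(list(encoder = encoder, nHeads = as.integer(nHeads),
                 lstmLayers = as.integer(lstmLayers),
                 mlpHidden = as.integer(mlpHidden),
                 bagSampleSize = as.integer(bagSampleSize),
                 inferenceDraws = as.integer(inferenceDraws),
                 scaleMode = scaleMode, summary = summary,
                 useAttention = useAttention, useLstm = useLstm),
            class = "dalanConfig")
}

#' Initialize a DALAN model
#'
#' Fresh random weights, optionally seeding the encoder trunk from a
#' stage-1 fine-tuned [RoiModel-class]; in that case the ROI model's frozen
#' parameter groups carry over (its temporary scalar head is discarded).
#'
#' @param config a [dalanConfig()].
#' @param roiModel optional [RoiModel-class] providing the encoder trunk.
#' @param freeze honour the ROI model's frozen groups (default `TRUE`).
#' @return an untrained [DalanModel-class].
#' @export
initDalan <- function(config, roiModel = NULL, freeze = TRUE) {
  if (!inherits(config, "dalanConfig")) stop("config must be a dalanConfig")
  D <- config$encoder$embeddingDim
  specs <- encoderSpecs(config$encoder)
  encParams <- if (is.null(roiModel)) encoderInit(config$encoder, specs)
               else roiModel@params$encoder
  params <- list(encoder = encParams)
  if (config$useAttention) {
    params$attn1 <- mhaInit(D)
    params$attn2 <- mhaInit(D)
  }
  if (config$useLstm) {
    params$lstm1 <- lstmStackInit(D, D, config$lstmLayers)
    params$lstm2 <- lstmStackInit(D, D, config$lstmLayers)
  }
  params$mlp <- list(l1 = linearInit(D, config$mlpHidden),
                     l2 = linearInit(config$mlpHidden, 1L))
  frozen <- if (!is.null(roiModel) && freeze)
    paste0("encoder/", roiModel@frozen) else character(0)
  new("DalanModel", config = unclass(config), params = params,
      frozen = frozen,
      history = data.frame(epoch = integer(), loss = numeric(),
                           val_cindex = numeric(), lr = numeric()))
}

# ---- full network forward / backward ------------------------------------
# X: (B*N) x L image batch with row order r = b + (n-1)*B, so that
# array(E, c(B, N, D)) recovers the per-bag embedding sequences.

dalanForward <- function(X, B, N, params, config, specs) {
  enc <- encoderForward(X, params$encoder, specs, config$encoder$backbone)
  D <- config$encoder$embeddingDim
  Earr <- enc$E
  dim(Earr) <- c(B, N, D)
  a1 <- NULL; l1 <- NULL; a2 <- NULL; l2 <- NULL
  cur <- Earr
  if (config$useAttention) {
    a1 <- mhaForward(cur, cur, params$attn1, config$nHeads, config$scaleMode)
    cur <- a1$Y
  }
  if (config$useLstm) {
    l1 <- lstmForward(cur, params$lstm1)
    cur <- l1$H
  }
  H1 <- cur
  if (config$useAttention) {
    a2 <- mhaForward(Earr, H1, params$attn2, config$nHeads, config$scaleMode)
    cur <- a2$Y
  }
  if (config$useLstm) {
    l2 <- lstmForward(cur, params$lstm2)
    cur <- l2$H
  }
  S <- if (config$summary == "last") matrix(cur[, N, ], B)
       else matrix(apply(cur, c(1, 3), mean), B)
  m1 <- linearForward(S, params$mlp$l1)
  r1 <- reluForward(m1)
  out <- linearForward(r1, params$mlp$l2)
  list(logHazard = as.vector(out),
       cache = list(enc = enc, Earr = Earr, a1 = a1, l1 = l1, a2 = a2,
                    l2 = l2, H2 = cur, S = S, m1 = m1, r1 = r1,
                    B = B, N = N, D = D))
}

dalanBackward <- function(dLogHazard, fw, params, config, specs) {
  cc <- fw$cache
  B <- cc$B; N <- cc$N; D <- cc$D
  grads <- list()
  dOut <- matrix(dLogHazard, ncol = 1L)
  l2b <- linearBackward(dOut, cc$r1, params$mlp$l2)
  dM1 <- reluBackward(l2b$dX, cc$m1)
  l1b <- linearBackward(dM1, cc$S, params$mlp$l1)
  grads$mlp <- list(l1 = l1b$grads, l2 = l2b$grads)
  dH2 <- array(0, c(B, N, D))
  if (config$summary == "last") dH2[, N, ] <- l1b$dX
  else for (n in seq_len(N)) dH2[, n, ] <- l1b$dX / N
  dEarr <- array(0, c(B, N, D))
  cur <- dH2
  if (config$useLstm) {
    lb2 <- lstmBackward(cur, params$lstm2, cc$l2$caches)
    grads$lstm2 <- lb2$grads
    cur <- lb2$dX
  }
  if (config$useAttention) {
    ab2 <- mhaBackward(cur, params$attn2, cc$a2$cache)
    grads$attn2 <- ab2$grads
    dEarr <- dEarr + ab2$dXq     # co-attention query = raw embeddings
    cur <- ab2$dXc               # context gradient flows into block 1
  }
  if (config$useLstm) {
    lb1 <- lstmBackward(cur, params$lstm1, cc$l1$caches)
    grads$lstm1 <- lb1$grads
    cur <- lb1$dX
  }
  if (config$useAttention) {
    ab1 <- mhaBackward(cur, params$attn1, cc$a1$cache)
    grads$attn1 <- ab1$grads
    dEarr <- dEarr + ab1$dXq + ab1$dXc   # self-attention: both streams
  } else {
    dEarr <- dEarr + cur
  }
  dE <- dEarr; dim(dE) <- c(B * N, D)
  eb <- encoderBackward(dE, cc$enc, params$encoder, specs,
                        config$encoder$backbone)
  grads$encoder <- eb$grads
  grads[names(params)]  # align with parameter ordering for the optimizer
}

# assemble the (B*N) x L image matrix for a list of bags: sample
# bagSampleSize ROIs with replacement per bag, optionally augment, then
# preprocess; row order r = b + (n-1)*B
assembleBagBatch <- function(bagList, config, augment) {
  B <- length(bagList)
  N <- config$bagSampleSize
  cfg <- config$encoder
  L <- prod(cfg$inputShape)
  X <- matrix(0, B * N, L)
  for (b in seq_len(B)) {
    rois <- bagList[[b]]@rois
    pick <- sample.int(length(rois), N, replace = TRUE)
    for (n in seq_len(N)) {
      img <- rois[[pick[n]]]
      if (augment) img <- augmentImage(img)
      X[b + (n - 1L) * B, ] <- as.vector(preprocess(img, cfg))
    }
  }
  X
}

#' Forward pass of DALAN on one patient bag
#'
#' Samples `bagSampleSize` ROIs with replacement (augmented and shuffled
#' when `training = TRUE`), encodes them, runs the two attention-LSTM
#' blocks and the MLP head, and returns the patient's log-hazard. At
#' inference (`training = FALSE`) the log-hazard is averaged over `draws`
#' independent ROI samplings.
#'
#' @param bag a [PatientBag-class].
#' @param model a [DalanModel-class].
#' @param training apply augmentation (default `FALSE`).
#' @param draws inference samplings to average (default the config value).
#' @return scalar log-hazard.
#' @export
forwardBag <- function(bag, model, training = FALSE, draws = NULL) {
  if (length(bag@rois) == 0L) stop("empty bag")
  config <- model@config
  if (is.null(draws)) draws <- if (training) 1L else config$inferenceDraws
  specs <- encoderSpecs(config$encoder)
  vals <- vapply(seq_len(draws), function(d) {
    X <- assembleBagBatch(list(bag), config, augment = training)
    dalanForward(X, 1L, config$bagSampleSize, model@params, config,
                 specs)$logHazard
  }, numeric(1))
  mean(vals)
}

#' Predict patient-level log-hazards for a set of bags
#'
#' Batched inference: for each of `draws` independent ROI samplings every
#' bag is scored once (no augmentation), and the log-hazards are averaged
#' across draws.
#'
#' @param model a [DalanModel-class].
#' @param bagList list of [PatientBag-class].
#' @param draws number of samplings (default from the model config).
#' @param seed optional integer making the sampling reproducible.
#' @return data.frame with columns `patient_id`, `log_hazard`,
#'   `normalized_risk`.
#' @export
predictRisk <- function(model, bagList, draws = NULL, seed = NULL) {
  if (length(bagList) == 0L) stop("no bags to score")
  config <- model@config
  if (is.null(draws)) draws <- config$inferenceDraws
  if (!is.null(seed)) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
  }
  specs <- encoderSpecs(config$encoder)
  B <- length(bagList)
  acc <- numeric(B)
  for (d in seq_len(draws)) {
    X <- assembleBagBatch(bagList, config, augment = FALSE)
    acc <- acc + dalanForward(X, B, config$bagSampleSize, model@params,
                              config, specs)$logHazard
  }
  lh <- acc / draws
  data.frame(patient_id = vapply(bagList, function(b) b@patientId,
                                 character(1)),
             log_hazard = lh,
             normalized_risk = normalizeRisk(lh),
             stringsAsFactors = FALSE)
}

#' Train DALAN on patient bags
#'
#' Bag-level training with the negative Cox partial log-likelihood formed
#' within each minibatch, AdamW with decoupled weight decay, global-norm
#' gradient clipping, and optional per-epoch exponential learning-rate
#' decay. Minibatches with no events are skipped with a warning. When
#' validation bags are supplied the per-epoch history records the
#' validation c-index (single-draw predictions).
#'
#' @param model an initialized [DalanModel-class] (see [initDalan()]).
#' @param trainBagList list of training [PatientBag-class] objects.
#' @param hyper bag-stage hyperparameters, e.g.
#'   `trainingProfile("desk")$bag`.
#' @param valBagList optional validation bags.
#' @param augment training-time augmentation (default `TRUE`; the
#'   no-augmentation ablation sets this `FALSE`).
#' @return the trained [DalanModel-class] with its `history` filled in.
#' @export
trainDalan <- function(model, trainBagList, hyper = trainingProfile()$bag,
                       valBagList = NULL, augment = TRUE) {
  if (length(trainBagList) < 2L) stop("need at least two training bags")
  config <- model@config
  specs <- encoderSpecs(config$encoder)
  params <- model@params
  state <- adamWInit(params)
  lr <- hyper$lr
  nb <- length(trainBagList)
  time <- vapply(trainBagList, function(b) b@time, numeric(1))
  event <- vapply(trainBagList, function(b) b@event, numeric(1))
  hist <- model@history
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(nb)
    losses <- numeric()
    for (start in seq(1L, nb, by = hyper$batchSize)) {
      idx <- ord[start:min(start + hyper$batchSize - 1L, nb)]
      if (length(idx) < 2L) next
      if (sum(event[idx]) == 0) {
        warning("skipping all-censored minibatch")
        next
      }
      X <- assembleBagBatch(trainBagList[idx], config, augment = augment)
      fw <- dalanForward(X, length(idx), config$bagSampleSize, params,
                         config, specs)
      losses <- c(losses,
                  coxPartialLikelihood(fw$logHazard, time[idx], event[idx]))
      dlh <- coxLossGradient(fw$logHazard, time[idx], event[idx])
      grads <- dalanBackward(dlh, fw, params, config, specs)
      grads <- clipGradients(grads, hyper$clipNorm)$grads
      stepped <- adamWStep(params, grads, state, lr, hyper$weightDecay,
                           frozen = model@frozen)
      params <- stepped$params
      state <- stepped$state
    }
    valC <- NA_real_
    if (!is.null(valBagList)) {
      tmp <- new("DalanModel", config = model@config, params = params,
                 frozen = model@frozen, history = hist)
      pr <- predictRisk(tmp, valBagList, draws = 1L)
      vt <- vapply(valBagList, function(b) b@time, numeric(1))
      ve <- vapply(valBagList, function(b) b@event, numeric(1))
      valC <- concordanceIndex(pr$log_hazard, vt, ve)
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   loss = mean(losses),
                                   val_cindex = valC, lr = lr))
    lr <- lr * hyper$lrDecay
  }
  new("DalanModel", config = model@config, params = params,
      frozen = model@frozen, history = hist)
}

#' One attention-LSTM block applied to an embedding sequence
#'
#' Exposes the block used inside DALAN: multi-head attention (self- or
#' co-attention depending on the query source) followed by a stacked LSTM,
#' returning the full hidden-state sequence. Mainly useful for inspection
#' and structural tests; fresh random weights are drawn when none are
#' given.
#'
#' @param x numeric array (B, N, D): the key/value sequence.
#' @param query numeric array (B, N, D); defaults to `x` (self-attention).
#' @param nHeads attention heads.
#' @param lstmLayers stacked LSTM layers.
#' @param params optional list with elements `attn` and `lstm`.
#' @param useAttention,useLstm structural switches.
#' @param scaleMode attention scaling.
#' @return numeric array (B, N, D) of hidden states.
#' @export
attentionLstmBlock <- function(x, query = x, nHeads = 4L, lstmLayers = 2L,
                               params = NULL, useAttention = TRUE,
                               useLstm = TRUE, scaleMode = "sqrt") {
  D <- dim(x)[3]
  if (is.null(params))
    params <- list(attn = mhaInit(D), lstm = lstmStackInit(D, D, lstmLayers))
  cur <- x
  if (useAttention)
    cur <- mhaForward(query, cur, params$attn, nHeads, scaleMode)$Y
  if (useLstm)
    cur <- lstmForward(cur, params$lstm)$H
  cur
}
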