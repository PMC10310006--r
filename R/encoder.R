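#' Encoder configuration
#'
#' Describes the weight-shared convolutional feature extractor that maps
#' every ROI image to a fixed-width embedding. Two backbones are available:
#' `"small_cnn"` (three stride-2 convolution blocks, global average
#' pooling, linear projection -- the CPU-friendly default) and
#' `"residual_cnn"` (a deeper variant with two residual blocks for larger
#' inputs). Histology-style three-channel inputs default to the ImageNet
#' normalization constants mean (0.485, 0.456, 0.406) / std (0.229, 0.224,
#' 0.225); single-channel inputs default to mean 0.5 / std 0.5.
#'
#' @param backbone `"small_cnn"` or `"residual_cnn"`.
#' @param embeddingDim embedding width (default 256).
#' @param inputShape integer `c(H, W, C)` of the (resized) network input.
#' @param normMean,normStd per-channel normalization constants; defaults
#'   depend on the channel count.
#' @param frozenFraction fraction of front parameter groups (in forward
#'   order) frozen after ROI-level fine-tuning (default 0.5).
#' @param channels filter counts of the three stages (default 16, 32, 64).
#' @return validated list of class `"encoderConfig"`.
#' @export
encoderConfig <- function(backbone = c("small_cnn", "residual_cnn"),
                          embeddingDim = 256L,
                          inputShape = c(28L, 28L, 1L),
                          normMean = NULL, normStd = NULL,
                          frozenFraction = 0.5,
                          channels = c(16L, 32L, 64L)) {
  backbone <- match.arg(backbone)
  stopifnot(embeddingDim > 0, length(inputShape) == 3L, all(inputShape > 0),
            frozenFraction >= 0, frozenFraction <= 1,
            length(channels) == 3L)
  C <- inputShape[3]
  if (is.null(normMean))
    normMean <- if (C == 3L) c(0.485, 0.456, 0.406) else rep(0.5, C)
  if (is.null(normStd))
    normStd <- if (C == 3L) c(0.229, 0.224, 0.225) else rep(0.5, C)
  if (length(normMean) != C || length(normStd) != C)
    stop("normalization vectors must have one entry per channel")
  structure(list(backbone = backbone, embeddingDim = as.integer(embeddingDim),
                 inputShape = as.integer(inputShape),
                 normMean = normMean, normStd = normStd,
                 frozenFraction = frozenFraction,
                 channels = as.integer(channels)),
            class = "encoderConfig")
}

#' Preprocess an ROI image for the encoder
#'
#' Resizes the image to the configured input size (bilinear, via
#' [EBImage::resize()]) when needed, then applies per-channel
#' standardization `(x - mean) / std`.
#'
#' @param image numeric array H x W x C with values in `[0, 1]`.
#' @param config an [encoderConfig()].
#' @return numeric array `inputShape[1] x inputShape[2] x C`.
#' @export
preprocess <- function(image, config) {
  d <- dim(image)
  C <- config$inputShape[3]
  if (d[3] != C)
    stop(sprintf("image has %d channel(s) but the encoder expects %d",
                 d[3], C))
  if (d[1] != config$inputShape[1] || d[2] != config$inputShape[2]) {
    ximg <- if (C == 1L) EBImage::Image(t(image[, , 1]))
            else EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
    r <- EBImage::resize(ximg, w = config$inputShape[2],
                         h = config$inputShape[1])
    a <- EBImage::imageData(r)
    image <- if (C == 1L) array(t(a), c(dim(a)[2], dim(a)[1], 1L))
             else aperm(a, c(2, 1, 3))
  }
  for (ch in seq_len(C))
    image[, , ch] <- (image[, , ch] - config$normMean[ch]) / config$normStd[ch]
  image
}

# Training-time augmentation on a raw [0,1] image: random horizontal and
# vertical flips always; 90-degree rotations for single-channel (digit)
# inputs; brightness/contrast jitter for three-channel (histology-style)
# inputs. Matches each design's augmentation list.
augmentImage <- function(image) {
  if (stats::runif(1) < 0.5)
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  if (stats::runif(1) < 0.5)
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  if (dim(image)[3] == 1L) {
    k <- sample(0:3, 1)
    if (k > 0) for (i in seq_len(k)) {
      image <- aperm(image, c(2, 1, 3))
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
    }
  } else {
    ctr <- stats::runif(1, 0.9, 1.1)
    image <- (image - 0.5) * ctr + 0.5 + stats::runif(1, -0.08, 0.08)
    image <- pmin(pmax(image, 0), 1)
  }
  image
}

# ---- backbone geometry and initialization -------------------------------
# A backbone is described by conv specs (pure geometry, no RNG) and named
# parameter groups in forward order; the forward order defines which
# "front" groups frozenFraction freezes.

encoderSpecs <- function(config) {
  H <- config$inputShape[1]; W <- config$inputShape[2]
  C <- config$inputShape[3]
  ch <- config$channels
  if (config$backbone == "small_cnn") {
    s1 <- convSpec(H, W, C, 3L, 2L, 1L, ch[1])
    s2 <- convSpec(s1$outH, s1$outW, ch[1], 3L, 2L, 1L, ch[2])
    s3 <- convSpec(s2$outH, s2$outW, ch[2], 3L, 2L, 1L, ch[3])
    list(conv1 = s1, conv2 = s2, conv3 = s3)
  } else {
    stem <- convSpec(H, W, C, 3L, 2L, 1L, ch[1])
    r1 <- convSpec(stem$outH, stem$outW, ch[1], 3L, 1L, 1L, ch[1])
    d1 <- convSpec(stem$outH, stem$outW, ch[1], 3L, 2L, 1L, ch[2])
    r2 <- convSpec(d1$outH, d1$outW, ch[2], 3L, 1L, 1L, ch[2])
    d2 <- convSpec(d1$outH, d1$outW, ch[2], 3L, 2L, 1L, ch[3])
    list(stem = stem, res1 = r1, down1 = d1, res2 = r2, down2 = d2)
  }
}

encoderInit <- function(config, specs = encoderSpecs(config)) {
  ch <- config$channels
  if (config$backbone == "small_cnn") {
    list(conv1 = convInit(specs$conv1), conv2 = convInit(specs$conv2),
         conv3 = convInit(specs$conv3),
         fc = linearInit(ch[3], config$embeddingDim))
  } else {
    list(stem = convInit(specs$stem),
         res1 = list(a = convInit(specs$res1), b = convInit(specs$res1)),
         down1 = convInit(specs$down1),
         res2 = list(a = convInit(specs$res2), b = convInit(specs$res2)),
         down2 = convInit(specs$down2),
         fc = linearInit(ch[3], config$embeddingDim))
  }
}

encoderParamNames <- function(config) {
  if (config$backbone == "small_cnn") c("conv1", "conv2", "conv3", "fc")
  else c("stem", "res1", "down1", "res2", "down2", "fc")
}

# names of the front encoder groups frozen at a given fraction
frozenGroups <- function(config) {
  nms <- encoderParamNames(config)
  nms[seq_len(floor(config$frozenFraction * length(nms)))]
}

# ---- encoder forward / backward -----------------------------------------
# X: B x (H*W*C) matrix of preprocessed images flattened column-major in
# (H, W, C) order. Activation maps travel as (B*P) x F matrices and are
# reshaped to image layout between convolutions.

# reshape a (B*P) x F conv activation into a B x (P*F) image matrix;
# position index p enumerates (h, w) column-major, matching convSpec
mapToImages <- function(Y, B, spec) {
  dim(Y) <- c(B, spec$P * spec$nFilters)   # pure reshape, b fastest
  Y
}

imagesToMap <- function(dX, B, spec) {
  dim(dX) <- c(B * spec$P, spec$nFilters)
  dX
}

# residual block: out = relu(X + conv_b(relu(conv_a(X)))), geometry kept
resForward <- function(X, spec, p) {
  ca <- convForward(X, spec, p$a)
  aa <- reluForward(ca$Y)
  xb <- mapToImages(aa, ca$B, spec)
  cb <- convForward(xb, spec, p$b)
  pre <- X + mapToImages(cb$Y, cb$B, spec)
  list(out = reluForward(pre), pre = pre, ca = ca, xb = xb, cb = cb)
}

resBackward <- function(dOut, blk, spec, p) {
  B <- blk$ca$B
  dPre <- reluBackward(dOut, blk$pre)
  bb <- convBackward(imagesToMap(dPre, B, spec), blk$cb, spec, p$b)
  dYa <- reluBackward(imagesToMap(bb$dX, B, spec), blk$ca$Y)
  ba <- convBackward(dYa, blk$ca, spec, p$a)
  list(grads = list(a = ba$grads, b = bb$grads), dX = dPre + ba$dX)
}

# conv + relu, returning the image-layout activation
convReluForward <- function(X, spec, p) {
  cf <- convForward(X, spec, p)
  a <- reluForward(cf$Y)
  list(out = mapToImages(a, cf$B, spec), cf = cf)
}

convReluBackward <- function(dOut, blk, spec, p) {
  dY <- reluBackward(imagesToMap(dOut, blk$cf$B, spec), blk$cf$Y)
  convBackward(dY, blk$cf, spec, p)
}

encoderForward <- function(X, params, specs, backbone) {
  B <- nrow(X)
  if (backbone == "small_cnn") {
    b1 <- convReluForward(X, specs$conv1, params$conv1)
    b2 <- convReluForward(b1$out, specs$conv2, params$conv2)
    c3 <- convForward(b2$out, specs$conv3, params$conv3)
    a3 <- reluForward(c3$Y)
    z <- poolForward(a3, B, specs$conv3$P)
    E <- linearForward(z, params$fc)
    list(E = E, cache = list(b1 = b1, b2 = b2, c3 = c3, z = z, B = B))
  } else {
    st <- convReluForward(X, specs$stem, params$stem)
    r1 <- resForward(st$out, specs$res1, params$res1)
    d1 <- convReluForward(r1$out, specs$down1, params$down1)
    r2 <- resForward(d1$out, specs$res2, params$res2)
    c2 <- convForward(r2$out, specs$down2, params$down2)
    a2 <- reluForward(c2$Y)
    z <- poolForward(a2, B, specs$down2$P)
    E <- linearForward(z, params$fc)
    list(E = E, cache = list(st = st, r1 = r1, d1 = d1, r2 = r2, c2 = c2,
                             z = z, B = B))
  }
}

encoderBackward <- function(dE, fw, params, specs, backbone) {
  cc <- fw$cache
  B <- cc$B
  lb <- linearBackward(dE, cc$z, params$fc)
  if (backbone == "small_cnn") {
    dA3 <- poolBackward(lb$dX, B, specs$conv3$P)
    dY3 <- reluBackward(dA3, cc$c3$Y)
    g3 <- convBackward(dY3, cc$c3, specs$conv3, params$conv3)
    g2 <- convReluBackward(g3$dX, cc$b2, specs$conv2, params$conv2)
    g1 <- convReluBackward(g2$dX, cc$b1, specs$conv1, params$conv1)
    list(grads = list(conv1 = g1$grads, conv2 = g2$grads, conv3 = g3$grads,
                      fc = lb$grads),
         dX = g1$dX)
  } else {
    dA2 <- poolBackward(lb$dX, B, specs$down2$P)
    dY2 <- reluBackward(dA2, cc$c2$Y)
    gd2 <- convBackward(dY2, cc$c2, specs$down2, params$down2)
    gr2 <- resBackward(gd2$dX, cc$r2, specs$res2, params$res2)
    gd1 <- convReluBackward(gr2$dX, cc$d1, specs$down1, params$down1)
    gr1 <- resBackward(gd1$dX, cc$r1, specs$res1, params$res1)
    gst <- convReluBackward(gr1$dX, cc$st, specs$stem, params$stem)
    list(grads = list(stem = gst$grads, res1 = gr1$grads, down1 = gd1$grads,
                      res2 = gr2$grads, down2 = gd2$grads, fc = lb$grads),
         dX = gst$dX)
  }
}

# flatten a list of preprocessed images into the B x L batch matrix
stackImages <- function(images) {
  do.call(rbind, lapply(images, as.vector))
}

#' Encode a bag of ROI images into an embedding sequence
#'
#' Applies the weight-shared encoder to every image of a bag and returns
#' one embedding row per image. The same weights are applied to each image,
#' so duplicated images produce identical rows and reordering the bag
#' permutes the rows identically.
#'
#' @param images list of raw H x W x C images in `[0, 1]`.
#' @param model a [RoiModel-class] or [DalanModel-class] (its encoder part
#'   is used).
#' @return numeric matrix `length(images) x embeddingDim`.
#' @export
encodeBag <- function(images, model) {
  if (length(images) == 0L) stop("empty bag")
  cfg <- if (is(model, "DalanModel")) model@config$encoder else model@config
  params <- if (is(model, "DalanModel")) model@params$encoder
            else model@params$encoder
  specs <- encoderSpecs(cfg)
  X <- stackImages(lapply(images, preprocess, config = cfg))
  encoderForward(X, params, specs, cfg$backbone)$E
}
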