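#' Random uniform pixel-weight mask
#'
#' Draws the elementwise `Uniform(0, 1)` weight tensor `M` that turns image
#' content into survival signal: an ROI's latent survival time is a
#' function of `mean(I * M)` (see [roiSurvivalTime()]). One mask is shared
#' by all ROIs of a simulation replicate so that survival is a fixed random
#' linear functional of image content.
#'
#' @param shape integer vector `c(H, W, D)`, all positive.
#' @param seed integer seed; the mask is reproducible given the seed.
#' @return numeric array of dimension `shape` with values in `[0, 1]`.
#' @examples
#' m <- generateWeightMask(c(28, 28, 1), seed = 7)
#' @export
generateWeightMask <- function(shape, seed) {
  if (length(shape) != 3L || any(shape <= 0))
    stop("shape must be three positive dimensions (H, W, D)")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(seed)
  array(stats::runif(prod(shape)), dim = shape)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Latent survival time of a single ROI
#'
#' Computes `T = exp( mean(I * M) + noiseScale * eps )` with
#' `eps ~ Lognormal(0, 1)`: the weighted mean pixel intensity of the image
#' sets the log survival time, perturbed by a small multiplicative noise
#' term. The result is strictly positive and strictly increasing in any
#' pixelwise dominance of the image at fixed mask and noise draw.
#'
#' @param image numeric array H x W x D, values in `[0, 1]`.
#' @param mask weight mask of identical dimension (see
#'   [generateWeightMask()]).
#' @param noiseScale scale of the noise term (default 0.001).
#' @param eps optional fixed noise value; when `NULL` one draw from
#'   `Lognormal(0, 1)` is taken from the current RNG stream.
#' @return a positive scalar survival time.
#' @export
roiSurvivalTime <- function(image, mask, noiseScale = 0.001, eps = NULL) {
  if (!identical(dim(image), dim(mask)))
    stop("image and mask dimensions differ")
  if (is.null(eps)) eps <- stats::rlnorm(1, meanlog = 0, sdlog = 1)
  exp(mean(image * mask) + noiseScale * eps)
}

#' Patient-level survival time from ROI times
#'
#' The subject's final survival time is the arithmetic mean of the latent
#' survival times of its ROIs.
#'
#' @param roiTimes non-empty numeric vector of ROI survival times.
#' @return scalar mean.
#' @export
patientSurvivalTime <- function(roiTimes) {
  if (length(roiTimes) == 0L) stop("empty ROI time vector")
  mean(roiTimes)
}

#' Apply random right-censoring to true survival times
#'
#' Selects exactly `floor(censorFraction * n)` subjects uniformly at random
#' (without replacement) and replaces their observed time with a draw from
#' `Uniform(0, T_i)`; all other subjects keep `time = T_i`, `event = 1`.
#'
#' @param trueTimes positive numeric vector of true survival times.
#' @param censorFraction fraction of subjects to censor, in `[0, 1]`.
#' @return data.frame with columns `time`, `event`, `true_time`.
#' @export
applyCensoring <- function(trueTimes, censorFraction = 0.5) {
  if (censorFraction < 0 || censorFraction > 1)
    stop("censorFraction must be in [0, 1]")
  n <- length(trueTimes)
  nCens <- floor(censorFraction * n)
  censIdx <- if (nCens > 0) sample.int(n, nCens) else integer(0)
  time <- trueTimes
  event <- rep(1, n)
  if (nCens > 0) {
    time[censIdx] <- stats::runif(nCens, 0, trueTimes[censIdx])
    event[censIdx] <- 0
  }
  data.frame(time = time, event = event, true_time = trueTimes)
}

# ---- synthetic ROI image generators -------------------------------------
# Stand-ins for the handwritten-digit and cancer-texture ROI sources: fully
# procedural, so no image download is needed. Both emit H x W x D arrays in
# [0, 1] with enough within-class intensity variation to carry survival
# signal through the weighted-mean functional.

#' Synthetic digit-like ROI images
#'
#' Procedurally drawn 28 x 28 single-channel strokes: `"zero-like"` images
#' are rings, `"six-like"` images are smaller rings with an ascending tail.
#' Stroke radius, thickness, centre jitter, tail angle and additive noise
#' are randomized per image, so the two classes have overlapping but
#' distinct total-ink distributions -- the property that creates
#' class-linked survival signal under [roiSurvivalTime()].
#'
#' @param classLabel `"zero-like"` or `"six-like"`.
#' @param n number of images.
#' @param seed optional integer; when given, the batch is reproducible.
#' @return list of `n` arrays of dimension 28 x 28 x 1.
#' @export
synthDigitImages <- function(classLabel = c("zero-like", "six-like"), n,
                             seed = NULL) {
  classLabel <- match.arg(classLabel)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
  }
  lapply(seq_len(n), function(i) .drawDigit(classLabel))
}

.drawDigit <- function(classLabel, size = 28L) {
  gx <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  gy <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  img <- matrix(0, size, size)
  softStroke <- function(dist, thickness) {
    # smooth stroke profile: 1 on the centreline, Gaussian falloff
    exp(-(dist / thickness)^2)
  }
  if (classLabel == "zero-like") {
    cx <- size / 2 + stats::runif(1, -2, 2)
    cy <- size / 2 + stats::runif(1, -2, 2)
    r <- stats::runif(1, 6.5, 9.5)
    th <- stats::runif(1, 1.2, 2.6)
    d <- abs(sqrt((gx - cx)^2 + (gy - cy)^2) - r)
    img <- softStroke(d, th)
  } else {
    # six-like: smaller lower ring plus a tail rising to the upper right
    cx <- size / 2 + stats::runif(1, -2, 2)
    cy <- size / 2 + 3.5 + stats::runif(1, -1.5, 1.5)
    r <- stats::runif(1, 4.0, 6.0)
    th <- stats::runif(1, 1.2, 2.4)
    d <- abs(sqrt((gx - cx)^2 + (gy - cy)^2) - r)
    img <- softStroke(d, th)
    # tail: thick line segment from the ring top toward the top of the frame
    ang <- stats::runif(1, 55, 80) * pi / 180
    x0 <- cx + r * cos(ang * 0.3); y0 <- cy - r * sin(ang * 0.3)
    len <- stats::runif(1, 7, 11)
    x1 <- x0 + len * cos(ang); y1 <- y0 - len * sin(ang)
    # distance from each pixel to the segment (x0,y0)-(x1,y1)
    vx <- x1 - x0; vy <- y1 - y0
    tproj <- pmin(pmax(((gx - x0) * vx + (gy - y0) * vy) / (vx^2 + vy^2), 0), 1)
    dseg <- sqrt((gx - (x0 + tproj * vx))^2 + (gy - (y0 + tproj * vy))^2)
    img <- pmax(img, softStroke(dseg, th))
  }
  img <- img * stats::runif(1, 0.75, 1.0) +
    matrix(stats::rnorm(size * size, 0, 0.04), size, size)
  array(pmin(pmax(img, 0), 1), dim = c(size, size, 1L))
}

#' Synthetic texture ROI images
#'
#' Smooth random fields (coarse Gaussian noise octaves upsampled
#' bilinearly) with a per-image brightness offset drawn from a wide
#' distribution, emulating heterogeneous tissue-texture tiles. At
#' `heterogeneity = 1` per-image mean intensities span roughly
#' `[0.15, 0.85]`; at 0 all images share the same mean up to field noise.
#'
#' @param n number of images.
#' @param shape integer `c(H, W, 3)`.
#' @param heterogeneity brightness spread in `[0, 1]` (default 1).
#' @param seed optional integer for reproducibility.
#' @return list of `n` arrays of dimension `shape`.
#' @export
synthTextureImages <- function(n, shape = c(32L, 32L, 3L),
                               heterogeneity = 1, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (length(shape) != 3L || shape[3] != 3L)
    stop("shape must be (H, W, 3)")
  if (!is.null(seed)) {
    old <- .Random.seed.save()
    on.exit(.Random.seed.restore(old))
    set.seed(seed)
  }
  H <- shape[1]; W <- shape[2]
  lapply(seq_len(n), function(i) {
    b <- 0.5 + heterogeneity * 0.75 * (stats::runif(1) - 0.5)
    img <- array(0, dim = shape)
    for (ch in 1:3) {
      field <- .bilinearUpsample(matrix(stats::rnorm(36, 0, 1), 6, 6), H, W)
      img[, , ch] <- b + 0.12 * field
    }
    pmin(pmax(img, 0), 1)
  })
}

# bilinear upsample of a coarse matrix to H x W
.bilinearUpsample <- function(m, H, W) {
  h0 <- nrow(m); w0 <- ncol(m)
  ry <- seq(1, h0, length.out = H)
  rx <- seq(1, w0, length.out = W)
  y0 <- pmin(floor(ry), h0 - 1L); x0 <- pmin(floor(rx), w0 - 1L)
  fy <- ry - y0; fx <- rx - x0
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1L, drop = FALSE]
  c_ <- m[y0 + 1L, x0, drop = FALSE]; d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  top <- a * (1 - fx)[col(a)] + b * fx[col(b)]
  bot <- c_ * (1 - fx)[col(c_)] + d * fx[col(d)]
  top * (1 - fy)[row(top)] + bot * fy[row(bot)]
}

#' Simulation configuration
#'
#' Bundles and validates all parameters of a simulation replicate. The
#' defaults are the study conditions used throughout the package: 50%
#' random censoring, noise scale 0.001, 80/20 patient-level train/test
#' split.
#'
#' @param design `"two_roi_digit"` (two 28 x 28 x 1 ROIs per patient, one
#'   zero-like and one six-like) or `"multi_roi_texture"` (multi-ROI bags
#'   of H x W x 3 textures).
#' @param nPatients number of patients.
#' @param imageShape `c(H, W, D)`; defaults to 28 x 28 x 1 for the digit
#'   design and 32 x 32 x 3 for the texture design.
#' @param roisPerPatient ROIs per bag; fixed at 2 for the digit design. A
#'   length-2 vector gives a uniform integer range.
#' @param censorFraction fraction censored (default 0.5).
#' @param noiseScale Lognormal noise scale in the ROI time (default 0.001).
#' @param splitFraction training fraction (default 0.8).
#' @param nRepeats replicate count carried in experiment drivers
#'   (default 20).
#' @param heterogeneity texture brightness spread (default 1).
#' @param maskPerRoi draw an independent weight mask per ROI instead of one
#'   shared mask per replicate (ablation switch; default `FALSE`).
#' @param seed integer master seed.
#' @return validated list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(design = c("two_roi_digit", "multi_roi_texture"),
                             nPatients = 500L,
                             imageShape = NULL,
                             roisPerPatient = NULL,
                             censorFraction = 0.5,
                             noiseScale = 0.001,
                             splitFraction = 0.8,
                             nRepeats = 20L,
                             heterogeneity = 1,
                             maskPerRoi = FALSE,
                             seed = 1L) {
  design <- match.arg(design)
  if (is.null(imageShape))
    imageShape <- if (design == "two_roi_digit") c(28L, 28L, 1L)
                  else c(32L, 32L, 3L)
  if (is.null(roisPerPatient))
    roisPerPatient <- if (design == "two_roi_digit") 2L else c(3L, 8L)
  if (design == "two_roi_digit" && !identical(as.integer(roisPerPatient), 2L))
    stop("the digit design has exactly two ROIs per patient")
  stopifnot(nPatients >= 2, all(imageShape > 0),
            censorFraction >= 0, censorFraction <= 1,
            noiseScale >= 0, splitFraction > 0, splitFraction < 1,
            nRepeats >= 1, heterogeneity >= 0)
  structure(list(design = design, nPatients = as.integer(nPatients),
                 imageShape = as.integer(imageShape),
                 roisPerPatient = as.integer(roisPerPatient),
                 censorFraction = censorFraction, noiseScale = noiseScale,
                 splitFraction = splitFraction, nRepeats = as.integer(nRepeats),
                 heterogeneity = heterogeneity, maskPerRoi = maskPerRoi,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

#' Build one simulated cohort of patient bags
#'
#' Generates ROI images per patient, a weight mask (one per replicate by
#' default, shared by every ROI), latent ROI survival times via
#' [roiSurvivalTime()], patient times as ROI means, random censoring, and a
#' patient-level train/test split.
#'
#' @param config a [simulationConfig()].
#' @return a [BagCohort-class]; the generating mask is attached and
#'   retrievable with [cohortMask()].
#' @examples
#' cfg <- simulationConfig("two_roi_digit", nPatients = 20, seed = 3)
#' cohort <- buildSimulation(cfg)
#' table(survivalData(cohort)$split)
#' @export
buildSimulation <- function(config) {
  if (!inherits(config, "simulationConfig"))
    stop("config must come from simulationConfig()")
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config$seed)
  n <- config$nPatients
  shape <- config$imageShape
  mask <- generateWeightMask(shape, seed = sample.int(2^30, 1))

  allRois <- vector("list", n)
  trueTimes <- numeric(n)
  for (p in seq_len(n)) {
    if (config$design == "two_roi_digit") {
      rois <- c(synthDigitImages("zero-like", 1), synthDigitImages("six-like", 1))
    } else {
      k <- if (length(config$roisPerPatient) == 2L)
        sample(config$roisPerPatient[1]:config$roisPerPatient[2], 1)
        else config$roisPerPatient
      rois <- synthTextureImages(k, shape, config$heterogeneity)
    }
    tRois <- vapply(rois, function(img) {
      m <- if (config$maskPerRoi)
        array(stats::runif(prod(shape)), dim = shape) else mask
      roiSurvivalTime(img, m, config$noiseScale)
    }, numeric(1))
    allRois[[p]] <- rois
    trueTimes[p] <- patientSurvivalTime(tRois)
  }
  rec <- applyCensoring(trueTimes, config$censorFraction)
  nTrain <- floor(config$splitFraction * n)
  trainIdx <- sample.int(n, nTrain)
  split <- rep("test", n)
  split[trainIdx] <- "train"
  bagsList <- lapply(seq_len(n), function(p)
    patientBag(sprintf("P%04d", p), allRois[[p]],
               time = rec$time[p], event = rec$event[p],
               trueTime = rec$true_time[p]))
  bagCohort(bagsList, split = split, design = config$design, mask = mask)
}

#' Export / import a simulated cohort as PNG images plus a manifest
#'
#' `exportCohort()` writes one PNG per ROI and a manifest CSV with columns
#' `patient_id`, `roi_path`, `time`, `event`, `true_time`, `split`.
#' `importCohort()` reads such a directory back into a [BagCohort-class].
#'
#' @param cohort a [BagCohort-class].
#' @param dir output directory (created if needed).
#' @return `exportCohort()`: the manifest data.frame, invisibly.
#' @export
exportCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (b in bags(cohort)) {
    for (k in seq_along(b@rois)) {
      fn <- file.path(dir, sprintf("%s_roi%02d.png", b@patientId, k))
      img <- b@rois[[k]]
      # EBImage expects x-y(-channel) order; transpose rows/cols
      e <- if (dim(img)[3] == 1L) EBImage::Image(t(img[, , 1]))
           else EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
      EBImage::writeImage(e, fn)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = b@patientId, roi_path = basename(fn),
        time = b@time, event = b@event, true_time = b@trueTime,
        split = cohort@split[match(b@patientId,
          vapply(bags(cohort), function(x) x@patientId, character(1)))],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' @rdname exportCohort
#' @export
importCohort <- function(dir) {
  manifest <- readManifest(file.path(dir, "manifest.csv"))
  ids <- unique(manifest$patient_id)
  bagsList <- lapply(ids, function(id) {
    rows <- manifest[manifest$patient_id == id, , drop = FALSE]
    rois <- lapply(rows$roi_path, function(p) {
      e <- EBImage::readImage(file.path(dir, p))
      a <- EBImage::imageData(e)
      if (length(dim(a)) == 2L) array(t(a), c(dim(a)[2], dim(a)[1], 1L))
      else aperm(a, c(2, 1, 3))
    })
    patientBag(id, rois, time = rows$time[1], event = rows$event[1],
               trueTime = if ("true_time" %in% names(rows))
                 rows$true_time[1] else NA_real_)
  })
  split <- vapply(ids, function(id)
    manifest$split[match(id, manifest$patient_id)], character(1))
  bagCohort(bagsList, split = unname(split), design = "external")
}
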