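#' @import methods
NULL

#' Patient bag of lesion ROI images with survival outcome
#'
#' A `PatientBag` holds one subject's multiple-instance data: a non-empty
#' list of region-of-interest (ROI) images, the observed survival time
#' `Y = min(T, C)`, the event indicator (1 = event observed, 0 = right
#' censored), and -- for simulated subjects -- the pre-censoring true
#' survival time, retained for diagnostics.
#'
#' Images are numeric arrays of dimension height x width x channels with
#' all values in `[0, 1]`.
#'
#' @slot patientId character scalar identifier.
#' @slot rois list of numeric arrays (H x W x C), values in `[0, 1]`.
#' @slot time observed time, non-negative.
#' @slot event event indicator, 0 or 1.
#' @slot trueTime pre-censoring survival time (`NA` for real data).
#'
#' @seealso [patientBag()], [BagCohort-class]
#' @exportClass PatientBag
setClass("PatientBag",
  representation(
    patientId = "character",
    rois = "list",
    time = "numeric",
    event = "numeric",
    trueTime = "numeric"
  )
)

setValidity("PatientBag", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L || is.na(object@patientId))
    msg <- c(msg, "patientId must be a single non-NA string")
  if (length(object@rois) < 1L)
    msg <- c(msg, "a bag must contain at least one ROI image")
  if (!all(vapply(object@rois, function(x) is.array(x) && length(dim(x)) == 3L,
                  logical(1))))
    msg <- c(msg, "each ROI must be a 3-d numeric array (H x W x C)")
  if (length(object@time) != 1L || object@time < 0)
    msg <- c(msg, "time must be a single non-negative number")
  if (length(object@event) != 1L || !(object@event %in% c(0, 1)))
    msg <- c(msg, "event must be 0 or 1")
  if (!is.na(object@trueTime)) {
    if (object@event == 1 && !isTRUE(all.equal(object@time, object@trueTime)))
      msg <- c(msg, "an uncensored bag must have time == trueTime")
    if (object@event == 0 && object@time >= object@trueTime)
      msg <- c(msg, "a censored bag must have time < trueTime")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatientBag
#'
#' @param patientId subject identifier.
#' @param rois non-empty list of H x W x C numeric arrays in `[0, 1]`.
#' @param time observed survival time (`min(T, C)`).
#' @param event 1 if the event was observed, 0 if censored.
#' @param trueTime pre-censoring survival time; `NA` when unknown.
#' @return A [PatientBag-class] object.
#' @examples
#' img <- array(runif(28 * 28), c(28, 28, 1))
#' patientBag("P1", list(img), time = 1.2, event = 1, trueTime = 1.2)
#' @export
patientBag <- function(patientId, rois, time, event, trueTime = NA_real_) {
  new("PatientBag",
      patientId = as.character(patientId), rois = rois,
      time = as.numeric(time), event = as.numeric(event),
      trueTime = as.numeric(trueTime))
}

setMethod("show", "PatientBag", function(object) {
  d <- dim(object@rois[[1]])
  cat(sprintf(
    "PatientBag '%s': %d ROI(s) of %dx%dx%d, time = %.4g, event = %d\n",
    object@patientId, length(object@rois), d[1], d[2], d[3],
    object@time, as.integer(object@event)))
})

#' Cohort of patient bags
#'
#' A `BagCohort` is an ordered collection of [PatientBag-class] objects with
#' a train/test split label per bag and, for simulated cohorts, the random
#' pixel-weight mask that generated the survival times.
#'
#' @slot bags list of [PatientBag-class].
#' @slot split character vector, one of `"train"`/`"test"` per bag.
#' @slot design character scalar describing how the cohort was built
#'   (e.g. `"two_roi_digit"`, `"multi_roi_texture"`, `"external"`).
#' @slot mask the weight mask array used by the simulator, or an empty list
#'   element when not applicable.
#'
#' @seealso [bagCohort()], [survivalData()], [trainBags()], [testBags()]
#' @exportClass BagCohort
setClass("BagCohort",
  representation(
    bags = "list",
    split = "character",
    design = "character",
    mask = "list"
  )
)

setValidity("BagCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@bags, is, logical(1), "PatientBag")))
    msg <- c(msg, "all elements of bags must be PatientBag objects")
  if (length(object@split) != length(object@bags))
    msg <- c(msg, "split must have one label per bag")
  if (!all(object@split %in% c("train", "test")))
    msg <- c(msg, "split labels must be 'train' or 'test'")
  ids <- vapply(object@bags, function(b) b@patientId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "patient ids must be unique within a cohort")
  if (length(msg)) msg else TRUE
})

#' Construct a BagCohort
#'
#' @param bags list of [PatientBag-class] objects with unique patient ids.
#' @param split character vector of `"train"`/`"test"`, one per bag.
#' @param design free-text label for the cohort's origin.
#' @param mask optional weight-mask array (simulated cohorts).
#' @return A [BagCohort-class] object.
#' @export
bagCohort <- function(bags, split = rep("train", length(bags)),
                      design = "external", mask = NULL) {
  new("BagCohort", bags = bags, split = split, design = design,
      mask = if (is.null(mask)) list() else list(mask))
}

setMethod("show", "BagCohort", function(object) {
  k <- lengths(lapply(object@bags, function(b) b@rois))
  cat(sprintf(
    "BagCohort (%s): %d patients (%d train / %d test), %d ROIs total\n",
    object@design, length(object@bags),
    sum(object@split == "train"), sum(object@split == "test"), sum(k)))
})

#' Cohort accessors
#'
#' `survivalData()` returns the cohort's outcome table; `bags()` the list of
#' [PatientBag-class] objects; `trainBags()`/`testBags()` the split subsets;
#' `cohortMask()` the simulator weight mask (or `NULL`).
#'
#' @param x a [BagCohort-class].
#' @return `survivalData()`: a `data.frame` with columns `patient_id`,
#'   `time`, `event`, `true_time`, `n_rois`, `split`. `bags()`,
#'   `trainBags()`, `testBags()`: lists of [PatientBag-class].
#' @export
setGeneric("survivalData", function(x) standardGeneric("survivalData"))

#' @rdname survivalData
#' @export
setMethod("survivalData", "BagCohort", function(x) {
  data.frame(
    patient_id = vapply(x@bags, function(b) b@patientId, character(1)),
    time = vapply(x@bags, function(b) b@time, numeric(1)),
    event = vapply(x@bags, function(b) b@event, numeric(1)),
    true_time = vapply(x@bags, function(b) b@trueTime, numeric(1)),
    n_rois = vapply(x@bags, function(b) length(b@rois), integer(1)),
    split = x@split,
    stringsAsFactors = FALSE
  )
})

#' @rdname survivalData
#' @export
setGeneric("bags", function(x) standardGeneric("bags"))

#' @rdname survivalData
#' @export
setMethod("bags", "BagCohort", function(x) x@bags)

#' @rdname survivalData
#' @export
setGeneric("trainBags", function(x) standardGeneric("trainBags"))

#' @rdname survivalData
#' @export
setMethod("trainBags", "BagCohort", function(x) x@bags[x@split == "train"])

#' @rdname survivalData
#' @export
setGeneric("testBags", function(x) standardGeneric("testBags"))

#' @rdname survivalData
#' @export
setMethod("testBags", "BagCohort", function(x) x@bags[x@split == "test"])

#' @rdname survivalData
#' @export
setGeneric("cohortMask", function(x) standardGeneric("cohortMask"))

#' @rdname survivalData
#' @export
setMethod("cohortMask", "BagCohort", function(x) {
  if (length(x@mask)) x@mask[[1]] else NULL
})

#' Fitted ROI-level Cox CNN
#'
#' Convolutional encoder plus scalar Cox head trained on ROI-level data
#' (every ROI inherits its patient's observed time and event). Used both as
#' stage-1 fine-tuning for DALAN and as the scorer behind the naive
#' aggregation baselines.
#'
#' @slot config the [encoderConfig()] list used to build the network.
#' @slot params named list of weight matrices/vectors.
#' @slot frozen character vector of parameter-group names marked frozen.
#' @slot history data.frame of per-epoch training diagnostics.
#' @exportClass RoiModel
setClass("RoiModel",
  representation(config = "list", params = "list",
                 frozen = "character", history = "data.frame"))

setMethod("show", "RoiModel", function(object) {
  cat(sprintf(
    "RoiModel (%s backbone): %d parameters, %d frozen group(s), %d epoch(s) trained\n",
    object@config$backbone, paramCount(object@params),
    length(object@frozen), nrow(object@history)))
})

#' Fitted DALAN aggregation model
#'
#' The full patient-level model: weight-shared CNN encoder, two
#' attention-LSTM blocks (self-attention then co-attention), and an MLP Cox
#' head producing one log-hazard per patient.
#'
#' @slot config the [dalanConfig()] list.
#' @slot params named list of weight matrices/vectors.
#' @slot frozen character vector of frozen parameter-group names.
#' @slot history data.frame of per-epoch loss / validation c-index / lr.
#' @exportClass DalanModel
setClass("DalanModel",
  representation(config = "list", params = "list",
                 frozen = "character", history = "data.frame"))

setMethod("show", "DalanModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DalanModel: %d parameters (%s encoder, %d-head attention%s, %d-layer LSTM%s)\n",
    paramCount(object@params), cfg$encoder$backbone, cfg$nHeads,
    if (cfg$useAttention) "" else " [disabled]",
    cfg$lstmLayers,
    if (cfg$useLstm) "" else " [disabled]"))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s); final loss %.4f\n",
                nrow(object@history),
                object@history$loss[nrow(object@history)]))
})

# total number of scalar parameters in a nested param list
paramCount <- function(params) {
  sum(vapply(rapply(params, length, how = "unlist"), identity, numeric(1)))
}
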