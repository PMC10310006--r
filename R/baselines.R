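#' Aggregate ROI-level hazards to one patient-level risk
#'
#' The naive (non-trainable) aggregation rules: the patient-level predicted
#' hazard is the mean, minimum, maximum or median of the ROI-wise predicted
#' hazards. The median of an even count is the midpoint of the two central
#' values. All rules are permutation-invariant in the ROI order.
#'
#' @param roiRisks non-empty numeric vector of ROI log-hazards.
#' @param rule one of `"average"`, `"min"`, `"max"`, `"median"`.
#' @return scalar patient-level risk.
#' @examples
#' aggregatePatientRisk(c(1, 2, 3, 10), "median")  # 2.5
#' @export
aggregatePatientRisk <- function(roiRisks,
                                 rule = c("average", "min", "max", "median")) {
  rule <- match.arg(rule)
  if (length(roiRisks) == 0L) stop("empty ROI risk vector")
  switch(rule,
         average = mean(roiRisks),
         min = min(roiRisks),
         max = max(roiRisks),
         median = stats::median(roiRisks))
}

#' Patient-level predictions from an ROI model under an aggregation rule
#'
#' Scores every ROI of every bag (no sampling) with the fitted ROI-wise
#' Cox CNN and aggregates per patient.
#'
#' @param model a [RoiModel-class].
#' @param bagList list of [PatientBag-class].
#' @param rule aggregation rule (see [aggregatePatientRisk()]).
#' @return data.frame with `patient_id`, `log_hazard`, `normalized_risk`.
#' @export
predictAggregated <- function(model, bagList, rule = "average") {
  lh <- vapply(bagList, function(b)
    aggregatePatientRisk(predictRoiRisks(model, b@rois), rule), numeric(1))
  data.frame(patient_id = vapply(bagList, function(b) b@patientId,
                                 character(1)),
             log_hazard = lh,
             normalized_risk = normalizeRisk(lh),
             stringsAsFactors = FALSE)
}

#' Evaluate a naive aggregation baseline
#'
#' Computes the patient-level concordance index of an ROI-wise Cox model
#' combined with a naive aggregation rule on a set of test bags.
#'
#' @inheritParams predictAggregated
#' @return scalar c-index.
#' @export
evaluateBaseline <- function(model, bagList, rule = "average") {
  pr <- predictAggregated(model, bagList, rule)
  time <- vapply(bagList, function(b) b@time, numeric(1))
  event <- vapply(bagList, function(b) b@event, numeric(1))
  concordanceIndex(pr$log_hazard, time, event)
}
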