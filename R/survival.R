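#' Negative Cox partial log-likelihood of predicted log-hazards
#'
#' Loss used to train all deep Cox models in this package. For uncensored
#' subjects `U` and risk sets `R_i = { j : time_j >= time_i }` (ties enter
#' the risk set, Breslow-style), the unreduced loss is
#' \deqn{- \sum_{i \in U} \big( h_i - \log \sum_{j \in R_i} e^{h_j} \big),}
#' where `h` are the predicted log-hazards. The log-sum-exp is stabilised by
#' max subtraction. By default the sum is divided by the number of events so
#' that batch size does not rescale gradients; `reduction = "sum"` gives the
#' raw sum.
#'
#' @param logHazards numeric vector of predicted log relative hazards.
#' @param time numeric vector of observed times, same length.
#' @param event 0/1 event indicators, same length.
#' @param reduction `"mean"` (per event, default) or `"sum"`.
#' @return A single non-negative number. An input with no events returns 0
#'   with a warning (no term contributes).
#' @examples
#' coxPartialLikelihood(c(0.5, -0.2), time = c(1, 2), event = c(1, 1),
#'                      reduction = "sum")  # log(1 + exp(-0.7))
#' @export
coxPartialLikelihood <- function(logHazards, time, event,
                                 reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  n <- length(logHazards)
  if (n == 0L) stop("empty input: no subjects")
  if (length(time) != n || length(event) != n)
    stop("logHazards, time and event must have equal length")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  ev <- which(event == 1)
  if (length(ev) == 0L) {
    warning("all subjects censored: Cox loss is 0 (no events contribute)")
    return(0)
  }
  m <- max(logHazards)
  eh <- exp(logHazards - m)
  loss <- 0
  for (i in ev) {
    inRisk <- time >= time[i]
    loss <- loss - (logHazards[i] - (m + log(sum(eh[inRisk]))))
  }
  if (reduction == "mean") loss / length(ev) else loss
}

# Gradient of the (mean-per-event) Cox loss w.r.t. logHazards.
# Returns a vector of the same length; used by the training loops.
coxLossGradient <- function(logHazards, time, event,
                            reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  n <- length(logHazards)
  ev <- which(event == 1)
  g <- numeric(n)
  if (length(ev) == 0L) return(g)
  m <- max(logHazards)
  eh <- exp(logHazards - m)
  for (i in ev) {
    inRisk <- time >= time[i]
    p <- eh * inRisk
    p <- p / sum(p)
    g <- g + p
    g[i] <- g[i] - 1
  }
  if (reduction == "mean") g / length(ev) else g
}

#' Concordance index for censored survival data
#'
#' Fraction of admissible pairs whose predicted risk ordering agrees with
#' the observed time ordering. Admissible pairs are `(i, j)` with subject
#' `i` uncensored and `time_j > time_i`; agreement means the longer-lived
#' subject `j` received the lower risk (`risk_j < risk_i`). The default
#' follows the strict-inequality definition, under which a tied prediction
#' contributes 0 to the numerator; `ties = "half"` scores tied predictions
#' 0.5, matching the convention of most survival packages.
#'
#' @param risk numeric vector of predicted risks (higher = shorter expected
#'   survival, e.g. log-hazards).
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param ties `"strict"` (default) or `"half"`.
#' @return Concordance in `[0, 1]`. Errors if no admissible pair exists.
#' @examples
#' concordanceIndex(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1)) # 1
#' @export
concordanceIndex <- function(risk, time, event, ties = c("strict", "half")) {
  ties <- match.arg(ties)
  n <- length(risk)
  if (n < 2L) stop("need at least two subjects")
  if (length(time) != n || length(event) != n)
    stop("risk, time and event must have equal length")
  laterTime <- outer(time, time, FUN = function(ti, tj) tj > ti)  # [i, j]
  admissible <- laterTime & (event == 1)                          # rows i in U
  denom <- sum(admissible)
  if (denom == 0L)
    stop("no admissible pairs: need an uncensored subject with a later-observed comparator")
  lowerRisk <- outer(risk, risk, FUN = function(ri, rj) rj < ri)
  num <- sum(admissible & lowerRisk)
  if (ties == "half") {
    tiedRisk <- outer(risk, risk, FUN = "==")
    num <- num + 0.5 * sum(admissible & tiedRisk)
  }
  num / denom
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, with the median
#' survival time defined as the first observed time at which the estimate
#' drops to 0.5 or below (`NA` if never reached). Estimation is delegated
#' to [survival::survfit()].
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @return A list of class `"kmCurve"` with elements `time`, `surv`
#'   (estimate immediately after each time), `nRisk`, `nEvent`, `median`,
#'   and `fn`, a right-continuous step function `S(t)` with `S(0) = 1`.
#' @examples
#' km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
#' km$median      # 2
#' km$fn(1.5)     # 2/3
#' @export
kaplanMeier <- function(time, event) {
  if (length(time) == 0L) stop("empty input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  s <- summary(fit, censored = TRUE)
  surv <- s$surv
  tms <- s$time
  fn <- stats::stepfun(tms, c(1, surv), right = FALSE)
  medianIdx <- which(surv <= 0.5)
  med <- if (length(medianIdx)) tms[min(medianIdx)] else NA_real_
  structure(list(time = tms, surv = surv, nRisk = s$n.risk,
                 nEvent = s$n.event, median = med, fn = fn),
            class = "kmCurve")
}

#' @export
print.kmCurve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time point(s), %d event(s), median %s\n",
              length(x$time), sum(x$nEvent),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test across survival groups
#'
#' Standard log-rank chi-square test with `k - 1` degrees of freedom for
#' `k` groups, via [survival::survdiff()].
#'
#' @param time observed times.
#' @param event 0/1 event indicators.
#' @param group group membership (factor or vector coercible to factor);
#'   at least two non-empty groups.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank test needs at least two non-empty groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Normalize predicted risks to z-scores
#'
#' Centres and scales a cohort's predicted log-hazards to mean 0, SD 1
#' (the "normalized risk score" used for reporting and group comparisons).
#'
#' @param risk numeric vector of raw risks.
#' @return numeric vector of the same length. If the risks are constant the
#'   normalized scores are all 0.
#' @export
normalizeRisk <- function(risk) {
  s <- stats::sd(risk)
  if (!is.finite(s) || s == 0) return(rep(0, length(risk)))
  (risk - mean(risk)) / s
}

#' Stratify a cohort into low/mid/high risk tertiles
#'
#' Assigns each patient to the 0-33, 33-66 or 66-100 percentile group of
#' the normalized risk score. Ties at a cut point are resolved
#' deterministically by stable sort order (first occurrence ranks first),
#' so group sizes differ by at most one when no ties straddle a cut.
#'
#' @param risk numeric vector of risks (raw or normalized; the assignment
#'   is invariant to affine transformations).
#' @return factor with levels `low`, `mid`, `high`.
#' @examples
#' stratifyByRisk(c(-1, 0, 1))  # low, mid, high
#' @export
stratifyByRisk <- function(risk) {
  n <- length(risk)
  if (n < 3L) stop("need at least 3 patients to form tertiles")
  r <- rank(risk, ties.method = "first")
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  g <- ifelse(r <= cut1, "low", ifelse(r <= cut2, "mid", "high"))
  factor(g, levels = c("low", "mid", "high"))
}

#' Read / write survival manifests and predictions
#'
#' Manifests are CSV files with at least the columns `patient_id`, `time`,
#' `event` (header required). `writePredictions()` writes a CSV with
#' columns `patient_id`, `log_hazard`, `normalized_risk`, `risk_group`.
#'
#' @param path file path.
#' @return `readManifest()`: a data.frame.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' @rdname readManifest
#' @param patientId,logHazard vectors of equal length.
#' @export
writePredictions <- function(path, patientId, logHazard) {
  z <- normalizeRisk(logHazard)
  df <- data.frame(patient_id = patientId,
                   log_hazard = logHazard,
                   normalized_risk = z,
                   risk_group = if (length(logHazard) >= 3)
                     as.character(stratifyByRisk(z)) else NA_character_,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
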