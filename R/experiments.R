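#' Deterministic per-replicate seed derivation
#'
#' Replicate `r` of a run with master seed `s` uses seed
#' `(s * 10000 + r) mod (2^31 - 1)`; an optional stage offset separates
#' the data-generation and training RNG streams of the same replicate.
#'
#' @param masterSeed integer master seed.
#' @param replicate replicate number (1-based).
#' @param stage non-negative integer stage offset.
#' @return integer seed.
#' @export
replicateSeed <- function(masterSeed, replicate, stage = 0L) {
  as.integer((as.numeric(masterSeed) * 10000 + replicate + stage * 1000) %%
               (2^31 - 1))
}

# short stable fingerprint of a configuration list
configHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}

# desk-scale DALAN configuration for a given simulated image shape: small
# backbone, 64-wide embeddings, 4 heads -- sized so the full two-stage
# protocol trains in CPU minutes
deskDalanConfig <- function(imageShape = c(28L, 28L, 1L)) {
  dalanConfig(encoder = encoderConfig("small_cnn", embeddingDim = 64L,
                                      inputShape = imageShape,
                                      channels = c(8L, 16L, 32L)),
              nHeads = 4L, lstmLayers = 2L, mlpHidden = 32L,
              bagSampleSize = 10L, inferenceDraws = 8L)
}

# one full replicate: simulate, stage-1 fine-tune, train the requested
# methods, return per-method test c-indices
runReplicate <- function(simConfig, methods, masterSeed, r, profile,
                         dalanCfg, variant = "full") {
  scfg <- simConfig
  scfg$seed <- replicateSeed(masterSeed, r)
  cohort <- buildSimulation(scfg)
  tr <- trainBags(cohort)
  te <- testBags(cohort)
  teTime <- vapply(te, function(b) b@time, numeric(1))
  teEvent <- vapply(te, function(b) b@event, numeric(1))
  set.seed(replicateSeed(masterSeed, r, stage = 1L))
  if (is.null(dalanCfg)) dalanCfg <- deskDalanConfig(scfg$imageShape)

  naive <- intersect(methods, c("average", "min", "max", "median"))
  needStage1 <- length(naive) > 0 ||
    ("dalan" %in% methods && variant != "no_finetuned_weights")
  roiModel <- if (needStage1)
    fineTuneRoiLevel(dalanCfg$encoder, tr, profile$stage1) else NULL

  out <- numeric(0)
  for (rule in naive)
    out[rule] <- evaluateBaseline(roiModel, te, rule)
  if ("dalan" %in% methods) {
    cfg <- dalanCfg
    if (variant == "no_lstm") cfg <- modifyDalanConfig(cfg, useLstm = FALSE)
    if (variant == "no_attention")
      cfg <- modifyDalanConfig(cfg, useAttention = FALSE)
    model <- initDalan(cfg,
                       roiModel = if (variant == "no_finetuned_weights")
                         NULL else roiModel,
                       freeze = variant != "no_frozen_cnn")
    model <- trainDalan(model, tr, profile$bag,
                        augment = variant != "no_augmentation")
    pr <- predictRisk(model, te, seed = replicateSeed(masterSeed, r, 2L))
    out["dalan"] <- concordanceIndex(pr$log_hazard, teTime, teEvent)
  }
  out
}

modifyDalanConfig <- function(cfg, ...) {
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "dalanConfig")
}

#' Compare DALAN against the naive aggregation baselines
#'
#' Runs `nRepeats` independent replicates. Each replicate regenerates the
#' simulated cohort (fresh weight mask and split), fine-tunes the ROI-level
#' encoder, trains DALAN from the fine-tuned trunk, evaluates every method
#' on the held-out test bags, and records the patient-level c-index.
#' Replicate failures are recorded and the run continues.
#'
#' @param simConfig a [simulationConfig()].
#' @param methods subset of `c("dalan", "average", "min", "max", "median")`.
#' @param nRepeats number of replicates.
#' @param masterSeed master seed; per-replicate seeds come from
#'   [replicateSeed()].
#' @param profile a [trainingProfile()].
#' @param dalanCfg optional [dalanConfig()]; defaults to the desk-scale
#'   configuration matching the simulated image shape.
#' @return list of class `"dalanComparison"` with `results` (one row per
#'   method x replicate: `method`, `replicate`, `cindex`, `seed`,
#'   `config_hash`), `summary` (mean and SD per method), and `failures`.
#' @export
runComparison <- function(simConfig,
                          methods = c("dalan", "average", "min", "max",
                                      "median"),
                          nRepeats = 5L, masterSeed = 1L,
                          profile = trainingProfile("desk"),
                          dalanCfg = NULL) {
  stopifnot(nRepeats >= 1)
  hash <- configHash(list(sim = unclass(simConfig), profile = profile))
  rows <- list()
  failures <- character(0)
  for (r in seq_len(nRepeats)) {
    res <- tryCatch(
      runReplicate(simConfig, methods, masterSeed, r, profile, dalanCfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    for (m in names(res))
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, replicate = r, cindex = unname(res[m]),
        seed = replicateSeed(masterSeed, r), config_hash = hash,
        stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarizeResults(results),
                 failures = failures),
            class = "dalanComparison")
}

summarizeResults <- function(results) {
  if (is.null(results) || nrow(results) == 0L)
    return(data.frame(method = character(), mean = numeric(),
                      sd = numeric(), n = integer()))
  agg <- stats::aggregate(cindex ~ method, results,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        n = length(x)))
  data.frame(method = agg$method,
             mean = agg$cindex[, "mean"],
             sd = agg$cindex[, "sd"],
             n = as.integer(agg$cindex[, "n"]),
             stringsAsFactors = FALSE)
}

#' @export
print.dalanComparison <- function(x, ...) {
  cat("Method comparison (test c-index, mean ± SD over replicates):\n")
  s <- x$summary[order(-x$summary$mean), ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %.3f ± %.3f  (n = %d)\n", s$method[i],
                s$mean[i], s$sd[i], s$n[i]))
  if (length(x$failures))
    cat("Failures:\n ", paste(x$failures, collapse = "\n  "), "\n")
  invisible(x)
}

#' Ablation study over DALAN variants
#'
#' Runs the comparison protocol for structural variants of DALAN: `"full"`
#' (the complete model), `"no_finetuned_weights"` (skip stage-1
#' fine-tuning), `"no_frozen_cnn"` (train all CNN weights),
#' `"no_lstm"` (attention-only blocks), `"no_attention"` (LSTM-only
#' blocks), `"no_augmentation"` (no training-time augmentation).
#'
#' @inheritParams runComparison
#' @param variants character vector of variant names.
#' @return list of class `"dalanComparison"` with one arm per variant.
#' @export
runAblation <- function(simConfig,
                        variants = c("full", "no_finetuned_weights",
                                     "no_frozen_cnn", "no_lstm",
                                     "no_attention", "no_augmentation"),
                        nRepeats = 5L, masterSeed = 1L,
                        profile = trainingProfile("desk"),
                        dalanCfg = NULL) {
  known <- c("full", "no_finetuned_weights", "no_frozen_cnn", "no_lstm",
             "no_attention", "no_augmentation")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unknown ablation variant(s): ",
                        paste(bad, collapse = ", "))
  hash <- configHash(list(sim = unclass(simConfig), profile = profile))
  rows <- list()
  failures <- character(0)
  for (v in variants) {
    for (r in seq_len(nRepeats)) {
      res <- tryCatch(
        runReplicate(simConfig, "dalan", masterSeed, r, profile, dalanCfg,
                     variant = v),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s replicate %d: %s", v, r,
                                        conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = v, replicate = r, cindex = unname(res["dalan"]),
        seed = replicateSeed(masterSeed, r), config_hash = hash,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results, summary = summarizeResults(results),
                 failures = failures),
            class = "dalanComparison")
}

#' Risk-group stratification report
#'
#' Normalizes predicted log-hazards, stratifies the cohort into risk
#' tertiles, estimates a Kaplan-Meier curve with median survival per
#' group, tests curve separation with the log-rank test, and -- when a
#' table of categorical clinical covariates is supplied -- compares the
#' normalized risk across each covariate's levels with a Wilcoxon rank-sum
#' test (two levels) or a Kruskal-Wallis test (more levels). Covariates
#' with fewer than two observed levels are skipped with a warning.
#'
#' @param logHazard numeric vector of patient-level log-hazards.
#' @param time,event observed survival data, same length.
#' @param covariates optional data.frame of categorical covariates
#'   (one row per patient).
#' @return list of class `"riskGroupReport"`: `group` (factor),
#'   `normalizedRisk`, `km` (per-group [kaplanMeier()] curves),
#'   `medianSurvival`, `logrank`, `covariateTests` (data.frame with
#'   `covariate`, `test`, `statistic`, `p`).
#' @export
riskGroupReport <- function(logHazard, time, event, covariates = NULL) {
  if (length(logHazard) < 3L) stop("need at least 3 patients")
  z <- normalizeRisk(logHazard)
  grp <- stratifyByRisk(z)
  km <- lapply(levels(grp), function(g)
    kaplanMeier(time[grp == g], event[grp == g]))
  names(km) <- levels(grp)
  med <- vapply(km, function(k) k$median, numeric(1))
  lr <- logrankTest(time, event, grp)
  covTests <- NULL
  if (!is.null(covariates)) {
    rows <- list()
    for (nm in names(covariates)) {
      v <- factor(covariates[[nm]])
      v <- droplevels(v[!is.na(v)])
      zv <- z[!is.na(covariates[[nm]])]
      if (nlevels(v) < 2L) {
        warning(sprintf("covariate '%s' has fewer than two levels; skipped",
                        nm))
        next
      }
      if (nlevels(v) == 2L) {
        tst <- stats::wilcox.test(zv ~ v, exact = FALSE)
        rows[[nm]] <- data.frame(covariate = nm, test = "wilcoxon",
                                 statistic = unname(tst$statistic),
                                 p = tst$p.value, stringsAsFactors = FALSE)
      } else {
        tst <- stats::kruskal.test(zv ~ v)
        rows[[nm]] <- data.frame(covariate = nm, test = "kruskal-wallis",
                                 statistic = unname(tst$statistic),
                                 p = tst$p.value, stringsAsFactors = FALSE)
      }
    }
    covTests <- if (length(rows)) do.call(rbind, c(rows,
                                                   make.row.names = FALSE))
                else data.frame(covariate = character(), test = character(),
                                statistic = numeric(), p = numeric())
  }
  structure(list(group = grp, normalizedRisk = z, km = km,
                 medianSurvival = med, logrank = lr,
                 covariateTests = covTests),
            class = "riskGroupReport")
}

#' @export
print.riskGroupReport <- function(x, ...) {
  cat("Risk-group report (tertiles of normalized risk):\n")
  for (g in names(x$km))
    cat(sprintf("  %-4s n = %3d, median survival %s\n", g,
                sum(x$group == g),
                if (is.na(x$medianSurvival[g])) "not reached"
                else format(x$medianSurvival[g], digits = 4)))
  cat(sprintf("  log-rank chi-square = %.3f (df %d), p = %.3g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  if (!is.null(x$covariateTests) && nrow(x$covariateTests))
    for (i in seq_len(nrow(x$covariateTests)))
      cat(sprintf("  %s: %s p = %.3g\n", x$covariateTests$covariate[i],
                  x$covariateTests$test[i], x$covariateTests$p[i]))
  invisible(x)
}
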