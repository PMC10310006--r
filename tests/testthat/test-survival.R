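test_that("Cox partial-likelihood loss matches hand-derived forms", {
  # single uncensored subject: its term h - log exp(h) vanishes
  expect_equal(coxPartialLikelihood(1.7, 3, 1, reduction = "sum"), 0)
  expect_equal(coxPartialLikelihood(-4, 3, 1), 0)
  # two subjects, both events, t1 < t2: loss = log(1 + exp(h2 - h1))
  for (d in c(-3, -0.5, 0, 0.5, 3)) {
    expect_equal(
      coxPartialLikelihood(c(0.2, 0.2 + d), c(1, 2), c(1, 1), "sum"),
      log(1 + exp(d)))
  }
  # mean reduction divides the sum by the number of events
  lh <- c(0.3, -1, 2, 0.1)
  tt <- c(2, 1, 4, 3); ev <- c(1, 1, 0, 1)
  expect_equal(coxPartialLikelihood(lh, tt, ev, "mean"),
               coxPartialLikelihood(lh, tt, ev, "sum") / 3)
})

test_that("Cox loss handles degenerate inputs as specified", {
  expect_error(coxPartialLikelihood(numeric(0), numeric(0), numeric(0)),
               "empty")
  expect_warning(out <- coxPartialLikelihood(c(1, 2), c(1, 2), c(0, 0)),
                 "censored")
  expect_equal(out, 0)
  expect_error(coxPartialLikelihood(c(1, 2), c(1, 2, 3), c(1, 1, 1)),
               "equal length")
})

test_that("Cox loss is invariant to constant shifts of the log-hazards", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    lh <- rnorm(n); tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    base <- coxPartialLikelihood(lh, tt, ev)
    for (shift in c(-50, -1, 2, 100)) {
      expect_equal(coxPartialLikelihood(lh + shift, tt, ev), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("Cox loss gradient matches finite differences", {
  set.seed(3)
  lh <- rnorm(6); tt <- rexp(6); ev <- c(1, 0, 1, 1, 0, 1)
  g <- dalan:::coxLossGradient(lh, tt, ev)
  eps <- 1e-6
  for (i in seq_along(lh)) {
    p <- lh; p[i] <- p[i] + eps
    m <- lh; m[i] <- m[i] - eps
    num <- (coxPartialLikelihood(p, tt, ev) -
              coxPartialLikelihood(m, tt, ev)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("concordance index follows the strict pairwise definition", {
  # risks anti-ordered with times, all uncensored: perfect concordance
  expect_equal(concordanceIndex(c(5, 4, 1, 0), 1:4, rep(1, 4)), 1)
  # identical predictions: strict indicator never fires; half-credit = 0.5
  expect_equal(concordanceIndex(rep(2, 4), 1:4, rep(1, 4)), 0)
  expect_equal(concordanceIndex(rep(2, 4), 1:4, rep(1, 4), ties = "half"),
               0.5)
  expect_error(concordanceIndex(1, 1, 1), "two")
  # censored subjects form no admissible pairs as the earlier member
  expect_error(concordanceIndex(c(1, 2), c(1, 2), c(0, 0)), "admissible")
})

test_that("concordance index equals the brute-force pair oracle", {
  set.seed(21)
  for (rep in 1:50) {
    inst <- randomSurvivalInstance(sample(4:30, 1))
    ok <- tryCatch(bruteForceCIndex(inst$risk, inst$time, inst$event),
                   error = function(e) NULL)
    if (is.null(ok)) next
    expect_identical(concordanceIndex(inst$risk, inst$time, inst$event), ok)
    expect_identical(
      concordanceIndex(inst$risk, inst$time, inst$event, ties = "half"),
      bruteForceCIndex(inst$risk, inst$time, inst$event, ties = "half"))
  }
})

test_that("half-tie concordance agrees with survival::concordance", {
  set.seed(5)
  n <- 80
  tt <- rexp(n); ev <- rbinom(n, 1, 0.6); risk <- rnorm(n)
  ours <- concordanceIndex(risk, tt, ev, ties = "half")
  ref <- survival::concordance(survival::Surv(tt, ev) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("risks independent of outcome give chance-level concordance", {
  set.seed(31)
  n <- 2000
  tt <- rexp(n); ev <- rbinom(n, 1, 0.5); risk <- rnorm(n)
  expect_lt(abs(concordanceIndex(risk, tt, ev) - 0.5), 0.03)
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # all events at distinct times
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 2)
  expect_equal(km$fn(0), 1)
  expect_equal(km$fn(1.5), 2 / 3)
  # all censored: flat at 1, median never reached
  km <- kaplanMeier(c(1, 2, 5), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))
  # single event
  km <- kaplanMeier(5, 1)
  expect_equal(km$fn(4.9), 1)
  expect_equal(km$fn(5), 0)
  expect_equal(km$median, 5)
  # censoring between events: S = 1 * 3/4 at t=1, then (3/4)*(1/2) at t=3
  km <- kaplanMeier(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km$fn(1.5), 3 / 4)
  expect_equal(km$fn(3.5), 3 / 8)
  expect_true(is.na(km$median) == FALSE)
  # tied event times: both leave at once
  km <- kaplanMeier(c(2, 2, 4), c(1, 1, 1))
  expect_equal(km$fn(2), 1 / 3)
  expect_equal(km$median, 2)
  expect_error(kaplanMeier(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier curves are non-increasing and right-continuous", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:60, 1)
    tt <- rexp(n); ev <- rbinom(n, 1, 0.5)
    km <- kaplanMeier(tt, ev)
    expect_true(all(diff(km$surv) <= 1e-12))
    # right continuity: value at an event time equals the post-jump level
    for (t in km$time[km$nEvent > 0])
      expect_equal(km$fn(t), km$surv[match(t, km$time)])
  }
})

test_that("log-rank test behaves at its reference points", {
  tt <- c(1, 2, 3, 4)
  ev <- c(1, 1, 0, 1)
  same <- logrankTest(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  # well-separated exponential samples
  set.seed(17)
  t1 <- rexp(100, 1); t2 <- rexp(100, 10)
  lr <- logrankTest(c(t1, t2), rep(1, 200), rep(c("s", "f"), each = 100))
  expect_lt(lr$p, 0.001)
  expect_equal(lr$df, 1L)
  expect_error(logrankTest(tt, ev, rep("a", 4)), "two")
})

test_that("risk normalization yields z-scores and tolerates constants", {
  set.seed(19)
  r <- rnorm(50, 5, 3)
  z <- normalizeRisk(r)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sd(z), 1, tolerance = 1e-6)
  expect_equal(normalizeRisk(rep(2, 5)), rep(0, 5))
})

test_that("tertile stratification partitions by rank with stable ties", {
  expect_equal(as.character(stratifyByRisk(c(-1, 0, 1))),
               c("low", "mid", "high"))
  g <- stratifyByRisk(seq(9, 1))  # 9 distinct values, descending
  expect_equal(unname(table(g)), as.array(c(3L, 3L, 3L)),
               ignore_attr = TRUE)
  expect_error(stratifyByRisk(c(1, 2)), "3 patients")
  # duplicates at a cut point resolve by first occurrence
  g2 <- stratifyByRisk(c(0, 0, 0, 1, 2, 3))
  expect_equal(as.character(g2), c("low", "low", "mid", "mid", "high",
                                   "high"))
  # group sizes differ by at most 1 for arbitrary n without ties
  for (n in c(4, 5, 7, 10, 11)) {
    tbl <- table(stratifyByRisk(rnorm(n)))
    expect_lte(max(tbl) - min(tbl), 1)
  }
})

test_that("stratification is invariant to affine transformation of risks", {
  set.seed(23)
  for (rep in 1:10) {
    r <- rnorm(sample(5:40, 1))
    g <- stratifyByRisk(r)
    expect_identical(g, stratifyByRisk(3.7 * r - 11))
    expect_identical(g, stratifyByRisk(normalizeRisk(r)))
  }
})

test_that("prediction manifests round-trip through CSV", {
  set.seed(29)
  path <- tempfile(fileext = ".csv")
  df <- writePredictions(path, sprintf("P%02d", 1:6), rnorm(6))
  back <- utils::read.csv(path)
  expect_equal(names(back), c("patient_id", "log_hazard", "normalized_risk",
                              "risk_group"))
  expect_equal(back$log_hazard, df$log_hazard)
  expect_equal(sort(unique(back$risk_group)), c("high", "low", "mid"))
  # manifest reader enforces the mandatory columns
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(patient_id = "x", time = 1), bad,
                   row.names = FALSE)
  expect_error(readManifest(bad), "event")
})
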