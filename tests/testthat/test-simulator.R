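test_that("weight masks are reproducible uniform draws of the right shape", {
  m1 <- generateWeightMask(c(28, 28, 1), seed = 7)
  m2 <- generateWeightMask(c(28, 28, 1), seed = 7)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(28, 28, 1))
  expect_true(all(m1 >= 0 & m1 <= 1))
  big <- generateWeightMask(c(100, 100, 100), seed = 1)
  expect_lt(abs(mean(big) - 0.5), 0.01)
  expect_error(generateWeightMask(c(0, 28, 1), seed = 1), "positive")
})

test_that("ROI survival time implements the weighted-mean exponential law", {
  img <- array(1, c(4, 4, 1)); msk <- array(1, c(4, 4, 1))
  # degenerate all-one image and mask with noise disabled: T = e
  expect_equal(roiSurvivalTime(img, msk, noiseScale = 0), exp(1))
  # fixed noise draw makes T bit-reproducible
  expect_identical(roiSurvivalTime(img, msk, 0.001, eps = 1.3),
                   roiSurvivalTime(img, msk, 0.001, eps = 1.3))
  # strict monotonicity under pixelwise dominance at fixed mask and noise
  set.seed(5)
  a <- array(runif(16, 0, 0.5), c(4, 4, 1))
  b <- a; b[2, 3, 1] <- b[2, 3, 1] + 0.3
  m <- generateWeightMask(c(4, 4, 1), seed = 2)
  expect_lt(roiSurvivalTime(a, m, eps = 0.8), roiSurvivalTime(b, m, eps = 0.8))
  expect_error(roiSurvivalTime(a, array(1, c(3, 4, 1))), "dimensions")
})

test_that("noise term has the log-normal median exp(noiseScale)", {
  set.seed(41)
  zero <- array(0, c(4, 4, 1)); msk <- array(0.5, c(4, 4, 1))
  draws <- replicate(20000, roiSurvivalTime(zero, msk, noiseScale = 0.001))
  expect_lt(abs(median(draws) - exp(0.001)), 0.002)
  expect_true(all(draws > 0))
})

test_that("patient survival time is the mean of ROI times", {
  expect_equal(patientSurvivalTime(c(2, 4)), 3)
  expect_equal(patientSurvivalTime(5.5), 5.5)
  expect_equal(patientSurvivalTime(rep(1.2, 7)), 1.2)
  expect_error(patientSurvivalTime(numeric(0)), "empty")
})

test_that("censoring selects an exact fraction and shortens observed times", {
  set.seed(43)
  tt <- rexp(1000) + 0.1
  none <- applyCensoring(tt, 0)
  expect_true(all(none$event == 1))
  expect_equal(none$time, tt)
  all <- applyCensoring(tt, 1)
  expect_true(all(all$event == 0))
  expect_true(all(all$time < tt))
  expect_true(all(all$time >= 0))
  half <- applyCensoring(tt, 0.5)
  expect_equal(sum(half$event == 0), 500)
  expect_true(all(half$time[half$event == 0] < tt[half$event == 0]))
  expect_true(all(half$time[half$event == 1] == tt[half$event == 1]))
  expect_error(applyCensoring(tt, 1.5), "censorFraction")
})

test_that("digit-like generators differ in ink and are reproducible", {
  z <- synthDigitImages("zero-like", 3, seed = 9)
  s <- synthDigitImages("six-like", 3, seed = 9)
  for (img in c(z, s)) {
    expect_equal(dim(img), c(28, 28, 1))
    expect_true(all(img >= 0 & img <= 1))
  }
  expect_identical(z, synthDigitImages("zero-like", 3, seed = 9))
  expect_error(synthDigitImages("eight-like", 1), "arg")
  # class separation in mean total intensity, detectable by rank-sum
  set.seed(47)
  mz <- vapply(synthDigitImages("zero-like", 500), mean, numeric(1))
  ms <- vapply(synthDigitImages("six-like", 500), mean, numeric(1))
  expect_lt(wilcox.test(mz, ms)$p.value, 0.01)
  # overlap in intensity still leaves within-class variation
  expect_gt(sd(mz), 0.001)
})

test_that("texture images span a wide brightness range", {
  imgs <- synthTextureImages(1000, c(16L, 16L, 3L), heterogeneity = 1,
                             seed = 3)
  means <- vapply(imgs, mean, numeric(1))
  expect_lte(min(means), 0.2)
  expect_gte(max(means), 0.8)
  expect_true(all(vapply(imgs, function(i) all(i >= 0 & i <= 1),
                         logical(1))))
  flat <- synthTextureImages(50, c(16L, 16L, 3L), heterogeneity = 0,
                             seed = 3)
  expect_lt(sd(vapply(flat, mean, numeric(1))), 0.02)
  expect_identical(synthTextureImages(2, c(16L, 16L, 3L), seed = 8),
                   synthTextureImages(2, c(16L, 16L, 3L), seed = 8))
})

test_that("simulated cohorts respect the configured design", {
  cfg <- simulationConfig("two_roi_digit", nPatients = 100, seed = 31)
  co <- buildSimulation(cfg)
  df <- survivalData(co)
  expect_equal(nrow(df), 100)
  expect_equal(sum(df$split == "train"), 80)
  expect_equal(sum(df$split == "test"), 20)
  expect_equal(sum(df$event == 0), 50)   # 50% censoring, exactly
  expect_true(all(df$n_rois == 2))
  expect_false(anyDuplicated(df$patient_id) > 0)
  # censored records observe less than their true time, events exactly it
  expect_true(all(df$time[df$event == 0] < df$true_time[df$event == 0]))
  expect_equal(df$time[df$event == 1], df$true_time[df$event == 1])
  # reproducibility of the whole cohort
  expect_identical(survivalData(buildSimulation(cfg)), df)
  # distinct seeds give distinct masks
  cfg2 <- simulationConfig("two_roi_digit", nPatients = 100, seed = 32)
  expect_false(identical(cohortMask(buildSimulation(cfg2)), cohortMask(co)))
})

test_that("bag true times equal the mean of the per-ROI time law", {
  cfg <- simulationConfig("two_roi_digit", nPatients = 15, seed = 3,
                          noiseScale = 0)
  co <- buildSimulation(cfg)
  m <- cohortMask(co)
  for (b in bags(co)) {
    tRois <- vapply(b@rois, function(i) exp(mean(i * m)), numeric(1))
    expect_equal(b@trueTime, mean(tRois), tolerance = 1e-12)
  }
})

test_that("the weighted-intensity oracle orders a noise-free simulation", {
  cfg <- simulationConfig("two_roi_digit", nPatients = 80, seed = 13,
                          noiseScale = 0, censorFraction = 0)
  co <- buildSimulation(cfg)
  m <- cohortMask(co)
  df <- survivalData(co)
  risk <- vapply(bags(co), function(b)
    -mean(vapply(b@rois, function(i) mean(i * m), numeric(1))), numeric(1))
  expect_gte(concordanceIndex(risk, df$time, df$event), 0.97)
})

test_that("texture design and per-ROI mask switches work", {
  cfg <- simulationConfig("multi_roi_texture", nPatients = 10, seed = 5,
                          imageShape = c(16L, 16L, 3L),
                          roisPerPatient = c(2L, 4L))
  co <- buildSimulation(cfg)
  k <- survivalData(co)$n_rois
  expect_true(all(k >= 2 & k <= 4))
  cfgm <- simulationConfig("two_roi_digit", nPatients = 10, seed = 5,
                           maskPerRoi = TRUE)
  expect_s4_class(buildSimulation(cfgm), "BagCohort")
  expect_error(simulationConfig("two_roi_digit", roisPerPatient = 5),
               "two ROIs")
})

test_that("cohorts export to PNG + manifest and import back", {
  co <- tinyCohort(n = 5, seed = 19)
  dir <- tempfile()
  manifest <- exportCohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), sum(survivalData(co)$n_rois))
  co2 <- importCohort(dir)
  df1 <- survivalData(co)
  df2 <- survivalData(co2)
  ord <- match(df1$patient_id, df2$patient_id)
  expect_equal(df2$time[ord], df1$time, tolerance = 1e-6)
  expect_equal(df2$event[ord], df1$event)
  expect_identical(df2$split[ord], df1$split)
  # pixel content survives the 8-bit PNG round trip
  b1 <- bags(co)[[1]]
  b2 <- bags(co2)[[match(b1@patientId, df2$patient_id)]]
  expect_lt(max(abs(b1@rois[[1]] - b2@rois[[1]])), 1 / 255)
})
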