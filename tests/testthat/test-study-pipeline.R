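test_that("record validation enforces the study schema", {
  ok <- data.frame(subject_id = "S01", tooth = "16", surface = "vestibular",
                   timepoint = "T1", method = "scan", p_percent = 12.2)
  expect_silent(validateRecords(ok))
  camOk <- ok; camOk$method <- "camera"
  expect_silent(validateRecords(camOk))

  bad <- ok; bad$tooth <- "17"
  expect_error(validateRecords(bad), "not a Ramfjord tooth")
  badCam <- data.frame(subject_id = "S01", tooth = "21",
                       surface = "vestibular", timepoint = "T1",
                       method = "camera", p_percent = 5)
  expect_error(validateRecords(badCam), "camera records")
  badP <- ok; badP$p_percent <- 101
  expect_error(validateRecords(badP), "p_percent")
  dup <- rbind(ok, ok)
  expect_error(validateRecords(dup), "duplicate")
  # row numbers are reported
  expect_error(validateRecords(rbind(ok, bad)), "row 2")
})

test_that("records survive a CSV round trip", {
  st <- generateLongitudinalStudy(3, seed = 5)
  path <- tempfile(fileext = ".csv")
  writeRecords(st$records, path)
  back <- loadRecords(path)
  expect_equal(back$p_percent, st$records$p_percent, tolerance = 1e-12)
  expect_identical(back$tooth, st$records$tooth)
})

test_that("subject-level means follow the six-tooth definition", {
  rec <- tinyStudyRecords(4)
  # subject with all six vestibular values equal to v has mean v
  v <- 11.5
  rec$p_percent[rec$subject_id == "S01" & rec$surface == "vestibular" &
                  rec$timepoint == "T1"] <- v
  s <- subjectLevelSummary(rec, "vestibular", nBoot = 100, seed = 1)
  m <- s$subjectMeans
  expect_equal(m$mean_p[m$subject_id == "S01" & m$timepoint == "T1"], v)

  # explicit sort-and-middle oracle for the across-subject median
  t2 <- m$mean_p[m$timepoint == "T2"]
  srt <- sort(t2)
  oracleMed <- if (length(srt) %% 2 == 1) srt[(length(srt) + 1) / 2] else
    mean(srt[length(srt) / 2 + 0:1])
  expect_equal(s$timepointSummary$median[
    s$timepointSummary$timepoint == "T2"], oracleMed)

  # a missing site is an error, never silently averaged
  incomplete <- rec[!(rec$subject_id == "S02" & rec$tooth == "24" &
                        rec$surface == "vestibular" & rec$timepoint == "T1"), ]
  expect_error(subjectLevelSummary(incomplete, "vestibular"), "missing teeth")
})

test_that("site-level table matches loop oracles and pools correctly", {
  rec <- tinyStudyRecords(5)
  site <- siteLevelSummary(rec, nBoot = 200, seed = 2)
  # every per-site cell against direct computation
  for (i in which(site$tooth != "All")) {
    v <- rec$p_percent[rec$tooth == site$tooth[i] &
                         rec$surface == site$surface[i] &
                         rec$timepoint == site$timepoint[i]]
    expect_equal(site$median[i], median(v))
    expect_equal(site$min[i], min(v))
    expect_equal(site$max[i], max(v))
    expect_identical(site$n[i], length(v))
  }
  # the "All" row is recomputable from the union of the 12 site cells
  for (tp in c("T1", "T2", "T3")) {
    pooled <- rec$p_percent[rec$timepoint == tp]
    i <- which(site$tooth == "All" & site$timepoint == tp)
    expect_equal(site$median[i], median(pooled))
    expect_equal(site$min[i], min(pooled))
    expect_equal(site$max[i], max(pooled))
    expect_identical(site$n[i], length(pooled))
  }
  # constant cell collapses its CI
  constRec <- tinyStudyRecords(3)
  constRec$p_percent <- 9
  s2 <- siteLevelSummary(constRec, nBoot = 100, seed = 1)
  expect_true(all(s2$ci_low == 9 & s2$ci_high == 9))
})

test_that("percent change reproduces the reference worked example", {
  med <- referenceSiteMedians()
  all3 <- med[med$tooth == "All", ]
  t1 <- all3$median[all3$timepoint == "T1"]
  t2 <- all3$median[all3$timepoint == "T2"]
  t3 <- all3$median[all3$timepoint == "T3"]
  expect_identical(percentChange(t1, t2, "increase"), 47L)
  expect_identical(percentChange(t2, t3, "decrease"), 43L)
  expect_identical(percentChange(8, 8, "increase"), 0L)
  expect_error(percentChange(0, 5, "increase"), "base")
})

test_that("timepoint comparisons carry the Bonferroni schedule", {
  st <- generateLongitudinalStudy(10, seed = 3)
  subj <- compareTimepoints(st$records, "subject")
  expect_identical(nrow(subj), 4L)
  expect_equal(unique(subj$alpha_adjusted), 0.05 / 6)
  site <- compareTimepoints(st$records, "site")
  expect_identical(nrow(site), 24L)
  expect_equal(unique(site$alpha_adjusted), 0.05 / 24)
  ovv <- compareTimepoints(st$records, "oral_vs_vestibular_subject")
  expect_identical(nrow(ovv), 3L)
  expect_equal(unique(ovv$alpha_adjusted), 0.05 / 3)
  expect_identical(subj$significant, subj$p_value <= subj$alpha_adjusted)

  one <- st$records[st$records$subject_id == "S01", ]
  expect_error(compareTimepoints(one, "subject"), "at least 2")
})

test_that("method agreement pairs camera and scan per tooth", {
  st <- generateLongitudinalStudy(6, seed = 8)
  rec <- st$records
  camSites <- rec[rec$tooth %in% c("16", "36") &
                    rec$surface == "vestibular", ]
  cam <- camSites
  cam$method <- "camera"
  # identical methods: zero bias
  rep0 <- methodAgreementReport(rbind(rec, cam))
  expect_equal(rep0[["16"]]$blandAltman@bias, 0)
  expect_equal(rep0[["36"]]$blandAltman@bias, 0)

  # constant ratio: every log difference is -ln(1.05)
  cam2 <- cam
  cam2$p_percent <- camSites$p_percent / 1.05   # scan = 1.05 x camera
  rep1 <- methodAgreementReport(rbind(rec, cam2))
  expect_equal(rep1[["16"]]$blandAltman@bias, -log(1.05), tolerance = 1e-10)
  expect_equal(rep1[["16"]]$blandAltman@sdDiff, 0, tolerance = 1e-10)
  expect_equal(rep1[["16"]]$spearman@statistic, 1)

  # incomplete pairs are an error
  expect_error(methodAgreementReport(rbind(rec, cam[-1, ])), "incomplete")
})

test_that("reproducibility report is exact for identical repeats", {
  st <- generateLongitudinalStudy(5, seed = 12)
  rec <- st$records
  same <- reproducibilityReport(rec, rec, nBoot = 200, seed = 1)
  expect_equal(same@medianDiff@point, 0)
  expect_equal(same@icc@icc, 1)

  # small seeded noise: high ICC, equal to the ANOVA oracle
  noisy <- rec
  set.seed(42)
  noisy$p_percent <- pmin(pmax(rec$p_percent + rnorm(nrow(rec), 0, 0.5), 0),
                          100)
  rep2 <- reproducibilityReport(rec, noisy, nBoot = 200, seed = 1)
  expect_gt(rep2@icc@icc, 0.95)
  expect_equal(rep2@icc@icc,
               oracleICCA1(cbind(rec$p_percent, noisy$p_percent)),
               tolerance = 1e-10)
  expect_error(reproducibilityReport(rec, noisy[-1, ]), "identical sites")
})

test_that("study summaries are deterministic end to end", {
  st <- generateLongitudinalStudy(8, seed = 6)
  s1 <- summarizeStudy(st$records, nBoot = 200, seed = 4)
  s2 <- summarizeStudy(st$records, nBoot = 200, seed = 4)
  j1 <- jsonlite::toJSON(list(s1@siteTable, s1@subjectTable, s1@changes,
                              s1@tests), digits = NA)
  j2 <- jsonlite::toJSON(list(s2@siteTable, s2@subjectTable, s2@changes,
                              s2@tests), digits = NA)
  expect_identical(j1, j2)
  expect_true(all(s1@siteTable$median >= 0 & s1@siteTable$median <= 100))
})

test_that("the image pipeline recovers the injected effect directions", {
  tmpl <- sceneSpec(width = 64, height = 64, toothSemiAxes = c(22, 26),
                    nBlobs = 2L)
  st <- generateLongitudinalStudy(4, seed = 19, render = TRUE,
                                  renderSpec = tmpl)
  measured <- st$records
  # scan workflow: homogeneous illumination, so one threshold calibrated on
  # the most-stained image serves the whole batch
  ref <- st$scenes[[which.max(st$records$p_percent)]]
  cfg <- calibrateRedThreshold(ref@image)
  for (i in seq_len(nrow(measured))) {
    measured$p_percent[i] <- measurePlaque(st$scenes[[i]]@image, cfg,
                                           method = "scan")@pPercent
  }
  sv <- subjectLevelSummary(measured, "vestibular", nBoot = 100,
                            seed = 1)$timepointSummary
  expect_gt(sv$median[sv$timepoint == "T2"], sv$median[sv$timepoint == "T1"])
  expect_lt(sv$median[sv$timepoint == "T3"], sv$median[sv$timepoint == "T2"])
  # measured values stay close to the drawn truth throughout
  expect_lt(max(abs(measured$p_percent - st$records$p_percent)), 1.5)
})
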