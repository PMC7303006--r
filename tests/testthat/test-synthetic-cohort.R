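test_that("planted components are connected, exact-sized, and deterministic", {
  e <- plantComponent(4, 3, seed = 1)
  expect_equal(nrow(e), 3)
  expect_lte(length(unique(as.vector(e))), 4)
  expect_length(oracleComponents(e), 1)

  for (s in c(7, 8, 9)) {
    e <- plantComponent(50, 20, seed = s)
    expect_equal(nrow(e), 20)
    expect_equal(anyDuplicated(edgeKey(e)), 0L)
    # exactly one connected component among incident nodes (brute force)
    expect_length(oracleComponents(e), 1)
  }
  expect_identical(plantComponent(50, 20, seed = 7),
                   plantComponent(50, 20, seed = 7))
  expect_error(plantComponent(3, 4), "exceeds")
})

test_that("null cohorts have zero expected group difference on planted edges", {
  cfg <- smallCohortConfig(20, c(control = 4, remitter = 30,
                                 nonremitter = 30),
                           plantedEdgeCount = 8, effectDelta = 0,
                           postShiftNonremitter = 0, seed = 2)
  coh <- generateEdgeCohort(cfg)
  gt <- groundTruth(coh)
  sl <- cohortSlice(coh, "baseline", c("remitter", "nonremitter"))
  diff <- mean(sl$z[sl$labels == "remitter", gt$plantedIdx]) -
    mean(sl$z[sl$labels == "nonremitter", gt$plantedIdx])
  # Monte-Carlo error of the mean difference over 8 edges x 30 subjects
  se <- sqrt(2 * (0.25^2 + 0.05^2) / (30 * 8))
  expect_lt(abs(diff), 4 * se)
})

test_that("planted effect size is recovered at large n (law of large numbers)", {
  cfg <- smallCohortConfig(20, c(control = 4, remitter = 58,
                                 nonremitter = 105),
                           plantedEdgeCount = 10, effectDelta = 0.15,
                           seed = 3)
  coh <- generateEdgeCohort(cfg)
  gt <- groundTruth(coh)
  sl <- cohortSlice(coh, "baseline", c("remitter", "nonremitter"))
  diff <- mean(sl$z[sl$labels == "remitter", gt$plantedIdx]) -
    mean(sl$z[sl$labels == "nonremitter", gt$plantedIdx])
  expect_lt(abs(diff - 0.15), 0.04)
})

test_that("non-remitters shift on planted edges only at the second timepoint", {
  cfg <- smallCohortConfig(20, c(control = 4, remitter = 40,
                                 nonremitter = 40),
                           plantedEdgeCount = 10, effectDelta = 0,
                           postShiftNonremitter = 0.2, seed = 4)
  coh <- generateEdgeCohort(cfg)
  gt <- groundTruth(coh)
  pre <- cohortSlice(coh, "baseline", "nonremitter")$z
  post <- cohortSlice(coh, "week8", "nonremitter")$z
  shift <- mean(post[, gt$plantedIdx]) - mean(pre[, gt$plantedIdx])
  other <- mean(post[, -gt$plantedIdx]) - mean(pre[, -gt$plantedIdx])
  expect_lt(abs(shift - 0.2), 0.05)
  expect_lt(abs(other), 0.05)
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- smallCohortConfig(seed = 11)
  a <- SummarizedExperiment::assay(generateEdgeCohort(cfg), "z")
  b <- SummarizedExperiment::assay(generateEdgeCohort(cfg), "z")
  expect_identical(a, b)
  cfg2 <- smallCohortConfig(seed = 12)
  expect_false(identical(
    a, SummarizedExperiment::assay(generateEdgeCohort(cfg2), "z")))
})

test_that("materialized connectomes are symmetric with zero diagonal", {
  coh <- generateEdgeCohort(smallCohortConfig(seed = 5))
  cn <- cohortConnectome(coh, "S001", "baseline")
  z <- zMatrix(cn)
  expect_identical(z, t(z))
  expect_true(all(diag(z) == 0))
})

test_that("clinical tables satisfy the remission rule and exact allocation", {
  cfg <- smallCohortConfig(20, c(control = 10, remitter = 30,
                                 nonremitter = 30), seed = 6)
  coh <- generateEdgeCohort(cfg)
  cl <- generateClinicalTable(coh, clinicalSimConfig(seed = 6))
  expect_equal(nrow(cl), 70)
  expect_true(all(cl$hrsd17_week8[cl$outcome == "remitter"] <= 7))
  expect_true(all(cl$hrsd17_week8[cl$outcome == "nonremitter"] > 7))
  expect_identical(labelRemission(cl$hrsd17_week8[cl$group == "MDD"]),
                   cl$outcome[cl$group == "MDD"])
  # 1:1:1 allocation over three arms at n = 30 per outcome is exactly 10/10/10
  expect_equal(unname(table(cl$drug_arm[cl$outcome == "remitter"])),
               c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_true(all(is.na(cl$drug_arm[cl$group == "control"])))
  expect_true(all(cl$hrsd17_baseline[cl$group == "MDD"] >= 16))
})

test_that("baseline severity matches the configured mean at large n", {
  subj <- data.frame(subject_id = sprintf("S%05d", 1:10000),
                     outcome = rep(c("remitter", "nonremitter"), 5000))
  cl <- generateClinicalTable(subj, clinicalSimConfig(seed = 8))
  # truncation at the entry criterion (>= 16) raises the realized mean a bit
  expect_lt(abs(mean(cl$hrsd17_baseline) - 21.7), 1.0)
  # age truncation to 18..65 pulls the realized mean slightly below target
  expect_lt(abs(mean(cl$age[cl$outcome == "nonremitter"]) - 36.6), 2.0)
})

test_that("cohorts round-trip through the plain-text representation", {
  coh <- generateEdgeCohort(smallCohortConfig(10, c(control = 2,
                                                    remitter = 2,
                                                    nonremitter = 2),
                                              plantedEdgeCount = 4,
                                              seed = 7))
  dir <- withr::local_tempdir()
  man <- writeCohort(coh, dir)
  expect_true(all(file.exists(man$file)))
  p <- loadParcellation(file.path(dir, "parcellation.tsv"))
  expect_equal(networkLabels(p), networkLabels(parcellation(coh)))
  cn <- readConnectome(man$file[1], p, man$subject_id[1], man$timepoint[1])
  expect_equal(zMatrix(cn),
               edgesToMatrix(SummarizedExperiment::assay(coh, "z")[, 1], 10),
               tolerance = 1e-6)
})
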