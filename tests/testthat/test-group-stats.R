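test_that("remission labeling follows the week-8 cutoff", {
  expect_equal(labelRemission(7), "remitter")
  expect_equal(labelRemission(8), "nonremitter")
  expect_equal(labelRemission(13.3), "nonremitter")
  expect_warning(out <- labelRemission(c(5, NA)), "not-applicable")
  expect_equal(out, c("remitter", "not-applicable"))
})

test_that("outcome-by-drug ANOVA matches hand decompositions", {
  # balanced 2x3 with equal cell means -> zero F for every effect
  rec <- data.frame(outcome = rep(c("R", "NR"), each = 6),
                    drug_arm = rep(c("E", "S", "V"), 4))
  v <- rep(c(-1, 1), 6)   # every cell is {-1, 1}
  a <- anovaOutcomeByDrug(v, rec)
  expect_equal(a$F, rep(0, 3), tolerance = 1e-12)
  expect_equal(a$p, rep(1, 3), tolerance = 1e-12)

  # balanced 2x2: compare against a brute-force Type-III GLM fit
  set.seed(30)
  rec2 <- data.frame(outcome = rep(c("R", "NR"), each = 8),
                     drug_arm = rep(rep(c("E", "S"), each = 4), 2))
  v2 <- rnorm(16) + 0.8 * (rec2$outcome == "R") +
    0.5 * (rec2$outcome == "R") * (rec2$drug_arm == "S")
  a2 <- anovaOutcomeByDrug(v2, rec2)
  for (nm in c("outcome", "drug_arm", "outcome:drug_arm")) {
    eff <- sub("drug_arm", "drug", nm)
    o <- oracleTypeIIIF(v2, list(outcome = rec2$outcome,
                                 drug = rec2$drug_arm), eff)
    expect_equal(a2$F[a2$effect == eff], o$F, tolerance = 1e-8)
    expect_equal(a2$p[a2$effect == eff], o$p, tolerance = 1e-8)
  }

  # unbalanced design against the same oracle
  rec3 <- data.frame(outcome = c(rep("R", 5), rep("NR", 11)),
                     drug_arm = c("E", "E", "S", "S", "S",
                                  rep(c("E", "S"), c(4, 7))))
  v3 <- rnorm(16)
  a3 <- anovaOutcomeByDrug(v3, rec3)
  o3 <- oracleTypeIIIF(v3, list(outcome = rec3$outcome,
                                drug = rec3$drug_arm), "outcome:drug")
  expect_equal(a3$F[a3$effect == "outcome:drug"], o3$F, tolerance = 1e-8)

  expect_error(anovaOutcomeByDrug(v, data.frame(outcome = rep("R", 12),
                                                drug_arm = rec$drug_arm)),
               "2 levels")
  rec4 <- rec; rec4$drug_arm[rec4$outcome == "R"] <- "E"
  expect_error(anovaOutcomeByDrug(v, rec4), "empty design cell")
})

test_that("single-factor ANOVA reduces to the squared t and handles confounds", {
  set.seed(31)
  g <- rep(c("MDD", "control"), c(12, 10))
  v <- rnorm(22) + 0.5 * (g == "MDD")
  a <- anovaGroup(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  # groups with identical value multisets -> F = 0, p = 1
  v0 <- c(1:10, 1:10, 5.5, 5.5)          # both group means exactly 5.5
  g0 <- rep(c("control", "MDD"), c(10, 12))
  a0 <- anovaGroup(v0, g0)
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1, tolerance = 1e-12)
  # a covariate fully explaining the group difference kills the effect
  set.seed(77)
  conf <- rnorm(100)
  v2 <- 2 * conf + rnorm(100)
  gg <- ifelse(conf > 0, "MDD", "control")   # group = f(confound)
  raw <- anovaGroup(v2, gg)
  adj <- anovaGroup(v2, gg, covariates = data.frame(conf = conf))
  expect_lt(raw$p[1], 1e-6)
  expect_gt(adj$p[adj$effect == "group"], 0.05)
})

test_that("split-plot ANOVA agrees with an explicit sums-of-squares oracle", {
  # pre/post changes that average to zero within every group -> zero time
  # and interaction sums of squares against a nonzero within residual
  set.seed(32)
  pre <- rnorm(12)
  g <- rep(c("a", "b", "c"), 4)
  e <- rep(c(-1, 1), 6) * 0.5            # balanced within each group
  a0 <- mixedAnovaTimeGroup(pre, pre + e, g)
  expect_equal(a0$F[a0$effect == "time"], 0, tolerance = 1e-10)
  expect_equal(a0$F[a0$effect == "group:time"], 0, tolerance = 1e-10)

  # 8-subject two-group fixture against the hand decomposition
  pre2 <- c(1.2, 0.8, 1.5, 0.9, 2.1, 1.7, 2.4, 2.0)
  post2 <- c(1.3, 1.1, 1.4, 1.2, 3.0, 2.6, 3.1, 2.9)
  g2 <- rep(c("x", "y"), each = 4)
  a2 <- mixedAnovaTimeGroup(pre2, post2, g2)
  o <- oracleSplitPlot(pre2, post2, g2)
  expect_equal(a2$F[a2$effect == "group"], o$group$F, tolerance = 1e-8)
  expect_equal(a2$F[a2$effect == "time"], o$time$F, tolerance = 1e-8)
  expect_equal(a2$F[a2$effect == "group:time"], o$interaction$F,
               tolerance = 1e-8)
  expect_equal(a2$df2[a2$effect == "group"], o$group$df2)

  # three unbalanced groups against the same oracle
  set.seed(33)
  g3 <- rep(c("a", "b", "c"), c(4, 6, 5))
  pre3 <- rnorm(15); post3 <- pre3 + rnorm(15, 0.3)
  a3 <- mixedAnovaTimeGroup(pre3, post3, g3)
  o3 <- oracleSplitPlot(pre3, post3, g3)
  expect_equal(a3$F[a3$effect == "group:time"], o3$interaction$F,
               tolerance = 1e-8)
  expect_equal(a3$F[a3$effect == "group"], o3$group$F, tolerance = 1e-8)

  expect_message(mixedAnovaTimeGroup(c(pre3, NA), c(post3, 1),
                                     c(g3, "a")), "dropped")
})

test_that("post-hoc contrasts behave under null and planted patterns", {
  set.seed(34)
  g <- rep(c("ctrl", "nr", "r"), each = 20)
  pre <- rnorm(60)
  post <- pre + rnorm(60, 0, 0.3)
  ph0 <- posthocContrasts(pre, post, g)
  expect_equal(nrow(ph0), 9)
  # paired contrast on pre = post data -> p ~ 1
  phEq <- posthocContrasts(pre, pre + rnorm(60, 0, 1e-8), g)
  tw <- phEq[phEq$scope == "time-within-group", ]
  expect_true(all(tw$p > 0.01))
  # planted: only nr shifts at post
  post2 <- pre + ifelse(g == "nr", 0.8, 0) + rnorm(60, 0, 0.2)
  ph <- posthocContrasts(pre, post2, g)
  twp <- ph[ph$scope == "time-within-group", ]
  expect_lt(twp$p_adj[grepl("^nr", twp$contrast)], 0.05)
  expect_true(all(twp$p_adj[!grepl("^nr", twp$contrast)] > 0.05))
})

test_that("BH step-up matches the exhaustive rejection-set search", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_true(all(r$rejected))
  expect_true(bhFdr(0.04, 0.05)$rejected)
  expect_false(any(bhFdr(rep(1, 6))$rejected))
  # adjusted p monotone in raw-p rank
  set.seed(35)
  for (case in 1:50) {
    p <- runif(sample(1:10, 1))
    r <- bhFdr(p, q = 0.05)
    o <- order(p)
    expect_true(all(diff(r$p_adjusted[o]) >= -1e-15))
    expect_identical(r$rejected, oracleBH(p, 0.05))
  }
})

test_that("per-measure FDR uses the network-pair family, not the overall mean", {
  coh <- generateEdgeCohort(smallCohortConfig(
    20, c(control = 6, remitter = 10, nonremitter = 10),
    plantedEdgeCount = 8, effectDelta = 0.3, seed = 36))
  s <- summarizeSignature(coh, groundTruth(coh)$plantedEdges)
  res <- perMeasureStats(s, function(d) {
    b <- d[d$timepoint == "baseline" & d$outcome != "not-applicable", ]
    data.frame(p = t.test(value ~ outcome, data = b)$p.value)
  })
  expect_true(is.na(res$fdr_p[res$measure == "overall"]))
  sel <- res$measure != "overall"
  expect_identical(res$rejected[sel],
                   unname(oracleBH(res$p[sel], 0.05)))
})
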