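test_that("edge-wise t matches the textbook pooled formula", {
  set.seed(11)
  a <- matrix(rnorm(50), 5, 10)
  b <- matrix(rnorm(50, 0.5), 5, 10)
  st <- edgeTTest(a, b, tail = "two_sided")
  for (e in c(1, 4, 10))
    expect_equal(st$t[e], oraclePooledT(a[, e], b[, e]), tolerance = 1e-10)
  expect_equal(st$df, 8)
  # antisymmetry under group swap
  st2 <- edgeTTest(b, a, tail = "two_sided")
  expect_equal(st2$t, -st$t)
  expect_equal(st2$p, st$p)
  # identical data appended to both groups -> t = 0 everywhere
  st0 <- edgeTTest(a, a, tail = "two_sided")
  expect_equal(st0$t, rep(0, 10))
  # zero pooled variance -> t = 0, p = 1
  ac <- a; ac[, 3] <- 1
  bc <- b; bc[, 3] <- 1
  stc <- edgeTTest(ac, bc, tail = "greater")
  expect_equal(stc$t[3], 0)
  expect_equal(stc$p[3], 1)
})

test_that("covariate adjustment removes a planted confound", {
  set.seed(12)
  n <- 20
  conf <- c(rnorm(n, 2), rnorm(n, -2))   # group-aligned confound
  z <- matrix(rnorm(2 * n * 5), 2 * n, 5) + conf  # edges driven by confound
  raw <- edgeTTest(z[1:n, ], z[(n + 1):(2 * n), ], tail = "two_sided")
  adj <- edgeTTest(z[1:n, ], z[(n + 1):(2 * n), ],
                   covariates = cbind(conf), tail = "two_sided")
  expect_gt(min(abs(raw$t)), max(abs(adj$t)))
  expect_equal(adj$df, 2 * n - 3)
})

test_that("thresholding picks exactly the sub-threshold edges", {
  st <- structure(list(t = c(5, 1, 4, 0, 3), p = c(1e-5, 0.3, 1e-4, 0.9,
                                                   0.002),
                       df = 10, nA = 6, nB = 6, tail = "greater"),
                  class = "EdgeStatMap")
  expect_equal(thresholdEdges(st, 0.001), c(1L, 3L))
  expect_equal(thresholdEdges(st, 1), 1:5)
  expect_length(thresholdEdges(st, 1e-9), 0)
})

test_that("component extents agree with a brute-force union-find oracle", {
  ex <- edgeComponents(rbind(c(1, 2), c(2, 3), c(5, 6)), 6)
  expect_equal(vapply(ex, `[[`, 0, "size"), c(2, 1))
  expect_equal(ex[[1]]$nodes, 1:3)
  expect_length(edgeComponents(matrix(0L, 0, 2), 6), 0)
  cyc <- edgeComponents(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)), 4)
  expect_length(cyc, 1)
  expect_equal(cyc[[1]]$size, 4)
  set.seed(13)
  for (case in 1:200) {
    n <- sample(3:12, 1)
    all <- as.matrix(edgePairs(n))
    m <- sample.int(nrow(all), sample(0:min(12, nrow(all)), 1))
    pairs <- all[m, , drop = FALSE]
    got <- edgeComponents(pairs, n)
    want <- oracleComponents(pairs)
    expect_equal(vapply(got, `[[`, 0, "size"), lengths(want))
    for (k in seq_along(got))
      expect_setequal(edgeKey(got[[k]]$edges),
                      edgeKey(pairs[want[[k]], , drop = FALSE]))
  }
})

test_that("exhaustive NBS equals a hand-enumerated permutation null", {
  # 3 vs 3 subjects, 6 nodes: enumerate all 20 assignments by hand
  set.seed(14)
  n <- 6; nodes <- 6
  z <- matrix(rnorm(n * nrow(edgePairs(nodes)), 0, 1), n)
  z[1:3, 1:4] <- z[1:3, 1:4] + 3   # strong effect on a few edges
  labels <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
  cfg <- nbsConfig(componentFormingP = 0.05, exhaustive = TRUE,
                   tail = "greater")
  res <- nbs(z, labels, nodes, cfg)

  # independent oracle: plain t-tests + union-find per assignment
  pairs <- as.matrix(edgePairs(nodes))
  tcrit <- qt(1 - 0.05, 4)
  maxSize <- apply(combn(6, 3), 2, function(ix) {
    tv <- vapply(seq_len(ncol(z)), function(e)
      oraclePooledT(z[ix, e], z[-ix, e]), numeric(1))
    sup <- which(tv > tcrit)
    if (!length(sup)) return(0)
    max(lengths(oracleComponents(pairs[sup, , drop = FALSE])))
  })
  expect_setequal(nullDistribution(res), maxSize)
  obs <- nbsComponents(res)[[1]]$size
  expect_equal(nbsComponents(res)[[1]]$fwe_p, mean(maxSize >= obs))
})

test_that("NBS is reproducible per seed and p-values respect their bounds", {
  coh <- generateEdgeCohort(smallCohortConfig(
    20, c(control = 2, remitter = 10, nonremitter = 10),
    plantedEdgeCount = 6, effectDelta = 0.4, seed = 15))
  cfg <- nbsConfig(nPermutations = 99, seed = 8)
  a <- runNBS(coh, config = cfg)
  b <- runNBS(coh, config = cfg)
  expect_identical(nullDistribution(a), nullDistribution(b))
  expect_identical(nbsComponents(a), nbsComponents(b))
  for (cmp in nbsComponents(a)) {
    expect_gte(cmp$fwe_p, 1 / 100)
    expect_lte(cmp$fwe_p, 1)
  }
  expect_length(nullDistribution(a), 99)
  # monotone: larger observed size never has larger fwe_p
  sizes <- vapply(nbsComponents(a), `[[`, 0, "size")
  ps <- vapply(nbsComponents(a), `[[`, 0, "fwe_p")
  expect_true(all(diff(ps[order(sizes)]) <= 0 | diff(sort(sizes)) == 0))
})

test_that("node relabeling permutes components but not sizes or p-values", {
  set.seed(16)
  nodes <- 15
  nE <- nrow(edgePairs(nodes))
  z <- rbind(matrix(rnorm(8 * nE, 0.3), 8, nE),
             matrix(rnorm(8 * nE, 0), 8, nE))
  labels <- factor(rep(c("A", "B"), each = 8))
  cfg <- nbsConfig(componentFormingP = 0.01, nPermutations = 50, seed = 3)
  r1 <- nbs(z, labels, nodes, cfg)

  perm <- sample(nodes)
  pairs <- as.matrix(edgePairs(nodes))
  permPairs <- cbind(perm[pairs[, 1]], perm[pairs[, 2]])
  newIdx <- connbs:::edgeIndexOf(permPairs[, 1], permPairs[, 2], nodes)
  z2 <- z; z2[, newIdx] <- z
  r2 <- nbs(z2, labels, nodes, cfg)
  s1 <- sort(vapply(nbsComponents(r1), `[[`, 0, "size"))
  s2 <- sort(vapply(nbsComponents(r2), `[[`, 0, "size"))
  expect_equal(s1, s2)
  expect_equal(sort(vapply(nbsComponents(r1), `[[`, 0, "fwe_p")),
               sort(vapply(nbsComponents(r2), `[[`, 0, "fwe_p")))
})

test_that("permutations with no suprathreshold edge contribute size zero", {
  set.seed(17)
  z <- matrix(rnorm(10 * 45, 0, 1e-3), 10, 45)
  labels <- factor(rep(c("A", "B"), each = 5))
  res <- nbs(z, labels, 10, nbsConfig(componentFormingP = 1e-6,
                                      nPermutations = 30, seed = 5))
  expect_true(all(nullDistribution(res) == 0))
  expect_length(nbsComponents(res), 0)
})
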