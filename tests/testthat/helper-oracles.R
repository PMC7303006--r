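# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms (union-find, explicit sums of
# squares, exhaustive enumeration) and never call the code paths they check.

# union-find connected components over an edge list; returns a list of
# edge-row index sets, one per component, ordered by decreasing size then
# smallest incident node
oracleComponents <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  parent <- seq_len(max(pairs))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(pairs[, 1], find, integer(1))
  sets <- split(seq_len(nrow(pairs)), roots)
  minNode <- vapply(sets, function(ix) min(pairs[ix, , drop = FALSE]),
                    numeric(1))
  unname(sets[order(-lengths(sets), minNode)])
}

# brute-force Type-III F for the term named `drop` in a linear model:
# compare the full sum-to-zero-coded design against the design without that
# term's columns
oracleTypeIIIF <- function(values, factors, drop) {
  for (f in names(factors)) factors[[f]] <- factor(factors[[f]])
  d <- data.frame(value = values, factors)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  terms <- c(names(factors),
             if (length(factors) == 2) paste(names(factors), collapse = ":"))
  form <- stats::as.formula(paste("value ~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(form, d)
  asg <- attr(X, "assign")
  labs <- c("(Intercept)", terms)
  keep <- labs[asg + 1] != drop
  rssOf <- function(M) sum(stats::lsfit(M, values, intercept = FALSE)$residuals^2)
  rssFull <- rssOf(X)
  rssRed <- rssOf(X[, keep, drop = FALSE])
  df1 <- sum(!keep)
  df2 <- nrow(X) - ncol(X)
  F <- ((rssRed - rssFull) / df1) / (rssFull / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# explicit split-plot sums of squares for two timepoints (balanced in time):
# between-subject stratum tests group against subjects-within-group,
# within stratum tests time and group:time against the within residual
oracleSplitPlot <- function(pre, post, group) {
  group <- factor(group)
  n <- length(pre)
  y <- c(pre, post)
  subjMean <- (pre + post) / 2
  grand <- mean(y)
  grpMeans <- tapply(y, rep(group, 2), mean)
  ssGroup <- 2 * sum(tapply(subjMean, group, length) *
                       (tapply(subjMean, group, mean) - grand)^2)
  ssSubj <- 2 * sum((subjMean - grpMeans[group])^2)
  timeMeans <- c(mean(pre), mean(post))
  ssTime <- n * sum((timeMeans - grand)^2)
  cellMeans <- rbind(tapply(pre, group, mean), tapply(post, group, mean))
  ngr <- as.vector(table(group))
  ssCells <- sum(rep(ngr, each = 2) *
                   (as.vector(cellMeans) - grand)^2)
  ssInter <- ssCells - ssGroup - ssTime
  ssTot <- sum((y - grand)^2)
  ssErr <- ssTot - ssGroup - ssSubj - ssTime - ssInter
  g <- nlevels(group)
  dfG <- g - 1; dfS <- n - g; dfT <- 1; dfI <- g - 1; dfE <- n - g
  list(group = list(F = (ssGroup / dfG) / (ssSubj / dfS), df1 = dfG,
                    df2 = dfS),
       time = list(F = (ssTime / dfT) / (ssErr / dfE), df1 = dfT, df2 = dfE),
       interaction = list(F = (ssInter / dfI) / (ssErr / dfE), df1 = dfI,
                          df2 = dfE))
}

# exhaustive BH step-up: find the largest k with p_(k) <= k*q/m and reject
# everything at or below that order statistic
oracleBH <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# pooled-variance two-sample t computed the long way
oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

edgeKey <- function(pairs) paste(pmin(pairs[, 1], pairs[, 2]),
                                 pmax(pairs[, 1], pairs[, 2]))

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small shared fixtures
smallParc <- function(n) makeParcellation(n)

smallCohortConfig <- function(n = 30L, perGroup = c(control = 6, remitter = 8,
                                                    nonremitter = 8),
                              ...) {
  cohortSimConfig(nNodes = n, nPerGroup = perGroup,
                  parcellation = makeParcellation(n), ...)
}
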