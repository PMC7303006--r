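#' Configuration for the synthetic edge-level cohort generator
#'
#' Defaults emulate the design of a three-arm antidepressant outcome trial
#' with imaging at baseline and week 8: three groups (healthy control,
#' remitter, non-remitter; 62/58/105 subjects), a 333-node parcellation with
#' 13 intrinsic-network labels, Fisher-z edges with means and SDs on the scale
#' of published connectivity tables (means of order -0.3..0.8, SD around
#' 0.16-0.32), a planted connected differential subnetwork on which remitters
#' exceed non-remitters at both timepoints (a trait-like elevation), and a
#' non-remitter-only connectivity increase at the second timepoint on those
#' same edges.
#'
#' The generative model per subject s (group g) and timepoint t is
#' `z_e = mu[g,t,e] + b_s + eps_{e,t}` with `b_s ~ N(0, subjectSD)` shared
#' across edges and timepoints (inducing inter-edge correlation) and edge
#' noise `eps` with SD `edgeSD` and retest correlation `retestCor` between
#' timepoints.
#'
#' @param nNodes node count (>= 4).
#' @param nPerGroup named counts for `control`, `remitter`, `nonremitter`.
#' @param parcellation a [Parcellation-class] with `nNodes` nodes; default
#'   [makeParcellation()] template at this size.
#' @param plantedEdgeCount edges in the planted connected subnetwork.
#' @param effectDelta Fisher-z added to remitter means on planted edges (both
#'   timepoints).
#' @param edgeMeanBase baseline Fisher-z mean of every edge.
#' @param edgeSD per-edge noise SD (Fisher-z).
#' @param subjectSD SD of the per-subject scalar offset.
#' @param postShiftNonremitter Fisher-z added to non-remitter means on planted
#'   edges at the second timepoint only.
#' @param retestCor correlation of edge noise across the two timepoints.
#' @param seed RNG seed.
#' @return a list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nNodes = 333L,
                            nPerGroup = c(control = 62L, remitter = 58L,
                                          nonremitter = 105L),
                            parcellation = NULL,
                            plantedEdgeCount = 86L,
                            effectDelta = 0.15,
                            edgeMeanBase = 0.2,
                            edgeSD = 0.25,
                            subjectSD = 0.05,
                            postShiftNonremitter = 0.05,
                            retestCor = 0.7,
                            seed = 1L) {
  nNodes <- as.integer(nNodes)
  if (nNodes < 4L) stop("nNodes must be >= 4")
  need <- c("control", "remitter", "nonremitter")
  if (!all(need %in% names(nPerGroup)))
    stop("nPerGroup needs named counts for control, remitter, nonremitter")
  nPerGroup <- vapply(nPerGroup[need], as.integer, integer(1))
  if (any(nPerGroup < 2L)) stop("each group needs >= 2 subjects")
  maxEdges <- nNodes * (nNodes - 1) / 2
  if (plantedEdgeCount < 1L || plantedEdgeCount > maxEdges)
    stop("plantedEdgeCount infeasible for ", nNodes, " nodes")
  if (edgeSD <= 0) stop("edgeSD must be positive")
  if (retestCor < 0 || retestCor > 1) stop("retestCor must be in [0, 1]")
  if (is.null(parcellation)) parcellation <- makeParcellation(nNodes)
  if (nNodes(parcellation) != nNodes)
    stop("parcellation size does not match nNodes")
  structure(list(nNodes = nNodes, nPerGroup = nPerGroup,
                 parcellation = parcellation,
                 plantedEdgeCount = as.integer(plantedEdgeCount),
                 effectDelta = effectDelta, edgeMeanBase = edgeMeanBase,
                 edgeSD = edgeSD, subjectSD = subjectSD,
                 postShiftNonremitter = postShiftNonremitter,
                 retestCor = retestCor, seed = as.integer(seed)),
            class = "CohortSimConfig")
}

#' Plant a connected differential subnetwork
#'
#' Draws a ground-truth edge set that is connected by construction: a random
#' tree is grown over a node subset, then augmented with random extra edges
#' among those nodes until the requested edge count is reached. The node
#' subset size is chosen so the planted graph is sparse but connected
#' (roughly 0.7 nodes per edge, mimicking a signature of 86 edges spanning 59
#' nodes).
#'
#' @param nNodes nodes available.
#' @param plantedEdgeCount number of edges (>= 1).
#' @param seed RNG seed; the same seed always returns the same edge set.
#' @return integer matrix with columns `node_i`, `node_j` (node_i < node_j).
#' @examples
#' plantComponent(50, 20, seed = 7)
#' @export
plantComponent <- function(nNodes, plantedEdgeCount, seed = 1L) {
  nNodes <- as.integer(nNodes)
  m <- as.integer(plantedEdgeCount)
  if (m < 1L) stop("plantedEdgeCount must be >= 1")
  if (m > nNodes * (nNodes - 1) / 2)
    stop("plantedEdgeCount ", m, " exceeds the ", nNodes * (nNodes - 1) / 2,
         " unordered pairs available on ", nNodes, " nodes")
  ## node subset: enough nodes that density stays moderate, few enough that a
  ## spanning tree (k-1 edges) fits inside m
  k <- max(2L, min(nNodes, m + 1L, as.integer(floor(0.7 * m)) + 1L))
  while (k * (k - 1) / 2 < m) k <- k + 1L  # guarantee feasibility
  withSeed(seed, {
    nodes <- sort(sample.int(nNodes, k))
    ## random tree growth over the subset
    ord <- sample(nodes)
    edges <- matrix(0L, nrow = m, ncol = 2)
    nTree <- k - 1L
    if (nTree > m) { ord <- ord[seq_len(m + 1L)]; nTree <- m }
    for (t in seq_len(nTree)) {
      a <- ord[t + 1L]
      b <- ord[sample.int(t, 1L)]
      edges[t, ] <- c(min(a, b), max(a, b))
    }
    if (m > nTree) {
      all <- t(utils::combn(sort(ord), 2L))
      key <- all[, 1] * (nNodes + 1L) + all[, 2]
      used <- edges[seq_len(nTree), 1] * (nNodes + 1L) +
        edges[seq_len(nTree), 2]
      avail <- which(!(key %in% used))
      pick <- sample(avail, m - nTree)
      edges[(nTree + 1L):m, ] <- all[pick, , drop = FALSE]
    }
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    colnames(edges) <- c("node_i", "node_j")
    edges
  })
}

#' Generate a synthetic connectome cohort with planted effects
#'
#' Samples per-subject, per-timepoint Fisher-z edge vectors under the model
#' described in [cohortSimConfig()] and returns them as a
#' [ConnectomeCohort-class] whose `metadata()$groundTruth` records the planted
#' edge set, the per-group/timepoint mean structure, and the seed.
#'
#' @param config a [cohortSimConfig()].
#' @return a `ConnectomeCohort` (edges x scans; two columns per subject).
#' @examples
#' cfg <- cohortSimConfig(nNodes = 20, nPerGroup = c(control = 4,
#'   remitter = 4, nonremitter = 4), plantedEdgeCount = 8, seed = 3)
#' coh <- generateEdgeCohort(cfg)
#' dim(coh)
#' @export
generateEdgeCohort <- function(config) {
  stopifnot(inherits(config, "CohortSimConfig"))
  n <- config$nNodes
  pairs <- edgePairs(n)
  nE <- nrow(pairs)
  planted <- plantComponent(n, config$plantedEdgeCount, config$seed)
  plantedIdx <- edgeIndexOf(planted[, 1], planted[, 2], n)

  ## group x timepoint mean deltas on planted edges (added to edgeMeanBase)
  deltas <- list(
    control     = c(baseline = 0, week8 = 0),
    remitter    = c(baseline = config$effectDelta, week8 = config$effectDelta),
    nonremitter = c(baseline = 0, week8 = config$postShiftNonremitter))

  groups <- rep(names(config$nPerGroup), times = config$nPerGroup)
  nSubj <- length(groups)
  ids <- sprintf("S%03d", seq_len(nSubj))
  rho <- config$retestCor

  z <- withSeed(config$seed, {
    out <- matrix(0, nrow = nE, ncol = 2L * nSubj)
    for (s in seq_len(nSubj)) {
      b <- stats::rnorm(1, 0, config$subjectSD)
      e1 <- stats::rnorm(nE, 0, config$edgeSD)
      e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(nE, 0, config$edgeSD)
      mu1 <- rep(config$edgeMeanBase, nE)
      mu2 <- mu1
      d <- deltas[[groups[s]]]
      mu1[plantedIdx] <- mu1[plantedIdx] + d[["baseline"]]
      mu2[plantedIdx] <- mu2[plantedIdx] + d[["week8"]]
      out[, 2L * s - 1L] <- mu1 + b + e1
      out[, 2L * s] <- mu2 + b + e2
    }
    out
  })

  colData <- S4Vectors::DataFrame(
    subject_id = rep(ids, each = 2L),
    group = ifelse(rep(groups, each = 2L) == "control", "control", "MDD"),
    outcome = rep(ifelse(groups == "control", "not-applicable", groups),
                  each = 2L),
    timepoint = rep(c("baseline", "week8"), times = nSubj))
  colnames(z) <- paste(colData$subject_id, colData$timepoint, sep = ".")

  gt <- list(plantedEdges = planted, plantedIdx = plantedIdx,
             edgeMeanBase = config$edgeMeanBase, deltas = deltas,
             seed = config$seed)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = z), rowData = S4Vectors::DataFrame(pairs),
    colData = colData,
    metadata = list(parcellation = config$parcellation, groundTruth = gt,
                    simConfig = config[setdiff(names(config), "parcellation")]))
  new("ConnectomeCohort", se)
}

#' Extract a subjects-by-edges slice of a cohort
#'
#' Pulls one timepoint (and optionally a subset of outcome groups) out of a
#' [ConnectomeCohort-class] in the subjects x edges layout the statistical
#' engines consume.
#'
#' @param cohort a `ConnectomeCohort`.
#' @param timepoint scan label to keep.
#' @param outcomes optional character vector of `outcome` levels to keep.
#' @return list with `z` (subjects x edges matrix), `labels` (factor of
#'   outcomes, levels in the order given), `subjects` (ids).
#' @export
cohortSlice <- function(cohort, timepoint = "baseline", outcomes = NULL) {
  cd <- SummarizedExperiment::colData(cohort)
  keep <- cd$timepoint == timepoint
  if (!is.null(outcomes)) keep <- keep & cd$outcome %in% outcomes
  if (!any(keep)) stop("no scans match timepoint/outcome selection")
  z <- t(SummarizedExperiment::assay(cohort, "z")[, keep, drop = FALSE])
  labs <- if (is.null(outcomes)) factor(cd$outcome[keep])
          else factor(cd$outcome[keep], levels = outcomes)
  list(z = z, labels = labs, subjects = cd$subject_id[keep])
}

#' Materialize one scan of a cohort as a Connectome
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param subject subject id.
#' @param timepoint scan label.
#' @return a [Connectome-class].
#' @export
cohortConnectome <- function(cohort, subject, timepoint = "baseline") {
  cd <- SummarizedExperiment::colData(cohort)
  k <- which(cd$subject_id == subject & cd$timepoint == timepoint)
  if (length(k) != 1) stop("scan not found: ", subject, "/", timepoint)
  z <- edgesToMatrix(SummarizedExperiment::assay(cohort, "z")[, k],
                     nNodes(cohort))
  Connectome(z, parcellation(cohort), subject, timepoint)
}

# ---------------------------------------------------------------------------
# clinical table
# ---------------------------------------------------------------------------

#' Configuration for the synthetic clinical table
#'
#' Defaults reproduce the demographic and clinical profile of the emulated
#' trial: depression severity (17-item Hamilton) around 21.7 +/- 4.0 at
#' baseline (entry criterion >= 16), week-8 scores of 4.9 +/- 1.7 for
#' remitters (remission rule: week-8 score <= 7) and 13.3 +/- 3.9 for
#' non-remitters, group-specific age distributions, 51% female, three drug
#' arms (escitalopram/sertraline/venlafaxine-XR) allocated 1:1:1 by largest
#' remainder, and treatment-naivety rates of 64%/33% for
#' remitters/non-remitters.
#'
#' @param hrsdBaseline `c(mean, sd)` of baseline severity (truncated at the
#'   entry criterion of 16).
#' @param hrsdWeek8 named list of `c(mean, sd)` per outcome; remitter scores
#'   are truncated to 0..7 and non-remitter scores to 8..52 so outcome labels
#'   always satisfy the remission rule.
#' @param age named list of `c(mean, sd)` per group, truncated to 18..65.
#' @param sexFemale proportion female.
#' @param drugArms arm labels.
#' @param allocation relative allocation weights over arms.
#' @param naiveRate named proportions of treatment-naive subjects per outcome.
#' @param seed RNG seed.
#' @return list of class `ClinicalSimConfig`.
#' @export
clinicalSimConfig <- function(hrsdBaseline = c(21.7, 4.0),
                              hrsdWeek8 = list(remitter = c(4.9, 1.7),
                                               nonremitter = c(13.3, 3.9)),
                              age = list(control = c(31.4, 13.0),
                                         remitter = c(29.7, 8.7),
                                         nonremitter = c(36.6, 12.7)),
                              sexFemale = 0.51,
                              drugArms = c("E", "S", "V"),
                              allocation = c(1, 1, 1),
                              naiveRate = c(remitter = 0.64,
                                            nonremitter = 0.33),
                              seed = 1L) {
  structure(list(hrsdBaseline = hrsdBaseline, hrsdWeek8 = hrsdWeek8,
                 age = age, sexFemale = sexFemale, drugArms = drugArms,
                 allocation = allocation, naiveRate = naiveRate,
                 seed = as.integer(seed)),
            class = "ClinicalSimConfig")
}

#' Generate the subject metadata table for a cohort
#'
#' One row per subject with age, sex, group, outcome, drug arm, baseline and
#' week-8 severity, and treatment naivety. Week-8 scores are sampled within
#' the outcome-consistent range, so [labelRemission()] applied to the table
#' always reproduces the generator's outcome labels.
#'
#' @param cohort a [ConnectomeCohort-class] (or a data.frame with
#'   `subject_id` and `outcome` columns, one row per subject).
#' @param config a [clinicalSimConfig()].
#' @return data.frame, one row per subject.
#' @export
generateClinicalTable <- function(cohort, config = clinicalSimConfig()) {
  stopifnot(inherits(config, "ClinicalSimConfig"))
  if (is(cohort, "ConnectomeCohort")) {
    cd <- as.data.frame(SummarizedExperiment::colData(cohort))
    subj <- unique(cd[, c("subject_id", "outcome")])
  } else {
    subj <- unique(cohort[, c("subject_id", "outcome")])
  }
  n <- nrow(subj)
  grp <- ifelse(subj$outcome == "not-applicable", "control", subj$outcome)
  withSeed(config$seed, {
    agePar <- config$age
    age <- numeric(n)
    for (g in names(agePar)) {
      k <- grp == g
      age[k] <- round(rtruncnorm(sum(k), agePar[[g]][1], agePar[[g]][2],
                                 18, 65), 1)
    }
    sex <- ifelse(stats::runif(n) < config$sexFemale, "F", "M")
    hb <- rep(NA_real_, n)
    mdd <- grp != "control"
    hb[mdd] <- round(rtruncnorm(sum(mdd), config$hrsdBaseline[1],
                                config$hrsdBaseline[2], 16, 52))
    hb[!mdd] <- round(rtruncnorm(sum(!mdd), 3, 2, 0, 7))
    h8 <- rep(NA_real_, n)
    for (g in names(config$hrsdWeek8)) {
      k <- grp == g
      lim <- if (g == "remitter") c(0, 7) else c(8, 52)
      h8[k] <- round(rtruncnorm(sum(k), config$hrsdWeek8[[g]][1],
                                config$hrsdWeek8[[g]][2], lim[1], lim[2]))
    }
    arm <- rep(NA_character_, n)
    for (g in c("remitter", "nonremitter")) {
      k <- which(grp == g)
      counts <- allocateExact(length(k), config$allocation)
      arm[k] <- sample(rep(config$drugArms, times = counts))
    }
    naive <- rep(NA, n)
    for (g in names(config$naiveRate))
      naive[grp == g] <- stats::runif(sum(grp == g)) < config$naiveRate[[g]]
    data.frame(subject_id = subj$subject_id,
               group = ifelse(mdd, "MDD", "control"),
               outcome = subj$outcome, drug_arm = arm,
               age = age, sex = sex,
               hrsd17_baseline = hb, hrsd17_week8 = h8,
               treatment_naive = naive, stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to plain-text files
#'
#' External representation of a cohort: one N x N matrix file per
#' subject-timepoint scan (tab-delimited), a parcellation table, a subject
#' manifest CSV, and the ground-truth planted edge list.
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeParcellation(parcellation(cohort), file.path(dir, "parcellation.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  n <- nNodes(cohort)
  files <- character(nrow(cd))
  for (k in seq_len(nrow(cd))) {
    files[k] <- file.path(dir, sprintf("%s_%s.tsv", cd$subject_id[k],
                                       cd$timepoint[k]))
    m <- edgesToMatrix(SummarizedExperiment::assay(cohort, "z")[, k], n)
    utils::write.table(m, files[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  manifest <- cbind(cd, file = files)
  utils::write.csv(manifest, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    ge <- as.data.frame(gt$plantedEdges)
    ge$delta <- gt$deltas$remitter[["baseline"]]
    utils::write.table(ge, file.path(dir, "ground_truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(manifest)
}
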