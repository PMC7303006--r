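#' End-to-end pipeline configuration
#'
#' Bundles the stage configurations, output paths and the single global seed
#' from which every stage seed is derived (simulate: seed, clinical:
#' seed + 1, NBS permutations: seed + 2, cross-validation: seed + 3), so one
#' seed reproduces the whole run. The default problem size is a desk-scale
#' cohort (60 nodes, 20 subjects per group); pass a full-size
#' [cohortSimConfig()] for the 333-node design.
#'
#' @param cohort a [cohortSimConfig()] (its `seed` is overridden by the
#'   global seed).
#' @param clinical a [clinicalSimConfig()].
#' @param nbs an [nbsConfig()].
#' @param q FDR level for the per-measure longitudinal analysis.
#' @param cvPerm permutations for the classifier-improvement test.
#' @param seed global seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(cohort = cohortSimConfig(
                             nNodes = 60,
                             nPerGroup = c(control = 20, remitter = 20,
                                           nonremitter = 20),
                             plantedEdgeCount = 30, effectDelta = 0.25,
                             postShiftNonremitter = 0.12),
                           clinical = clinicalSimConfig(),
                           nbs = nbsConfig(nPermutations = 500),
                           q = 0.05, cvPerm = 200L, seed = 1L) {
  structure(list(cohort = cohort, clinical = clinical, nbs = nbs, q = q,
                 cvPerm = as.integer(cvPerm), seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in order: `simulate` (edge-level cohort + clinical table),
#' `nbs` (remitter vs non-remitter at baseline), `summarize` (per-subject
#' signature means over the significant component edges), `stats`
#' (outcome-by-drug ANOVA, baseline MDD-vs-control ANOVA, per-measure mixed
#' time-by-group ANOVA with BH-FDR and post-hoc contrasts, cross-validated
#' classifier comparison), `report`. Later stages require earlier ones: a
#' missing prerequisite aborts with an error naming the stage to run first.
#' All artifacts are plain-text files under `outDir`, plus a JSON manifest
#' sufficient to re-run the pipeline bit-identically.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @param stages subset of the stage names above (order enforced).
#' @param state results of a previous partial run to resume from.
#' @return invisibly, a list with per-stage results and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run"),
                        stages = c("simulate", "nbs", "summarize", "stats",
                                   "report"),
                        state = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  all <- c("simulate", "nbs", "summarize", "stats", "report")
  stages <- match.arg(stages, all, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- if (is.null(state)) list() else state
  need <- function(what, stage, prereq) {
    if (is.null(res[[what]]))
      stop("stage '", stage, "' needs output of stage '", prereq,
           "'; run it first")
  }

  if ("simulate" %in% stages) {
    cfgS <- config$cohort; cfgS$seed <- config$seed
    class(cfgS) <- "CohortSimConfig"
    res$cohort <- generateEdgeCohort(cfgS)
    cfgC <- config$clinical; cfgC$seed <- config$seed + 1L
    class(cfgC) <- "ClinicalSimConfig"
    res$clinical <- generateClinicalTable(res$cohort, cfgC)
    utils::write.csv(res$clinical, file.path(outDir, "subjects.csv"),
                     row.names = FALSE)
    writeParcellation(parcellation(res$cohort),
                      file.path(outDir, "parcellation.tsv"))
    gt <- groundTruth(res$cohort)
    utils::write.table(as.data.frame(gt$plantedEdges),
                       file.path(outDir, "ground_truth_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("nbs" %in% stages) {
    need("cohort", "nbs", "simulate")
    cfgN <- config$nbs; cfgN$seed <- config$seed + 2L
    class(cfgN) <- "NBSConfig"
    res$nbs <- runNBS(res$cohort, config = cfgN)
    writeLines(format(nullDistribution(res$nbs)),
               file.path(outDir, "nbs_null_distribution.txt"))
    sig <- significantComponents(res$nbs)
    res$signatureEdges <- if (length(sig))
      do.call(rbind, lapply(sig, `[[`, "edges")) else NULL
    comps <- nbsComponents(res$nbs)
    if (length(comps)) {
      tab <- do.call(rbind, lapply(seq_along(comps), function(i)
        data.frame(component = i, comps[[i]]$edges,
                   size = comps[[i]]$size, fwe_p = comps[[i]]$fwe_p)))
      utils::write.table(tab, file.path(outDir, "nbs_components.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("summarize" %in% stages) {
    need("nbs", "summarize", "nbs")
    res$summarized <- TRUE
    if (is.null(res$signatureEdges)) {
      res$summaries <- NULL
    } else {
      res$summaries <- summarizeSignature(res$cohort, res$signatureEdges)
      utils::write.csv(res$summaries,
                       file.path(outDir, "signature_summaries.csv"),
                       row.names = FALSE)
      sl <- cohortSlice(res$cohort, "baseline",
                        c("remitter", "nonremitter"))
      idx <- edgeIndexOf(res$signatureEdges[, 1], res$signatureEdges[, 2],
                         nNodes(res$cohort))
      gs <- list(remitter = sl$z[sl$labels == "remitter", idx, drop = FALSE],
                 nonremitter = sl$z[sl$labels == "nonremitter", idx,
                                    drop = FALSE])
      res$edgeReport <- labelEdges(res$signatureEdges,
                                   parcellation(res$cohort), gs)
      utils::write.table(res$edgeReport,
                         file.path(outDir, "signature_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("stats" %in% stages) {
    if (!isTRUE(res$summarized))
      stop("stage 'stats' needs output of stage 'summarize'; run it first")
    if (!is.null(res$summaries)) {
      s <- res$summaries
      cl <- res$clinical
      ovBase <- s[s$measure == "overall" & s$timepoint == "baseline", ]
      m <- match(ovBase$subject_id, cl$subject_id)
      mdd <- ovBase$outcome != "not-applicable"
      res$stats <- list(
        outcome_by_drug = anovaOutcomeByDrug(ovBase$value[mdd],
                                             cl[m[mdd], ]),
        mdd_vs_control = anovaGroup(ovBase$value, ovBase$group,
                                    covariates = data.frame(
                                      age = cl$age[m])),
        time_by_group = perMeasureStats(s, function(d) {
          wide <- merge(d[d$timepoint == "baseline",
                          c("subject_id", "outcome", "value")],
                        d[d$timepoint == "week8",
                          c("subject_id", "value")],
                        by = "subject_id", suffixes = c("_pre", "_post"))
          a <- mixedAnovaTimeGroup(wide$value_pre, wide$value_post,
                                   wide$outcome)
          a[a$effect == "group:time", , drop = FALSE]
        }, q = config$q))
      ovW <- merge(ovBase[, c("subject_id", "outcome", "value")],
                   s[s$measure == "overall" & s$timepoint == "week8",
                     c("subject_id", "value")],
                   by = "subject_id", suffixes = c("_pre", "_post"))
      res$stats$posthoc <- posthocContrasts(
        ovW$value_pre, ovW$value_post, ovW$outcome,
        covariate = cl$age[match(ovW$subject_id, cl$subject_id)])
      mddRows <- ovBase[mdd, ]
      mc <- match(mddRows$subject_id, cl$subject_id)
      res$stats$cv <- cvModelComparison(
        baseFeatures = data.frame(age = cl$age[mc],
                                  sex = as.integer(cl$sex[mc] == "F"),
                                  hrsd_baseline = cl$hrsd17_baseline[mc]),
        addedFeature = mddRows$value,
        labels = factor(mddRows$outcome,
                        levels = c("remitter", "nonremitter")),
        nPerm = config$cvPerm, seed = config$seed + 3L)
      for (nm in c("outcome_by_drug", "mdd_vs_control", "time_by_group"))
        utils::write.table(res$stats[[nm]],
                           file.path(outDir, paste0("stats_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("report" %in% stages) {
    need("nbs", "report", "nbs")
    res$report <- renderReport(res)
    writeLines(res$report, file.path(outDir, "report.md"))
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("connbs")),
    seed = config$seed,
    stage_seeds = list(simulate = config$seed, clinical = config$seed + 1L,
                       nbs = config$seed + 2L, cv = config$seed + 3L),
    config = list(
      cohort = unclass(config$cohort[setdiff(names(config$cohort),
                                             "parcellation")]),
      clinical = unclass(config$clinical), nbs = unclass(config$nbs),
      q = config$q, cvPerm = config$cvPerm),
    assumptions = c(
      "censoring thresholds (FD 0.3 mm, DVARS 1.5% PSC) are configurable defaults",
      "24-parameter Volterra motion expansion",
      "concatenated-run correlation; per-run averaging available",
      "one-tailed component-forming threshold per contrast"),
    stages_run = stages,
    outputs = list.files(outDir))
  jsonlite::write_json(res$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Build a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping with optional `cohort`, `clinical`, `nbs`, `q`,
#' `cvPerm` and `seed` entries whose fields override the corresponding
#' [pipelineConfig()] defaults (field names as in the respective
#' constructors).
#'
#' @param path YAML file path.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  cargs <- y$cohort %||% list()
  if (!is.null(cargs$nPerGroup)) cargs$nPerGroup <- unlist(cargs$nPerGroup)
  cohort <- do.call(cohortSimConfig, cargs)
  clinical <- do.call(clinicalSimConfig, y$clinical %||% list())
  nbsCfg <- do.call(nbsConfig, y$nbs %||% list())
  pipelineConfig(cohort = cohort, clinical = clinical, nbs = nbsCfg,
                 q = y$q %||% 0.05, cvPerm = y$cvPerm %||% 200L,
                 seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a human-readable pipeline report
#'
#' Markdown summary: significant components with their network-pair
#' composition, per-group signature means (bar-plot data), ANOVA tables and
#' the classifier comparison. Regenerating the report from the same results
#' yields identical text.
#'
#' @param res pipeline results list from [runPipeline()].
#' @return character vector of markdown lines.
#' @export
renderReport <- function(res) {
  out <- c("# Connectome-wide analysis report", "")
  sig <- significantComponents(res$nbs)
  if (!length(sig)) {
    out <- c(out, "No significant component was identified at the",
             sprintf("component-wise corrected alpha = %g.",
                     res$nbs@config$alpha))
    return(out)
  }
  out <- c(out, sprintf("## Significant components (%d)", length(sig)), "")
  for (i in seq_along(sig))
    out <- c(out, sprintf("- component %d: %d edges across %d nodes, FWE p = %.4g",
                          i, sig[[i]]$size, length(sig[[i]]$nodes),
                          sig[[i]]$fwe_p))
  if (!is.null(res$edgeReport)) {
    pairs <- unique(res$edgeReport[, c("network_pair", "n_in_pair")])
    out <- c(out, "", "## Signature composition by network pair", "")
    out <- c(out, sprintf("- %s (%d connections)", pairs$network_pair,
                          pairs$n_in_pair))
  }
  if (!is.null(res$summaries)) {
    ov <- res$summaries[res$summaries$measure == "overall", ]
    agg <- stats::aggregate(value ~ outcome + timepoint, ov, mean)
    sdv <- stats::aggregate(value ~ outcome + timepoint, ov, stats::sd)
    out <- c(out, "", "## Mean signature connectivity by group and timepoint",
             "", sprintf("- %s / %s: %.3f +/- %.3f", agg$outcome,
                         agg$timepoint, agg$value, sdv$value))
  }
  if (!is.null(res$stats)) {
    fmtA <- function(a) sprintf("- %s: F(%d, %d) = %.2f, p = %.4g",
                                a$effect, a$df1, a$df2, a$F, a$p)
    out <- c(out, "", "## Outcome x drug ANOVA (baseline signature mean)", "",
             fmtA(res$stats$outcome_by_drug),
             "", "## MDD vs control (age-controlled, baseline)", "",
             fmtA(res$stats$mdd_vs_control),
             "", "## Time x group interaction per measure (BH-FDR)", "")
    tg <- res$stats$time_by_group
    out <- c(out, sprintf("- %s: F = %.2f, p = %.4g%s", tg$measure, tg$F,
                          tg$p,
                          ifelse(!is.na(tg$rejected) & tg$rejected,
                                 " (FDR significant)", "")))
    cv <- res$stats$cv
    out <- c(out, "", "## Cross-validated outcome classification", "",
             sprintf("- base model: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%",
                     100 * cv$base[["acc"]], 100 * cv$base[["sens"]],
                     100 * cv$base[["spec"]]),
             sprintf("- with signature: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%",
                     100 * cv$augmented[["acc"]], 100 * cv$augmented[["sens"]],
                     100 * cv$augmented[["spec"]]),
             sprintf("- improvement p = %.4g", cv$improvement_p))
  }
  out
}
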