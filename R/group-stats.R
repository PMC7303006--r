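#' Classify treatment outcome from week-8 severity
#'
#' Remission rule: a week-8 17-item Hamilton depression score of 7 or less.
#'
#' @param hrsd17Week8 numeric vector of week-8 scores (NA allowed).
#' @return character vector: "remitter", "nonremitter", or (with a warning)
#'   "not-applicable" for missing scores.
#' @examples
#' labelRemission(c(7, 8))
#' @export
labelRemission <- function(hrsd17Week8) {
  out <- ifelse(hrsd17Week8 <= 7, "remitter", "nonremitter")
  if (anyNA(hrsd17Week8)) {
    warning(sum(is.na(hrsd17Week8)), " missing week-8 score(s) labeled ",
            "not-applicable")
    out[is.na(hrsd17Week8)] <- "not-applicable"
  }
  out
}

## shared shape of every ANOVA result
.anovaRow <- function(effect, F, df1, df2, p)
  data.frame(effect = effect, F = F, df1 = df1, df2 = df2, p = p,
             row.names = NULL)

#' Two-way outcome-by-drug ANOVA
#'
#' Between-subjects ANOVA of a per-subject signature measure on treatment
#' outcome (remitter/non-remitter) crossed with antidepressant type, testing
#' in particular the outcome x drug interaction. Unbalanced cells are handled
#' with marginal (Type-III) sums of squares under sum-to-zero coding.
#'
#' @param values numeric per-subject measure.
#' @param records data.frame with `outcome` and `drug_arm` columns aligned to
#'   `values` (MDD subjects only).
#' @return data.frame with effect, F, df1, df2, p rows.
#' @export
anovaOutcomeByDrug <- function(values, records) {
  d <- data.frame(value = values,
                  outcome = factor(records$outcome),
                  drug = factor(records$drug_arm))
  if (nlevels(d$outcome) < 2 || nlevels(d$drug) < 2)
    stop("both factors need >= 2 levels")
  cells <- table(d$outcome, d$drug)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  fit <- stats::lm(value ~ outcome * drug, data = d,
                   contrasts = list(outcome = "contr.sum",
                                    drug = "contr.sum"))
  a <- car::Anova(fit, type = 3)
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  .anovaRow(rownames(a)[keep], a$`F value`[keep], a$Df[keep],
            a$Df[rownames(a) == "Residuals"], a$`Pr(>F)`[keep])
}

#' One-way group ANOVA (optionally covariate-adjusted)
#'
#' Between-subjects comparison of a signature measure across groups
#' (e.g. MDD vs control), with optional ANCOVA adjustment for covariates
#' such as age (Type-III sums of squares when covariates are present).
#'
#' @param values numeric per-subject measure.
#' @param group factor-like group labels.
#' @param covariates optional data.frame/matrix of numeric covariates.
#' @return data.frame with effect, F, df1, df2, p (the `group` row is the
#'   adjusted group effect).
#' @export
anovaGroup <- function(values, group, covariates = NULL) {
  d <- data.frame(value = values, group = factor(group))
  if (nlevels(d$group) < 2) stop("need >= 2 groups")
  if (is.null(covariates)) {
    fit <- stats::lm(value ~ group, data = d)
    a <- stats::anova(fit)
    return(.anovaRow("group", a$`F value`[1], a$Df[1], a$Df[2],
                     a$`Pr(>F)`[1]))
  }
  covariates <- as.data.frame(covariates)
  d <- cbind(d, covariates)
  form <- stats::as.formula(paste("value ~ group +",
                                  paste(names(covariates), collapse = " + ")))
  fit <- stats::lm(form, data = d, contrasts = list(group = "contr.sum"))
  a <- car::Anova(fit, type = 3)
  keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
  .anovaRow(rownames(a)[keep], a$`F value`[keep], a$Df[keep],
            a$Df[rownames(a) == "Residuals"], a$`Pr(>F)`[keep])
}

#' Mixed time-by-group (split-plot) ANOVA
#'
#' Repeated-measures ANOVA with time (two paired scans per subject) as the
#' within-subjects factor and group as the between-subjects factor: the
#' between effect is tested against between-subject variation, time and the
#' time x group interaction against the within-subject residual. With only
#' two timepoints sphericity holds trivially and no correction applies.
#' Subjects missing either timepoint are dropped with a message.
#'
#' @param pre,post numeric per-subject values at the two timepoints (aligned;
#'   NA drops the subject).
#' @param group group labels (2+ levels).
#' @return data.frame with rows `group`, `time`, `group:time`.
#' @export
mixedAnovaTimeGroup <- function(pre, post, group) {
  keep <- !(is.na(pre) | is.na(post))
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped for a missing timepoint")
  pre <- pre[keep]; post <- post[keep]
  group <- factor(group)[keep]
  group <- droplevels(group)
  if (any(table(group) < 2)) stop("each group needs >= 2 complete subjects")
  n <- length(pre)
  d <- data.frame(value = c(pre, post),
                  time = factor(rep(c("pre", "post"), each = n),
                                levels = c("pre", "post")),
                  group = rep(group, 2),
                  subject = factor(rep(seq_len(n), 2)))
  fit <- stats::aov(value ~ group * time + Error(subject), data = d)
  s <- summary(fit)
  btw <- s[["Error: subject"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  rn <- function(tab) trimws(rownames(tab))
  rbind(
    .anovaRow("group", btw[rn(btw) == "group", "F value"],
              btw[rn(btw) == "group", "Df"],
              btw[rn(btw) == "Residuals", "Df"],
              btw[rn(btw) == "group", "Pr(>F)"]),
    .anovaRow("time", wth[rn(wth) == "time", "F value"],
              wth[rn(wth) == "time", "Df"],
              wth[rn(wth) == "Residuals", "Df"],
              wth[rn(wth) == "time", "Pr(>F)"]),
    .anovaRow("group:time", wth[rn(wth) == "group:time", "F value"],
              wth[rn(wth) == "group:time", "Df"],
              wth[rn(wth) == "Residuals", "Df"],
              wth[rn(wth) == "group:time", "Pr(>F)"]))
}

#' Post-hoc contrasts for a time-by-group interaction
#'
#' Characterizes a significant interaction with (a) within-group paired
#' pre/post contrasts and (b) pairwise between-group contrasts at each
#' timepoint, optionally adjusted for a covariate such as age. P-values are
#' corrected over the whole emitted contrast family (default Bonferroni;
#' `adjust = "none"` disables).
#'
#' @param pre,post per-subject values at the two timepoints.
#' @param group group labels.
#' @param covariate optional numeric covariate for the between-group
#'   contrasts (within-group paired contrasts are unadjusted; the covariate
#'   cancels within subject).
#' @param adjust multiplicity correction passed to [stats::p.adjust()]
#'   applied across all rows.
#' @return data.frame with columns `contrast`, `scope`, `estimate`, `p`,
#'   `p_adj`.
#' @export
posthocContrasts <- function(pre, post, group, covariate = NULL,
                             adjust = "bonferroni") {
  group <- droplevels(factor(group))
  rows <- list()
  for (g in levels(group)) {
    k <- group == g
    tt <- stats::t.test(post[k], pre[k], paired = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      contrast = paste0(g, ": post vs pre"), scope = "time-within-group",
      estimate = unname(tt$estimate), p = tt$p.value)
  }
  gl <- levels(group)
  for (tp in c("pre", "post")) {
    v <- if (tp == "pre") pre else post
    for (a in seq_along(gl)) for (b in seq_along(gl)) {
      if (a >= b) next
      k <- group %in% gl[c(a, b)]
      d <- data.frame(value = v[k],
                      g = factor(group[k], levels = gl[c(a, b)]))
      if (!is.null(covariate)) d$cov <- covariate[k]
      fit <- stats::lm(if (is.null(covariate)) value ~ g else
        value ~ g + cov, data = d)
      cf <- summary(fit)$coefficients[2, ]
      rows[[length(rows) + 1]] <- data.frame(
        contrast = paste0(gl[a], " vs ", gl[b], " @ ", tp),
        scope = "group-within-time",
        estimate = -unname(cf["Estimate"]), p = unname(cf["Pr(>|t|)"]))
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p raw p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `p_adjusted` (monotone BH-adjusted p-values) and
#'   `rejected` (logical, adjusted p <= `q`, equivalent to the step-up rule
#'   p(i) <= i q / m).
#' @export
bhFdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, rejected = adj <= q)
}

#' Run an analysis per network-pair measure with FDR control
#'
#' Applies an analysis function to every measure of a long-format signature
#' summary (one family: the overall mean plus each network-pair mean) and
#' BH-adjusts a chosen p-value column across the non-overall measures.
#'
#' @param summaries long data.frame from [summarizeSignature()].
#' @param fun function(measureData) -> one-row (or k-row) data.frame with a
#'   `p` column; `measureData` has columns of `summaries` for one measure.
#' @param effect optional effect name to FDR-adjust when `fun` returns
#'   several rows per measure (default: all rows).
#' @param q FDR level.
#' @return data.frame of stacked results with `measure`, `fdr_p`, `rejected`
#'   columns added (FDR family = network-pair measures, overall excluded).
#' @export
perMeasureStats <- function(summaries, fun, effect = NULL, q = 0.05) {
  out <- do.call(rbind, lapply(split(summaries, summaries$measure),
                               function(d) {
    r <- fun(d)
    r$measure <- d$measure[1]
    r
  }))
  rownames(out) <- NULL
  sel <- out$measure != "overall"
  if (!is.null(effect)) sel <- sel & out$effect == effect
  out$fdr_p <- NA_real_
  out$rejected <- NA
  if (any(sel)) {
    fdr <- bhFdr(out$p[sel], q)
    out$fdr_p[sel] <- fdr$p_adjusted
    out$rejected[sel] <- fdr$rejected
  }
  out
}
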