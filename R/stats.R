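outcome_column <- function(outcome) {
  switch(outcome,
         carbonyl = "mean_carbonyl_gsu",
         hne = "mean_hne_gsu",
         csa = "mean_csa_um2",
         stop("unknown outcome: ", outcome))
}

# Drop covariates that are constant in the data (singular design), with a
# warning naming them.
usable_covariates <- function(summaries, covariates) {
  keep <- vapply(covariates, function(cv) {
    v <- summaries[[cv]]
    length(unique(v[!is.na(v)])) > 1
  }, logical(1))
  if (any(!keep))
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
  covariates[keep]
}

#' Covariate-adjusted group comparison (ANCOVA)
#'
#' Fits `outcome ~ group + covariates` on specimen summaries (covariates
#' coded 0/1), tests the group term by F-test, and reports least-squares
#' adjusted group means evaluated at the pooled-sample covariate
#' prevalences, together with the percent difference between groups under
#' both conventions (see [percent_difference()]).
#'
#' @param summaries Specimen summary table ([summarize_cohort()]).
#' @param outcome `"carbonyl"`, `"hne"` or `"csa"`.
#' @param covariates Character vector of binary covariate columns
#'   (default CAD and HTN, the demographics that differ between groups).
#' @return A `group_comparison` list: adjusted means, group-term `F_stat`
#'   with `df`, whole-model `model_F` with `df_model`/`df_resid`,
#'   `p_value` (group term), `percent_difference` (vs the larger mean,
#'   signed) and `percent_difference_vs_control`.
#' @export
adjusted_group_comparison <- function(summaries,
                                      outcome = c("carbonyl", "hne", "csa"),
                                      covariates = c("cad", "htn")) {
  outcome <- match.arg(outcome)
  ycol <- outcome_column(outcome)
  stopifnot(all(c("control", "pad") %in% summaries$group))
  covariates <- usable_covariates(summaries, covariates)
  d <- summaries
  d$y <- d[[ycol]]
  d$group <- factor(d$group, levels = c("control", "pad"))
  for (cv in covariates) d[[cv]] <- as.numeric(d[[cv]])
  rhs <- paste(c("group", covariates), collapse = " + ")
  fit <- lm(as.formula(paste("y ~", rhs)), data = d)
  fit0 <- lm(as.formula(paste("y ~", paste(c("1", covariates), collapse = " + "))),
             data = d)
  an <- anova(fit0, fit)
  sm <- summary(fit)
  newd <- data.frame(group = factor(c("control", "pad"),
                                    levels = c("control", "pad")))
  for (cv in covariates) newd[[cv]] <- mean(d[[cv]])
  adj <- predict(fit, newdata = newd)
  structure(list(
    outcome = outcome,
    adjusted_mean_control = unname(adj[1]),
    adjusted_mean_pad = unname(adj[2]),
    F_stat = an$F[2],
    df = c(an$Df[2], an$Res.Df[2]),
    model_F = unname(sm$fstatistic[1]),
    df_model = unname(sm$fstatistic[2]),
    df_resid = unname(sm$fstatistic[3]),
    p_value = an$`Pr(>F)`[2],
    percent_difference = percent_difference(adj[1], adj[2], "vs_larger"),
    percent_difference_vs_control = percent_difference(adj[1], adj[2], "vs_control"),
    covariates = covariates,
    fit = fit
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("%s: adjusted means control %.1f, PAD %.1f (%+.1f%% vs larger, ",
           "%+.1f%% vs control)\n  group F(%d,%d) = %.2f, p = %.2g; ",
           "adjusted for: %s\n"),
    x$outcome, x$adjusted_mean_control, x$adjusted_mean_pad,
    x$percent_difference, x$percent_difference_vs_control,
    x$df[1], x$df[2], x$F_stat, x$p_value,
    if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "nothing"))
  invisible(x)
}

#' Percent difference between group means
#'
#' Two reporting conventions: `vs_control` is the classical
#' (pad - control) / control x 100; `vs_larger` divides by the larger of
#' the two means, keeping the sign of (pad - control). With group means of
#' 486/695 gsu (carbonyl) and 261/436 gsu (HNE) the `vs_larger` convention
#' yields the familiar +30% and +40%; a CSA reduction of 5324 to 3760 um^2
#' is -29.4% under `vs_control`.
#'
#' @param mean_control,mean_pad Group means.
#' @param convention `"vs_larger"` (default) or `"vs_control"`.
#' @return Signed percent difference.
#' @export
percent_difference <- function(mean_control, mean_pad,
                               convention = c("vs_larger", "vs_control")) {
  convention <- match.arg(convention)
  denom <- switch(convention,
                  vs_control = mean_control,
                  vs_larger = max(mean_control, mean_pad))
  if (denom == 0) stop("zero denominator in percent difference")
  unname((mean_pad - mean_control) / denom * 100)
}

#' Damage trend across Fontaine stages
#'
#' Regresses a PAD outcome on the numeric Fontaine stage (2/3/4) plus
#' binary covariates; reports the per-stage slope, the R-squared of the
#' fitted model, and the two-sided p-value of the slope.
#'
#' @param summaries Specimen summaries restricted to (or containing) the
#'   PAD group; rows with missing stage are dropped.
#' @inheritParams adjusted_group_comparison
#' @return A `trend_result` list: `slope`, `slope_se`, `r_squared`,
#'   `p_value`, `n`, `stage_means`.
#' @export
stage_trend <- function(summaries, outcome = c("carbonyl", "hne", "csa"),
                        covariates = c("cad", "htn")) {
  outcome <- match.arg(outcome)
  d <- summaries[!is.na(summaries$fontaine_stage), , drop = FALSE]
  if (length(unique(d$fontaine_stage)) < 2)
    stop("need >= 2 distinct Fontaine stages")
  covariates <- usable_covariates(d, covariates)
  d$y <- d[[outcome_column(outcome)]]
  d$stage <- as.numeric(d$fontaine_stage)
  for (cv in covariates) d[[cv]] <- as.numeric(d[[cv]])
  rhs <- paste(c("stage", covariates), collapse = " + ")
  fit <- lm(as.formula(paste("y ~", rhs)), data = d)
  co <- summary(fit)$coefficients
  structure(list(
    outcome = outcome,
    slope = co["stage", "Estimate"],
    slope_se = co["stage", "Std. Error"],
    r_squared = summary(fit)$r.squared,
    p_value = co["stage", "Pr(>|t|)"],
    n = nrow(d),
    stage_means = tapply(d$y, d$stage, mean),
    covariates = covariates,
    fit = fit
  ), class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("%s vs Fontaine stage: slope %.1f per stage (SE %.1f), R^2 = %.2f, p = %.2g (n = %d)\n",
              x$outcome, x$slope, x$slope_se, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pearson partial correlation with the ankle-brachial index
#'
#' Partial correlation of a PAD outcome with ABI given binary covariates:
#' both variables are residualized on the covariates and the residuals are
#' correlated. The confidence interval uses the Fisher z transform with
#' standard error 1/sqrt(n - k - 3) (k covariates); the two-sided p-value
#' comes from the t distribution with n - k - 2 degrees of freedom. With
#' no covariates this reduces to the plain Pearson correlation.
#'
#' @param summaries Specimen summaries (PAD rows are used if `group`
#'   present).
#' @inheritParams adjusted_group_comparison
#' @param conf_level Confidence level of the interval.
#' @return A `partial_correlation` list: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `covariates`.
#' @export
abi_partial_correlation <- function(summaries,
                                    outcome = c("carbonyl", "hne", "csa"),
                                    covariates = c("cad", "htn"),
                                    conf_level = 0.95) {
  outcome <- match.arg(outcome)
  d <- summaries
  if ("group" %in% names(d) && any(d$group == "pad"))
    d <- d[d$group == "pad", , drop = FALSE]
  covariates <- usable_covariates(d, covariates)
  k <- length(covariates)
  n <- nrow(d)
  if (n <= k + 3) stop("insufficient n for partial correlation")
  d$y <- d[[outcome_column(outcome)]]
  for (cv in covariates) d[[cv]] <- as.numeric(d[[cv]])
  if (k > 0) {
    rhs <- paste(covariates, collapse = " + ")
    ry <- resid(lm(as.formula(paste("y ~", rhs)), data = d))
    rx <- resid(lm(as.formula(paste("abi ~", rhs)), data = d))
  } else {
    ry <- d$y; rx <- d$abi
  }
  r <- cor(rx, ry)
  z <- atanh(r)
  se <- 1 / sqrt(n - k - 3)
  zc <- qnorm(1 - (1 - conf_level) / 2)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  structure(list(
    outcome = outcome, r = r,
    ci_low = tanh(z - zc * se), ci_high = tanh(z + zc * se),
    p_value = 2 * pt(-abs(tstat), df),
    n = n, covariates = covariates
  ), class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("%s vs ABI: partial r = %.2f, %d%% CI [%.2f, %.2f], p = %.2g (n = %d)\n",
              x$outcome, x$r, 95, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Repeated-measures model of class-mean CSA across quartile classes
#'
#' Within-patient model of per-class mean CSA on quartile class with
#' patient as blocking factor (a within-subject ANOVA on up to four
#' repeated values per patient). If the overall class effect is
#' significant at `alpha`, least-squares pairwise contrasts of Q4 against
#' Q1, Q2 and Q3 are computed (unadjusted by default, matching raw
#' pairwise reporting; `adjust = "holm"` is available).
#'
#' @param quartile_tab Long table from [quartile_table()] with a `group`
#'   column.
#' @param marker `"carbonyl"` or `"hne"`.
#' @param group `"pad"` or `"control"`.
#' @param alpha Significance level gating the post hoc contrasts.
#' @param adjust Multiplicity adjustment for the contrasts
#'   (`"none"` or any method accepted by emmeans).
#' @return A `quartile_model` list: `overall_F`, `df`, `overall_p`,
#'   `class_means`, and `contrasts` (data frame of Q4 vs Q1/Q2/Q3, or
#'   `NULL` when the overall test is not significant).
#' @export
quartile_repeated_measures <- function(quartile_tab, marker = c("carbonyl", "hne"),
                                       group = c("pad", "control"),
                                       alpha = 0.05, adjust = "none") {
  marker <- match.arg(marker)
  group <- match.arg(group)
  d <- quartile_tab[quartile_tab$marker == marker &
                      quartile_tab$group == group &
                      !is.na(quartile_tab$mean_csa_um2), , drop = FALSE]
  if (nrow(d) == 0) stop("no non-missing class means for ", marker, "/", group)
  per_pat <- table(d$patient_id)
  if (sum(per_pat >= 2) < 2)
    stop("need >= 2 patients with >= 2 non-missing classes")
  d$patient_id <- factor(d$patient_id)
  d$class <- factor(d$class, levels = c("Q1", "Q2", "Q3", "Q4"))
  fit <- lm(mean_csa_um2 ~ patient_id + class, data = d)
  an <- anova(fit)
  overall_p <- an["class", "Pr(>F)"]
  # exactly flat class profiles leave a 0/0 F ratio; report it as no effect
  if (an["class", "Mean Sq"] < 1e-10 * mean(d$mean_csa_um2)^2) {
    an["class", "F value"] <- 0
    overall_p <- 1
  }
  contrasts <- NULL
  if (!is.na(overall_p) && overall_p < alpha) {
    em <- emmeans::emmeans(fit, "class")
    pw <- summary(emmeans::contrast(em, method = "pairwise", adjust = adjust))
    sel <- grepl("Q4", pw$contrast)
    contrasts <- data.frame(contrast = pw$contrast[sel],
                            estimate = pw$estimate[sel],
                            p_value = pw$p.value[sel],
                            stringsAsFactors = FALSE)
  }
  cm <- tapply(d$mean_csa_um2, d$class, mean)
  structure(list(
    marker = marker, group = group,
    overall_F = an["class", "F value"],
    df = c(an["class", "Df"], an["Residuals", "Df"]),
    overall_p = overall_p,
    class_means = cm,
    contrasts = contrasts
  ), class = "quartile_model")
}

#' @export
print.quartile_model <- function(x, ...) {
  cat(sprintf("CSA by %s quartile class (%s): F(%d,%d) = %.2f, p = %.2g\n",
              x$marker, x$group, x$df[1], x$df[2], x$overall_F, x$overall_p))
  cat("  class means (um^2):",
      paste(sprintf("%s %.0f", names(x$class_means), x$class_means),
            collapse = ", "), "\n")
  if (!is.null(x$contrasts))
    for (i in seq_len(nrow(x$contrasts)))
      cat(sprintf("  %s: %+0.0f um^2, p = %.2g\n", x$contrasts$contrast[i],
                  x$contrasts$estimate[i], x$contrasts$p_value[i]))
  invisible(x)
}

#' Agreement of the two damage markers across specimens
#'
#' Plain Pearson correlation (with test) between specimen mean carbonyl
#' and specimen mean HNE signal.
#'
#' @param summaries Specimen summary table (>= 3 rows).
#' @return List `r`, `p_value`, `n`, `ci_low`, `ci_high`.
#' @export
marker_agreement <- function(summaries) {
  if (nrow(summaries) < 3) stop("need >= 3 specimens")
  ct <- cor.test(summaries$mean_carbonyl_gsu, summaries$mean_hne_gsu)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(summaries),
       ci_low = ct$conf.int[1], ci_high = ct$conf.int[2])
}

#' Baseline demographics tests
#'
#' Compares each metadata variable between groups: chi-square test
#' (without continuity correction) for binary/logical variables, one-way
#' linear-model F-test for continuous ones. Variables with p < 0.05 are
#' flagged as covariate candidates for the adjusted analyses.
#'
#' @param metadata Patient metadata with a `group` column.
#' @param variables Columns to test; defaults to every column except
#'   identifiers and stage.
#' @return Data frame: `variable`, `test`, `statistic`, `df`, `p_value`,
#'   `covariate_candidate`. Tests on degenerate (zero-cell or constant)
#'   variables are reported as not computable (`NA`).
#' @export
demographics_table <- function(metadata,
                               variables = setdiff(names(metadata),
                                                   c("patient_id", "group",
                                                     "fontaine_stage"))) {
  rows <- lapply(variables, function(v) {
    x <- metadata[[v]]
    if (is.logical(x) || (is.numeric(x) && all(x %in% c(0, 1, NA)))) {
      tab <- table(metadata$group, x)
      if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(data.frame(variable = v, test = "chi_square",
                          statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, covariate_candidate = FALSE))
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chi_square",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value,
                 covariate_candidate = ct$p.value < 0.05)
    } else {
      fit <- lm(x ~ group, data = cbind(metadata, x = as.numeric(x)))
      an <- anova(fit)
      data.frame(variable = v, test = "linear_model_F",
                 statistic = an["group", "F value"], df = an["group", "Df"],
                 p_value = an["group", "Pr(>F)"],
                 covariate_candidate = an["group", "Pr(>F)"] < 0.05)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scatterplots of damage vs stage and vs ABI
#'
#' Writes SVG scatterplots of specimen mean damage against Fontaine stage
#' and against ABI for the PAD group, one file per marker/predictor.
#'
#' @param summaries Specimen summary table.
#' @param outdir Directory for the SVG files.
#' @return Character vector of files written, invisibly.
#' @export
plot_damage_relationships <- function(summaries, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  d <- summaries[summaries$group == "pad", , drop = FALSE]
  files <- character()
  for (mk in c("carbonyl", "hne")) {
    y <- d[[outcome_column(mk)]]
    for (pred in c("fontaine_stage", "abi")) {
      f <- file.path(outdir, sprintf("%s_vs_%s.svg", mk, pred))
      grDevices::svg(f, width = 5, height = 4)
      graphics::plot(d[[pred]], y,
                     xlab = if (pred == "abi") "Ankle-brachial index" else "Fontaine stage",
                     ylab = sprintf("Mean %s signal (gsu)", mk),
                     pch = 19, col = "grey30")
      graphics::abline(lm(y ~ d[[pred]]), col = "firebrick")
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(files)
}
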