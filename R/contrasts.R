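## Longitudinal change-score statistics: module-labelled change records,
## mixed-model group contrasts with age/sex covariates and a random subject
## intercept, Cohen's D, multiplicity correction and univariate
## brain--cortisol change associations.

#' Build module-labelled change records
#'
#' Turns per-(subject, timepoint) measures into change scores over every
#' consecutive 3-month interval of a subject's cohort for which both
#' endpoints are present, labelled with the module trained during the
#' interval (or `"retest"` for the control cohort).
#'
#' @param measures long table: `subject_id`, `timepoint`, `measure`,
#'   `value` (one row per subject, timepoint and named measure, e.g.
#'   `volume:R_CA13` or `cortisol:aucg`).
#' @param subjects subject roster: `subject_id`, `cohort`, `age`, `sex`.
#' @return data.table: `subject_id`, `cohort`, `module`, `t_a`, `t_b`,
#'   `measure`, `delta`, `age`, `sex`.
#' @export
build_change_records <- function(measures, subjects) {
  measures <- data.table::as.data.table(measures)
  subjects <- data.table::as.data.table(subjects)
  recs <- list()
  for (co in unique(subjects$cohort)) {
    sids <- subjects[cohort == co, subject_id]
    for (iv in cohort_intervals(co)) {
      a <- measures[subject_id %in% sids & timepoint == iv[1]]
      b <- measures[subject_id %in% sids & timepoint == iv[2]]
      m <- merge(a, b, by = c("subject_id", "measure"),
                 suffixes = c("_a", "_b"))
      m <- m[!is.na(value_a) & !is.na(value_b)]
      if (nrow(m) == 0) next
      recs[[paste(co, iv[1])]] <- m[, .(
        subject_id, cohort = co, module = module_schedule(co, iv),
        t_a = iv[1], t_b = iv[2], measure, delta = value_b - value_a)]
    }
  }
  if (!length(recs))
    return(data.table::data.table(
      subject_id = character(), cohort = character(), module = character(),
      t_a = character(), t_b = character(), measure = character(),
      delta = numeric(), age = numeric(), sex = character()))
  out <- data.table::rbindlist(recs)
  out <- merge(out, subjects[, .(subject_id, age, sex)], by = "subject_id",
               sort = FALSE)
  data.table::setorder(out, measure, subject_id, t_a)
  out[]
}

#' Canonical contrast arm filters
#'
#' The two main contrasts of the design plus the retest comparisons:
#' `Affect_vs_Perspective` (within the two 9-month cohorts),
#' `Presence_vs_ActiveControl` (Presence in TC1/TC2 vs the single-module
#' Affect cohort TC3, between subjects), and `<Module>_vs_Retest`.
#'
#' @param name contrast name.
#' @return A list of two arm filters, each `list(module=, cohort=)` with
#'   `NULL` meaning "any".
#' @export
contrast_arms <- function(name) {
  switch(name,
    Affect_vs_Perspective = list(
      A = list(module = "Affect", cohort = c("TC1", "TC2")),
      B = list(module = "Perspective", cohort = c("TC1", "TC2"))),
    Presence_vs_ActiveControl = list(
      A = list(module = "Presence", cohort = c("TC1", "TC2")),
      B = list(module = "Affect", cohort = "TC3")),
    Presence_vs_Retest = list(
      A = list(module = "Presence", cohort = NULL),
      B = list(module = "retest", cohort = "RCC")),
    Affect_vs_Retest = list(
      A = list(module = "Affect", cohort = c("TC1", "TC2")),
      B = list(module = "retest", cohort = "RCC")),
    Perspective_vs_Retest = list(
      A = list(module = "Perspective", cohort = NULL),
      B = list(module = "retest", cohort = "RCC")),
    stop("unknown contrast: ", name))
}

#' @keywords internal
filter_arm <- function(records, arm) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(arm$module)) keep <- keep & records$module %in% arm$module
  if (!is.null(arm$cohort)) keep <- keep & records$cohort %in% arm$cohort
  records[keep]
}

#' Fit a two-arm contrast on change scores
#'
#' Linear model of the change score on an arm indicator plus age and sex,
#' with a random intercept per subject when subjects contribute more than
#' one record (within-subject contrasts pool a subject's intervals). With
#' one record per subject the model degenerates to ordinary least squares,
#' and without covariates to the classical two-sample t-test. The reported
#' t is the Wald statistic of the arm indicator with a residual-df
#' approximation for its p-value.
#'
#' @param records change-record table (one measure).
#' @param arms a two-element list of arm filters (see [contrast_arms()]),
#'   or a contrast name.
#' @param covariates include age and sex (default TRUE).
#' @param extra_covariates optional character vector of additional numeric
#'   covariate columns present in `records` (e.g. the other subfields'
#'   change scores).
#' @return An object of class `contrast_result`: `contrast`, `t`, `df`,
#'   `p`, `d` (Cohen's D), `design` (`"between"`/`"within"`), per-arm `n`,
#'   `mean`, `sd` and 95% CI, and the `model` descriptor.
#' @export
fit_contrast <- function(records, arms, covariates = TRUE,
                         extra_covariates = NULL) {
  if (is.character(arms)) {
    nm <- arms
    arms <- contrast_arms(arms)
  } else nm <- paste(names(arms), collapse = "_vs_")
  records <- data.table::as.data.table(records)
  a <- filter_arm(records, arms[[1]])
  b <- filter_arm(records, arms[[2]])
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each arm needs at least 2 records")
  dat <- rbind(a[, arm := 1], b[, arm := 0])
  within <- length(intersect(a$subject_id, b$subject_id)) > 0
  dup <- any(duplicated(dat$subject_id))

  rhs <- "arm"
  if (covariates) rhs <- c(rhs, "age", "sex")
  if (!is.null(extra_covariates)) rhs <- c(rhs, extra_covariates)
  fixed <- stats::reformulate(rhs, response = "delta")

  if (dup) {
    form <- stats::update.formula(fixed, . ~ . + (1 | subject_id))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   "ignore"))))
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    X <- stats::model.matrix(fixed, dat)
    df <- nrow(dat) - qr(X)$rank
    model <- "lmm(delta ~ arm + covariates + (1|subject))"
  } else {
    fit <- stats::lm(fixed, data = dat)
    sm <- summary(fit)$coefficients
    co <- sm[, 1]; se <- sm[, 2]
    df <- fit$df.residual
    model <- "ols(delta ~ arm + covariates)"
  }
  est <- unname(co["arm"]); sev <- unname(se[which(names(co) == "arm")])
  t <- est / sev
  p <- 2 * stats::pt(-abs(t), df)

  n1 <- length(unique(a$subject_id)); n2 <- length(unique(b$subject_id))
  design <- if (within) "within" else "between"
  d <- if (within) cohens_d(t, n = length(intersect(a$subject_id,
                                                    b$subject_id)),
                            design = "within")
       else cohens_d(t, n1 = n1, n2 = n2, design = "between")
  arm_desc <- function(x) {
    m <- mean(x$delta); s <- stats::sd(x$delta); n <- nrow(x)
    ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * s / sqrt(n)
    list(n = n, mean = m, sd = s, ci95 = ci)
  }
  res <- list(contrast = nm, t = t, df = df, p = p, d = d, design = design,
              estimate = est, arm_a = arm_desc(a), arm_b = arm_desc(b),
              model = model)
  class(res) <- "contrast_result"
  res
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s (%s)\n", x$contrast, x$design))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g, Cohen's D = %.3f\n",
              x$t, x$df, x$p, x$d))
  cat(sprintf("  arm A: n = %d, mean = %.3f (sd %.3f)\n",
              x$arm_a$n, x$arm_a$mean, x$arm_a$sd))
  cat(sprintf("  arm B: n = %d, mean = %.3f (sd %.3f)\n",
              x$arm_b$n, x$arm_b$mean, x$arm_b$sd))
  invisible(x)
}

#' Cohen's D from a t statistic
#'
#' Between-subject design: `d = t * sqrt(1/n1 + 1/n2)`. Within-subject or
#' one-sample design: `d = t / sqrt(n)`.
#'
#' @param t t statistic.
#' @param n1,n2 per-arm subject counts (between design).
#' @param n subject count (within design).
#' @param design `"between"` or `"within"`.
#' @return Cohen's D.
#' @export
cohens_d <- function(t, n1 = NULL, n2 = NULL, n = NULL,
                     design = c("between", "within")) {
  design <- match.arg(design)
  if (design == "between") {
    stopifnot(!is.null(n1), !is.null(n2), n1 > 0, n2 > 0)
    t * sqrt(1 / n1 + 1 / n2)
  } else {
    stopifnot(!is.null(n), n > 0)
    t / sqrt(n)
  }
}

#' Multiple-comparison correction
#'
#' Benjamini-Hochberg step-up false-discovery-rate q-values (default,
#' matching reported q values) or Bonferroni.
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"bh"` or `"bonferroni"`.
#' @return q-values (same length; BH q-values are monotone and never below
#'   p).
#' @export
correct_multiplicity <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value list")
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Association between brain change and cortisol change
#'
#' Regresses the brain change score on the cortisol change score plus age
#' and sex, per subject-interval pair. With a single module the model is
#' ordinary least squares; pooling several modules adds a random subject
#' intercept (subjects contribute one pair per interval).
#'
#' @param brain change records of one brain measure.
#' @param cortisol change records of one cortisol measure.
#' @param modules module filter (default: the module(s) present in both).
#' @param covariates include age and sex.
#' @return A list: `t`, `df`, `p`, `slope`, `sign`, `n`, `model`.
#' @export
associate_change <- function(brain, cortisol, modules = NULL,
                             covariates = TRUE) {
  brain <- data.table::as.data.table(brain)
  cortisol <- data.table::as.data.table(cortisol)
  if (!is.null(modules)) {
    brain <- brain[module %in% modules]
    cortisol <- cortisol[module %in% modules]
  }
  m <- merge(brain[, .(subject_id, t_a, t_b, module, age, sex,
                       d_brain = delta)],
             cortisol[, .(subject_id, t_a, t_b, d_cort = delta)],
             by = c("subject_id", "t_a", "t_b"))
  rhs <- "d_cort"
  if (covariates) rhs <- c(rhs, "age", "sex")
  need <- length(rhs) + 2L
  if (nrow(m) < need) stop("too few paired records (n = ", nrow(m), ")")
  if (stats::sd(m$d_cort) == 0) stop("cortisol change score is constant")
  fixed <- stats::reformulate(rhs, response = "d_brain")
  if (any(duplicated(m$subject_id))) {
    form <- stats::update.formula(fixed, . ~ . + (1 | subject_id))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = m, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                   "ignore"))))
    co <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    df <- nrow(m) - qr(stats::model.matrix(fixed, m))$rank
    model <- "lmm"
  } else {
    fit <- stats::lm(fixed, data = m)
    sm <- summary(fit)$coefficients
    co <- sm[, 1]; se <- sm[, 2]
    df <- fit$df.residual
    model <- "ols"
  }
  i <- which(names(co) == "d_cort")
  t <- unname(co[i] / se[i])
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       slope = unname(co[i]), sign = sign(unname(co[i])), n = nrow(m),
       model = model)
}
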