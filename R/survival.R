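# Survival evaluation of prognostic scores: covariate standardisation,
# Cox proportional-hazards models (Efron ties), Harrell's c-index, AIC,
# likelihood-ratio tests between nested models, Kaplan-Meier curves with
# median-threshold risk grouping and the log-rank test, fixed-horizon
# ROC/AUC, and scaled-Schoenfeld proportional-hazards diagnostics.
#
# Model fitting is delegated to the survival package; the c-index and the
# horizon AUC are computed by explicit pairwise/rank formulas so they can
# be checked against independent oracles.

#' Standardise covariate columns to mean 0, SD 1
#'
#' The reference (training) cohort defines the means and SDs; validation
#' data must be standardised with the frozen training statistics by
#' passing them as `stats`. Zero-SD columns are dropped with a warning.
#'
#' @param table data.frame containing the covariate columns.
#' @param covariates character vector of column names to standardise.
#' @param stats optional data.frame (columns covariate, mean, sd) from a
#'   previous call, frozen training statistics.
#' @return the table with standardised columns and attribute `"scaling"`
#'   (the statistics used).
#' @export
standardize_covariates <- function(table, covariates = NULL, stats = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(covariates)) {
    covariates <- if (!is.null(stats)) {
      stats$covariate
    } else {
      names(table)[vapply(table, is.numeric, logical(1))]
    }
  }
  if (is.null(stats)) {
    mu <- vapply(covariates, function(v) mean(table[[v]]), numeric(1))
    sd_ <- vapply(covariates, function(v) stats::sd(table[[v]]), numeric(1))
    drop <- sd_ == 0 | !is.finite(sd_)
    if (any(drop)) {
      warning("dropping zero-SD covariate(s): ", paste(covariates[drop], collapse = ", "))
      table[covariates[drop]] <- NULL
      covariates <- covariates[!drop]
      mu <- mu[!drop]
      sd_ <- sd_[!drop]
    }
    stats <- data.frame(covariate = covariates, mean = mu, sd = sd_)
  }
  for (i in seq_len(nrow(stats))) {
    v <- stats$covariate[i]
    table[[v]] <- (table[[v]] - stats$mean[i]) / stats$sd[i]
  }
  attr(table, "scaling") <- stats
  table
}

#' Fit a Cox proportional-hazards model
#'
#' Wraps `survival::coxph` (Efron ties handling) and returns the summary
#' quantities used throughout the evaluation: coefficients, hazard ratios
#' with Wald 95% CIs and p-values, the partial log-likelihood, AIC
#' (`2k - 2LL`) and Harrell's c-index of the linear predictor.
#'
#' @param data data.frame with time/event columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event names of the survival time (years) and event columns.
#' @return object of class `cox_result`.
#' @export
cox_fit <- function(data, covariates, time = "survival_time_years", event = "event") {
  stopifnot(is.data.frame(data), length(covariates) >= 1)
  tt <- data[[time]]
  ev <- as.logical(data[[event]])
  stopifnot(all(tt > 0), sum(ev) >= 1)
  for (v in covariates) {
    if (stats::sd(data[[v]]) == 0) stop("constant covariate: ", v)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(", time, ",", event, ") ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  diagnostic <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      diagnostic <<- c(diagnostic, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)
  lp <- stats::predict(fit, type = "lp")
  structure(
    list(
      coefficients = stats::coef(fit),
      hazard_ratios = sm$conf.int[, "exp(coef)"],
      ci_lower = sm$conf.int[, "lower .95"],
      ci_upper = sm$conf.int[, "upper .95"],
      p_values = sm$coefficients[, "Pr(>|z|)"],
      loglik = fit$loglik[2],
      loglik_null = fit$loglik[1],
      n_params = length(stats::coef(fit)),
      aic = 2 * length(stats::coef(fit)) - 2 * fit$loglik[2],
      c_index = concordance_index(lp, tt, ev),
      n = nrow(data),
      n_events = sum(ev),
      covariates = covariates,
      linear_predictor = lp,
      time = tt,
      event = ev,
      converged = length(diagnostic) == 0 && all(abs(stats::coef(fit)) < 15),
      diagnostic = diagnostic,
      fit = fit
    ),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf(
    "Cox PH model (%d events / %d subjects), c-index %.3f, AIC %.1f%s\n",
    x$n_events, x$n, x$c_index, x$aic,
    if (x$converged) "" else "  [non-convergence flagged]"
  ))
  tab <- data.frame(
    HR = round(x$hazard_ratios, 3),
    lower = round(x$ci_lower, 3),
    upper = round(x$ci_upper, 3),
    p = signif(x$p_values, 3)
  )
  rownames(tab) <- x$covariates
  print(tab)
  invisible(x)
}

#' Harrell's concordance index by pairwise enumeration
#'
#' A pair (i, j) is comparable when the earlier time is an event (strictly
#' earlier, or tied with a censored later subject). The pair is concordant
#' when the earlier-event subject has the higher risk score; ties in risk
#' count one half.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time survival times.
#' @param event logical event indicators.
#' @return c-index in \[0, 1\], or `NA` if no pair is comparable.
#' @export
concordance_index <- function(risk, time, event) {
  event <- as.logical(event)
  n <- length(time)
  stopifnot(length(risk) == n, length(event) == n)
  Ei <- matrix(event, n, n)
  Ej <- t(Ei)
  lt <- outer(time, time, "<")
  eq <- outer(time, time, "==")
  comparable <- (lt & Ei) | (eq & Ei & !Ej)
  if (!any(comparable)) {
    return(NA_real_)
  }
  gt <- outer(risk, risk, ">")
  tie <- outer(risk, risk, "==")
  (sum(gt[comparable]) + 0.5 * sum(tie[comparable])) / sum(comparable)
}

#' Likelihood-ratio test between nested Cox models
#'
#' @param nested,full `cox_result` objects fitted on the same records with
#'   the nested model's covariates a subset of the full model's.
#' @return list with `statistic` (2 * (LL_full - LL_nested)), `df` and `p`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "cox_result"), inherits(full, "cox_result"))
  if (!all(nested$covariates %in% full$covariates)) {
    stop("models are not nested: nested covariates must be a subset of full")
  }
  if (nested$n != full$n || nested$n_events != full$n_events) {
    stop("models were fitted on different records")
  }
  df <- full$n_params - nested$n_params
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}

#' Kaplan-Meier curves and the log-rank test between groups
#'
#' @param time,event survival times and logical event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `fit` (a `survfit` object), `chisq`, `df` and `p`
#'   (two-sided log-rank).
#' @export
km_logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need at least two non-empty groups")
  event <- as.logical(event)
  d <- data.frame(time = time, event = event, group = droplevels(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(lr$n) - 1
  list(fit = fit, chisq = lr$chisq, df = df, p = stats::pchisq(lr$chisq, df, lower.tail = FALSE))
}

#' High/low risk grouping at the training median
#'
#' @param probabilities evaluation-set risk probabilities.
#' @param reference_probabilities probabilities defining the threshold
#'   (training cohort; pass the evaluation set itself for an apparent
#'   split).
#' @return factor with levels `low`, `high` (`high` when >= the reference
#'   median).
#' @export
median_risk_grouping <- function(probabilities, reference_probabilities) {
  stopifnot(length(reference_probabilities) >= 1)
  if (length(unique(probabilities)) < 2) {
    stop("degenerate split: all probabilities identical")
  }
  thr <- stats::median(reference_probabilities)
  factor(ifelse(probabilities >= thr, "high", "low"), levels = c("low", "high"))
}

#' ROC and AUC for mortality at a fixed horizon
#'
#' Positives are subjects with an event no later than `horizon`; negatives
#' are subjects followed at least `horizon` event-free (an event after the
#' horizon is a negative); subjects censored before the horizon are
#' excluded. AUC is the normalised Mann-Whitney statistic (ties one half),
#' identical to trapezoidal integration of the empirical ROC.
#'
#' @param probabilities risk scores.
#' @param time,event survival data.
#' @param horizon label horizon in years (default 1).
#' @return list with `auc`, `curve` (data.frame fpr/tpr by threshold),
#'   `n_pos`, `n_neg`, `n_excluded`.
#' @export
roc_auc_1yr <- function(probabilities, time, event, horizon = 1) {
  event <- as.logical(event)
  pos <- event & time <= horizon
  neg <- time >= horizon
  keep <- pos | neg
  lab <- pos[keep]
  sc <- probabilities[keep]
  if (!any(lab) || all(lab)) {
    return(list(
      auc = NA_real_, curve = NULL,
      n_pos = sum(lab), n_neg = sum(!lab), n_excluded = sum(!keep)
    ))
  }
  thr <- sort(unique(sc), decreasing = TRUE)
  curve <- data.frame(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) mean(sc[lab] >= t), numeric(1))),
    fpr = c(0, vapply(thr, function(t) mean(sc[!lab] >= t), numeric(1)))
  )
  list(
    auc = auc_mann_whitney(sc, lab), curve = curve,
    n_pos = sum(lab), n_neg = sum(!lab), n_excluded = sum(!keep)
  )
}

#' Proportional-hazards check via scaled Schoenfeld residuals
#'
#' Tests, per covariate, the correlation of the scaled Schoenfeld
#' residuals with the rank of event time (`survival::cox.zph`,
#' `transform = "rank"`).
#'
#' @param cox a `cox_result` with at least 3 events.
#' @return data.frame with columns covariate, chisq, df, p (plus a GLOBAL
#'   row for multivariable models).
#' @export
schoenfeld_ph_check <- function(cox) {
  stopifnot(inherits(cox, "cox_result"))
  if (cox$n_events < 3) stop("too few events for a proportional-hazards check")
  z <- survival::cox.zph(cox$fit, transform = "rank")
  tab <- as.data.frame(z$table)
  data.frame(
    covariate = rownames(tab),
    chisq = tab$chisq, df = tab$df, p = tab$p,
    row.names = NULL
  )
}

#' Write a Kaplan-Meier plot to a PNG file
#'
#' @param km result of [km_logrank()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
plot_km <- function(km, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 720, height = 540)
  on.exit(grDevices::dev.off())
  graphics::plot(km$fit,
    col = c("#2166ac", "#b2182b"), lwd = 2, mark.time = TRUE,
    xlab = "Years", ylab = "Survival probability"
  )
  graphics::legend("bottomleft",
    legend = names(km$fit$strata), col = c("#2166ac", "#b2182b"), lwd = 2,
    bty = "n"
  )
  graphics::title(sprintf("Kaplan-Meier by risk group (log-rank p = %.2g)", km$p))
  invisible(path)
}

#' Write a ROC curve plot to a PNG file
#'
#' @param roc result of [roc_auc_1yr()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(roc, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = 540, height = 540)
  on.exit(grDevices::dev.off())
  graphics::plot(roc$curve$fpr, roc$curve$tpr,
    type = "s", lwd = 2, col = "#b2182b",
    xlab = "False positive rate", ylab = "True positive rate",
    xlim = c(0, 1), ylim = c(0, 1)
  )
  graphics::abline(0, 1, lty = 3)
  graphics::title(sprintf("1-year mortality ROC (AUC = %.2f)", roc$auc))
  invisible(path)
}

#' Compare nested Cox models: c-index with bootstrap CI, AIC, LRT
#'
#' For each named model reports Harrell's c-index with a seeded percentile
#' bootstrap CI, the AIC, and the likelihood-ratio p-value against the
#' declared baseline model (when nested in it).
#'
#' @param models named list of `cox_result` objects fitted on the same
#'   records.
#' @param baseline name of the baseline model for the LRT column.
#' @param n_boot bootstrap resamples for the c-index CI.
#' @param seed bootstrap seed.
#' @return data.frame with one row per model.
#' @export
model_comparison_table <- function(models, baseline = names(models)[1],
                                   n_boot = 1000, seed = 1) {
  stopifnot(is.list(models), length(models) >= 1, !is.null(names(models)))
  base <- models[[baseline]]
  ref_n <- base$n
  ref_ev <- base$n_events
  for (nm in names(models)) {
    m <- models[[nm]]
    if (m$n != ref_n || m$n_events != ref_ev || !isTRUE(all.equal(sort(m$time), sort(base$time)))) {
      stop("model '", nm, "' was fitted on different records than the baseline")
    }
  }
  set.seed(seed)
  boot_idx <- replicate(n_boot, sample.int(ref_n, replace = TRUE), simplify = FALSE)
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    cb <- vapply(boot_idx, function(ii) {
      concordance_index(m$linear_predictor[ii], m$time[ii], m$event[ii])
    }, numeric(1))
    ci <- stats::quantile(cb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    lrt_p <- if (nm == baseline) {
      1
    } else if (all(base$covariates %in% m$covariates)) {
      likelihood_ratio_test(base, m)$p
    } else {
      NA_real_
    }
    data.frame(
      model = nm,
      c_index = m$c_index, c_lower = ci[1], c_upper = ci[2],
      aic = m$aic, lrt_p_vs_baseline = lrt_p
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
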