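# Integration layer: scales the six per-sample metric scores to [0, 1],
# fits the mixed-effect logistic model with patient-grouped
# cross-validation, normalizes integrated probabilities to the cohort
# baseline, and fits univariate per-metric models.

INTEGRATION_METRICS <- c("cn_z", "size_z", "ratio_z", "prc1_z",
                         "liver_coverage_z", "um_methylation_score")

#' Min-max scale the metric matrix
#'
#' Scales each metric column to `[0, 1]` over all rows (observed min maps
#' to 0, max to 1). The per-column scaling record is kept as an attribute
#' so raw values can be recovered.
#'
#' @param metrics Data.frame with `patient_id`, `timepoint`, and metric
#'   columns.
#' @param metric_cols Columns to scale (default: the six integration
#'   metrics present in the data).
#' @return The scaled data.frame with a `"scaling"` attribute.
#' @export
scale_metrics <- function(metrics, metric_cols = NULL) {
  if (is.null(metric_cols)) {
    metric_cols <- intersect(INTEGRATION_METRICS, names(metrics))
    if (!length(metric_cols)) {
      metric_cols <- setdiff(names(metrics), c("patient_id", "timepoint"))
    }
  }
  rec <- data.frame(metric = metric_cols, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(metric_cols)) {
    x <- metrics[[metric_cols[i]]]
    lo <- min(x); hi <- max(x)
    if (hi - lo < 1e-12) stop_data("constant metric column: ", metric_cols[i])
    rec$min[i] <- lo; rec$max[i] <- hi
    metrics[[metric_cols[i]]] <- (x - lo) / (hi - lo)
  }
  attr(metrics, "scaling") <- rec
  metrics
}

#' Invert the min-max scaling
#'
#' @param scaled A [scale_metrics()] result.
#' @return The data.frame on the raw scale.
#' @export
unscale_metrics <- function(scaled) {
  rec <- attr(scaled, "scaling")
  if (is.null(rec)) stop_config("no scaling record attached")
  for (i in seq_len(nrow(rec))) {
    scaled[[rec$metric[i]]] <-
      scaled[[rec$metric[i]]] * (rec$max[i] - rec$min[i]) + rec$min[i]
  }
  attr(scaled, "scaling") <- NULL
  scaled
}

#' Label timepoints for training the integration model
#'
#' Baseline samples and samples collected at or after the patient's relapse
#' date are labelled ctDNA positive; all other timepoints are negative.
#' Patients lost to follow-up are marked ineligible for training (they
#' still receive predictions).
#'
#' @param records,schedule As in [make_clinical_fixture()].
#' @return A data.frame with `patient_id`, `timepoint`, `month`, `label`
#'   (0/1), `eligible`.
#' @export
label_timepoints <- function(records, schedule) {
  bad <- records$relapse == "yes" & is.na(records$relapse_months)
  if (any(bad)) {
    stop_data("relapse = yes without relapse_months: ",
              paste(records$patient_id[bad], collapse = ", "))
  }
  collected <- schedule[schedule$collected == "yes", , drop = FALSE]
  month <- timepoint_months()[collected$timepoint]
  rec <- records[match(collected$patient_id, records$patient_id), , drop = FALSE]
  positive <- collected$timepoint == "baseline" |
    (rec$relapse == "yes" & month >= rec$relapse_months)
  data.frame(
    patient_id = collected$patient_id,
    timepoint = collected$timepoint,
    month = unname(month),
    label = as.integer(positive),
    eligible = rec$relapse != "lost",
    stringsAsFactors = FALSE
  )
}

# Fit a binomial GLMM with a patient random intercept; falls back to a
# fixed-effect logistic fit when the GLMM errors out (recorded in the
# returned flags).
fit_glmm <- function(formula, data, fallback_formula) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(calc.derivs = FALSE)),
      error = function(e) NULL
    ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  if (is.null(fit)) {
    fit <- suppressWarnings(
      stats::glm(fallback_formula, data = data, family = stats::binomial())
    )
    return(list(fit = fit, glmm = FALSE, messages = c(msgs, "glmer failed; glm fallback")))
  }
  list(fit = fit, glmm = TRUE, messages = msgs)
}

predict_prob <- function(fitted, newdata) {
  if (fitted$glmm) {
    stats::predict(fitted$fit, newdata = newdata, type = "response",
                   re.form = NA, allow.new.levels = TRUE)
  } else {
    stats::predict(fitted$fit, newdata = newdata, type = "response")
  }
}

#' Fit the mixed-effect logistic integration model
#'
#' Logistic regression of the ctDNA label on the scaled metrics with a
#' Gaussian random intercept per patient (Laplace approximation). Training
#' uses only eligible rows. Cross-validation folds are assigned at the
#' patient level — no patient's rows ever straddle folds — with the fold
#' count capped at the number of eligible patients (with a warning) when
#' the requested `n_folds` exceeds it. Cross-validated probabilities are
#' produced for every eligible row; the final model is refit on all
#' eligible rows and used to predict every row, including ineligible
#' patients. All predictions are population-level (random effects set to
#' zero) so held-out and never-seen patients are scored identically.
#'
#' @param scaled A [scale_metrics()] result.
#' @param labels A [label_timepoints()] result.
#' @param n_folds Requested folds (default 10).
#' @param seed Integer RNG seed for the fold shuffle.
#' @param metric_cols Metric columns (default: the scaling record).
#' @return An object of class `integration_fit` with coefficients,
#'   random-intercept variance, fold table, per-row probabilities
#'   (`prob`, `cv_prob`), `cv_accuracy`, and convergence flags.
#' @export
fit_integration_model <- function(scaled, labels, n_folds = 10L, seed = 1L,
                                  metric_cols = NULL) {
  if (is.null(metric_cols)) {
    rec <- attr(scaled, "scaling")
    metric_cols <- if (!is.null(rec)) rec$metric else
      setdiff(names(scaled), c("patient_id", "timepoint"))
  }
  data <- merge(scaled, labels, by = c("patient_id", "timepoint"), sort = FALSE)
  if (nrow(data) != nrow(scaled)) stop_data("metric rows and labels do not align")
  data <- data[order(data$patient_id, data$month), , drop = FALSE]
  train <- data[data$eligible, , drop = FALSE]
  if (length(unique(train$patient_id)) < 2L) {
    stop_data("need at least 2 eligible patients")
  }
  if (length(unique(train$label)) < 2L) {
    stop_model("training labels are single-class; model unidentifiable")
  }
  fml <- stats::as.formula(paste("label ~",
                                 paste(metric_cols, collapse = " + "),
                                 "+ (1 | patient_id)"))
  fml_fixed <- stats::as.formula(paste("label ~",
                                       paste(metric_cols, collapse = " + ")))

  patients <- sort(unique(train$patient_id))
  k <- min(n_folds, length(patients))
  if (k < n_folds) {
    warning("n_folds capped at ", k, " (number of eligible patients)")
  }
  fold_of <- withr_seed(seed, {
    stats::setNames(rep(seq_len(k), length.out = length(patients))[
      order(stats::runif(length(patients)))], patients)
  })

  cv_prob <- rep(NA_real_, nrow(data))
  messages <- character(0)
  for (f in seq_len(k)) {
    hold <- names(fold_of)[fold_of == f]
    tr <- train[!train$patient_id %in% hold, , drop = FALSE]
    if (length(unique(tr$label)) < 2L) next
    fitted <- fit_glmm(fml, tr, fml_fixed)
    messages <- c(messages, fitted$messages)
    rows <- which(data$eligible & data$patient_id %in% hold)
    cv_prob[rows] <- predict_prob(fitted, data[rows, , drop = FALSE])
  }

  final <- fit_glmm(fml, train, fml_fixed)
  messages <- c(messages, final$messages)
  prob <- predict_prob(final, data)
  coefs <- if (final$glmm) lme4::fixef(final$fit) else stats::coef(final$fit)
  re_var <- if (final$glmm) {
    as.numeric(lme4::VarCorr(final$fit)$patient_id[1, 1])
  } else NA_real_
  eligible_cv <- data$eligible & !is.na(cv_prob)
  cv_accuracy <- mean((cv_prob[eligible_cv] > 0.5) == (data$label[eligible_cv] == 1))
  structure(
    list(coefficients = coefs,
         random_intercept_var = re_var,
         folds = data.frame(patient_id = patients, fold = unname(fold_of),
                            stringsAsFactors = FALSE),
         rows = data[, c("patient_id", "timepoint", "month", "label", "eligible")],
         prob = prob,
         cv_prob = cv_prob,
         cv_accuracy = cv_accuracy,
         glmm = final$glmm,
         model = final$fit,
         messages = unique(messages)),
    class = "integration_fit"
  )
}

#' @export
print.integration_fit <- function(x, ...) {
  cat("integration_fit:", nrow(x$rows), "rows; CV accuracy =",
      signif(x$cv_accuracy, 4),
      if (x$glmm) "(GLMM)" else "(fixed-effect fallback)", "\n")
  invisible(x)
}

#' Normalize integrated probabilities to the cohort baseline
#'
#' Subtracts the mean probability of the cohort's baseline samples from
#' every row's probability, so trajectories are expressed relative to the
#' pretreatment state; the baseline rows' normalized scores average to 0
#' exactly. Patients without a baseline draw simply do not contribute to
#' the baseline mean.
#'
#' @param fit A [fit_integration_model()] result.
#' @return A data.frame with `patient_id`, `timepoint`, `month`, `prob`,
#'   `score` (baseline-normalized), and a `"baseline_mean"` attribute.
#' @export
normalize_to_baseline <- function(fit) {
  rows <- fit$rows
  base <- rows$timepoint == "baseline" & !is.na(fit$prob)
  if (!any(base)) stop_data("no baseline rows with predictions")
  baseline_mean <- mean(fit$prob[base])
  out <- data.frame(rows[, c("patient_id", "timepoint", "month")],
                    prob = fit$prob,
                    score = fit$prob - baseline_mean,
                    stringsAsFactors = FALSE)
  attr(out, "baseline_mean") <- baseline_mean
  out
}

#' Univariate per-metric mixed models
#'
#' One single-metric mixed-effect logistic model per column (same
#' structure as the integrated model), reporting a likelihood-ratio
#' p-value for the metric against the intercept-plus-random-intercept
#' null. A likelihood-ratio test is used rather than a Wald statistic
#' because the separable trajectories this model is designed to detect
#' drive Wald standard errors to infinity (Hauck-Donner effect), making
#' Wald p-values uninformative exactly when the signal is strongest. The
#' integrated model's per-metric drop-one LRT p-values are attached for
#' comparison.
#'
#' @param scaled A [scale_metrics()] result.
#' @param labels A [label_timepoints()] result.
#' @param metric_cols Metric columns (default: the scaling record).
#' @return A data.frame with `metric`, `estimate`, `p` and an
#'   `"integrated_p"` attribute.
#' @export
univariate_significance <- function(scaled, labels, metric_cols = NULL) {
  if (is.null(metric_cols)) {
    rec <- attr(scaled, "scaling")
    metric_cols <- if (!is.null(rec)) rec$metric else
      setdiff(names(scaled), c("patient_id", "timepoint"))
  }
  data <- merge(scaled, labels, by = c("patient_id", "timepoint"), sort = FALSE)
  train <- data[data$eligible, , drop = FALSE]
  if (length(unique(train$label)) < 2L) {
    stop_model("training labels are single-class")
  }
  fit_terms <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fit_glmm(stats::as.formula(paste("label ~", rhs, "+ (1 | patient_id)")),
             train,
             stats::as.formula(paste("label ~", rhs)))
  }
  lrt_p <- function(full, reduced) {
    stat <- max(0, 2 * (as.numeric(stats::logLik(full$fit)) -
                          as.numeric(stats::logLik(reduced$fit))))
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  null_fit <- fit_terms(character(0))
  out <- data.frame(metric = metric_cols, estimate = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(metric_cols)) {
    m <- metric_cols[i]
    fitted <- fit_terms(m)
    cf <- if (fitted$glmm) lme4::fixef(fitted$fit) else stats::coef(fitted$fit)
    out$estimate[i] <- unname(cf[m])
    out$p[i] <- lrt_p(fitted, null_fit)
  }
  full <- fit_terms(metric_cols)
  attr(out, "integrated_p") <- stats::setNames(
    vapply(metric_cols,
           function(m) lrt_p(full, fit_terms(setdiff(metric_cols, m))),
           numeric(1)),
    metric_cols)
  out
}
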