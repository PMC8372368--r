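#' Kaplan-Meier product-limit estimator
#'
#' Median survival is the smallest observed time at which the survival
#' probability drops to 0.5 or below, and is reported as NA (undefined)
#' when the curve never crosses 0.5.
#'
#' @param time event/censoring times in weeks (>= 0).
#' @param event event indicator (1 = event, 0 = censored).
#' @return list with `curve` (data.frame time, n_risk, n_event, survival)
#'   and `median` (weeks or NA).
#' @export
kaplan_meier <- function(time, event) {
  if (any(time < 0)) stop("negative survival time")
  if (!length(time)) stop("need >= 1 observation")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, survival = fit$surv)
  med <- curve$time[curve$survival <= 0.5]
  list(curve = curve, median = if (length(med)) min(med) else NA_real_)
}

#' Log-rank test across K groups
#'
#' Standard (unweighted) log-rank; chi-square with K - 1 degrees of freedom.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with `statistic`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) stop("need >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling by default (Breslow by
#' flag). Errors on non-convergence or monotone likelihood (infinite
#' coefficient), with the offending covariate named.
#'
#' @param time,event survival data.
#' @param covariates data.frame of covariates (factors allowed; no constant
#'   columns).
#' @param ties `"efron"` or `"breslow"`.
#' @return list with `table` (data.frame term, coef, hr, se, p),
#'   `loglik`, `score_test` (score chi-square at beta = 0), `ties`, `fit`.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  const <- names(covariates)[vapply(covariates, function(x)
    length(unique(x[!is.na(x)])) < 2, TRUE)]
  if (length(const)) stop("constant covariate(s): ", paste(const, collapse = ", "))
  if (sum(event) < ncol(covariates))
    warning("fewer events than covariates; estimates may be unstable")
  dat <- data.frame(.time = time, .event = event, covariates,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged", conditionMessage(w)))
        stop("monotone likelihood / non-convergence: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    se = s$coefficients[, "se(coef)"],
                    p = s$coefficients[, "Pr(>|z|)"], row.names = NULL)
  list(table = tab, loglik = fit$loglik[2],
       score_test = unname(s$sctest["test"]), ties = ties, fit = fit)
}

#' Univariate Cox screen of clinical variables
#'
#' Fits one single-covariate Cox model per variable (listwise deletion of
#' missing values per variable) and keeps those with Wald p < alpha. For
#' multi-level factors the minimum coefficient p is used. Variables whose
#' fit fails are skipped with a warning.
#'
#' @param clinical a [clinical_table()] (or data.frame).
#' @param variables character vector of column names to screen.
#' @param endpoint one of `"os"`, `"efs"`, `"remdur"`.
#' @param alpha selection threshold (default 0.05).
#' @return data.frame with variable, p, selected.
#' @export
univariate_screen <- function(clinical, variables, endpoint = "os",
                              alpha = 0.05) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  rows <- lapply(variables, function(v) {
    ok <- !is.na(clinical[[v]]) & !is.na(clinical[[tcol]]) &
      !is.na(clinical[[ecol]])
    p <- tryCatch({
      fit <- cox_fit(clinical[[tcol]][ok], clinical[[ecol]][ok],
                     stats::setNames(data.frame(clinical[[v]][ok]), v))
      min(fit$table$p)
    }, error = function(e) {
      warning("screen skipped variable ", v, ": ", conditionMessage(e))
      NA_real_
    })
    data.frame(variable = v, p = p)
  })
  out <- do.call(rbind, c(rows, list(data.frame(variable = character(),
                                                p = numeric()))))
  out$selected <- !is.na(out$p) & out$p < alpha
  out
}

#' Multivariable Cox model of cluster membership
#'
#' Cox model with cluster indicators (reference = cluster 1) plus the
#' screened clinical variables; reports the hazard ratio and Wald p of each
#' cluster relative to cluster 1 after adjustment. Unassigned samples
#' (label 0) are dropped.
#'
#' @param clinical a [clinical_table()] whose rows align with `labels` by
#'   `sample_id`.
#' @param labels named cluster labels.
#' @param variables screened adjustment variables (possibly empty: the model
#'   reduces to the cluster-only fit).
#' @param endpoint `"os"`, `"efs"` or `"remdur"`.
#' @return a [cox_fit()] result; cluster terms named `cluster2`, `cluster3`, ...
#' @export
cluster_outcome_model <- function(clinical, labels, variables = character(),
                                  endpoint = "os") {
  idx <- match(clinical$sample_id, names(labels))
  cl <- labels[idx]
  keep <- !is.na(cl) & cl > 0
  if (length(unique(cl[keep])) < 2) stop("need >= 2 clusters represented")
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  covs <- data.frame(cluster = factor(cl[keep]))   # terms cluster2, cluster3, ...
  for (v in variables) covs[[v]] <- clinical[[v]][keep]
  ok <- stats::complete.cases(covs) & !is.na(clinical[[tcol]][keep]) &
    !is.na(clinical[[ecol]][keep])
  cox_fit(clinical[[tcol]][keep][ok], clinical[[ecol]][keep][ok],
          covs[ok, , drop = FALSE])
}
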