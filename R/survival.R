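validate_survival <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be positive and finite", call. = FALSE)
  }
  if (!all(event %in% c(0, 1))) {
    stop("event status must be 0 (alive/censored) or 1 (dead)", call. = FALSE)
  }
  invisible(NULL)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times (days).
#' @param event Death status, 0 censored / 1 dead.
#' @return Data frame with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (the product-limit estimate, which is 1
#'   at time 0 and non-increasing).
#' @export
kaplan_meier <- function(time, event) {
  validate_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Multi-group log-rank test
#'
#' Standard g-sample log-rank statistic with `g - 1` degrees of freedom and
#' an upper-tail chi-square p-value.
#'
#' @param time Positive follow-up times.
#' @param event Death status, 0/1.
#' @param group Group labels (at least two distinct values).
#' @return List with `chisq`, `df`, `p_value`, and the per-group
#'   observed/expected table `table`.
#' @export
logrank_test <- function(time, event, group) {
  validate_survival(time, event)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) {
    stop("log-rank test needs at least two groups", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  p <- stats::pchisq(fit$chisq, df = df, lower.tail = FALSE)
  list(chisq = unname(fit$chisq), df = df, p_value = p,
       table = data.frame(group = levels(droplevels(group)),
                          n = as.integer(fit$n),
                          observed = as.numeric(fit$obs),
                          expected = as.numeric(fit$exp)))
}

#' Cox proportional-hazards fit with Wald tests and C-index
#'
#' Maximizes the Cox partial likelihood (Efron handling of tied event
#' times) over the supplied covariates and reports per-covariate
#' coefficients, standard errors and two-sided Wald p-values, plus the
#' model's Harrell concordance index. Constant or collinear covariate
#' columns are rejected by name before fitting.
#'
#' @param features Numeric matrix or data frame of covariates (normally
#'   z-scored), patients in rows.
#' @param time Positive follow-up times.
#' @param event Death status, 0/1.
#' @param alpha Wald significance level for the `significant` flag
#'   (default 0.05).
#' @param ties Tie-handling method for the partial likelihood, `"efron"`
#'   (default) or `"breslow"`.
#' @return Object of class `cox_fit`: list with `coefficients` (data frame
#'   `covariate`, `coef`, `se`, `z`, `p_value`, `significant`), `cindex`,
#'   `n`, `n_events`, `converged`.
#' @export
cox_fit <- function(features, time, event, alpha = 0.05,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  validate_survival(time, event)
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(time))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1L) {
    stop("Cox regression needs at least one event", call. = FALSE)
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant covariate(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  qrX <- qr(scale(X))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("collinear covariate(s): %s", paste(dropped, collapse = ", ")),
         call. = FALSE)
  }
  dat <- data.frame(X, check.names = FALSE)
  fit_warning <- NULL
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ ., data = dat, ties = ties),
    warning = function(w) {
      fit_warning <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  co <- s$coefficients
  coefs <- data.frame(covariate = rownames(co),
                      coef = co[, "coef"],
                      se = co[, "se(coef)"],
                      z = co[, "z"],
                      p_value = co[, "Pr(>|z|)"],
                      stringsAsFactors = FALSE)
  coefs$significant <- coefs$p_value < alpha
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs,
                 cindex = unname(s$concordance["C"]),
                 n = fit$n, n_events = fit$nevent,
                 converged = is.null(fit_warning) ||
                   !grepl("converge", fit_warning, fixed = TRUE),
                 warning = fit_warning,
                 model = fit),
            class = "cox_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d, C-index = %.3f\n",
              x$n, x$n_events, x$cindex))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Cox fits for all patients and per patient group
#'
#' Fits the pooled all-patient model plus one model per patient group,
#' mirroring per-subgroup survival reports. Groups whose fit fails (too few
#' events, constant covariates within the group) are reported as `NULL`
#' with a warning.
#'
#' @param features Covariate matrix, patients in rows.
#' @param time,event Survival outcome.
#' @param groups Group labels aligned with the rows of `features`.
#' @return Named list of `cox_fit` objects: `all` plus `group_<g>`.
#' @export
cox_fit_by_group <- function(features, time, event, groups) {
  out <- list(all = cox_fit(features, time, event))
  for (g in sort(unique(groups))) {
    idx <- groups == g
    nm <- paste0("group_", g)
    out[[nm]] <- tryCatch(
      cox_fit(features[idx, , drop = FALSE], time[idx], event[idx]),
      error = function(e) {
        warning(sprintf("Cox fit for group %s failed: %s", g, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  }
  out
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs (the earlier observed time is an
#' event) in which the higher risk score belongs to the patient with the
#' shorter survival; tied scores credit 0.5.
#'
#' @param scores Numeric risk scores (higher = higher predicted hazard).
#' @param time Positive follow-up times.
#' @param event Death status, 0/1.
#' @return Scalar in \[0, 1\].
#' @export
concordance_index <- function(scores, time, event) {
  validate_survival(time, event)
  stopifnot(length(scores) == length(time))
  cfit <- survival::concordance(survival::Surv(time, event) ~ scores,
                                reverse = TRUE)
  n_pairs <- sum(cfit$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) {
    stop("no comparable pairs: concordance is undefined", call. = FALSE)
  }
  unname(cfit$concordance)
}
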