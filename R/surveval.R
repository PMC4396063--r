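#' Cohort survival container
#'
#' Validates the per-patient survival data used throughout the evaluation
#' functions.
#'
#' @param sample_id Patient identifiers.
#' @param time Follow-up in years (> 0).
#' @param event 1 = progression/death, 0 = censored.
#' @param endpoint "PFS" or "OS".
#' @param ipi Optional International Prognostic Index score (0-5, may be NA).
#' @return data.frame of class `cohort_survival`.
#' @export
cohort_survival <- function(sample_id, time, event, endpoint = "PFS",
                            ipi = NULL) {
  if (any(time <= 0)) stop("follow-up times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  out <- data.frame(sample_id = as.character(sample_id),
                    time = as.numeric(time), event = as.integer(event),
                    stringsAsFactors = FALSE)
  out$ipi <- if (is.null(ipi)) NA_integer_ else as.integer(ipi)
  attr(out, "endpoint") <- match.arg(endpoint, c("PFS", "OS"))
  class(out) <- c("cohort_survival", "data.frame")
  out
}

#' Cox proportional hazards assessment of a resistance score
#'
#' Fits a proportional-hazards model (Breslow ties by default) for a
#' numeric resistance index or a sensitive/resistant contrast, univariately
#' or adjusted for IPI, and reports the hazard ratio with Wald 95% CI.
#' For a numeric covariate the HR is reported per `unit_scale` units (e.g.
#' `unit_scale = 10` gives the HR per +10 index). For a factor covariate
#' with levels sensitive/intermediate/resistant the intermediate patients
#' are excluded and the HR contrasts resistant against sensitive.
#'
#' @param cohort A [cohort_survival()] data.frame.
#' @param covariate Numeric index or factor of categories, aligned with the
#'   cohort rows.
#' @param adjust_ipi Add IPI as a linear covariate on the 0-5 score
#'   (`ipi_factor = TRUE` codes it as a factor instead).
#' @param unit_scale Unit of increase for a numeric covariate.
#' @param ties "breslow" (default) or "efron".
#' @param ipi_factor Code IPI as a factor.
#' @return List of class `hazard_estimate`: `hr`, `ci_low`, `ci_high`,
#'   `p_value`, `scale_note`, `adjusted_for`, `n`, `n_event`, `fit`.
#' @export
fit_cox <- function(cohort, covariate, adjust_ipi = FALSE, unit_scale = 1,
                    ties = c("breslow", "efron"), ipi_factor = FALSE) {
  ties <- match.arg(ties)
  df <- as.data.frame(cohort)
  if (sum(df$event) < 10)
    warning("fewer than 10 events: hazard estimates will be unstable")
  if (is.factor(covariate) || is.character(covariate)) {
    cv <- as.character(covariate)
    keep <- cv %in% c("sensitive", "resistant")
    df <- df[keep, , drop = FALSE]
    df$x <- as.integer(cv[keep] == "resistant")
    note <- "resistant vs sensitive"
  } else {
    df$x <- as.numeric(covariate) / unit_scale
    note <- if (unit_scale == 1) "per +1 index"
            else sprintf("per +%g index", unit_scale)
  }
  adjusted <- character(0)
  fml <- survival::Surv(time, event) ~ x
  if (adjust_ipi) {
    if (all(is.na(df$ipi))) stop("IPI adjustment requested but IPI is missing")
    df$ipi_cov <- if (ipi_factor) factor(df$ipi) else as.numeric(df$ipi)
    fml <- survival::Surv(time, event) ~ x + ipi_cov
    adjusted <- if (ipi_factor) "IPI (factor)" else "IPI (linear)"
  }
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = ties),
    error = function(e) stop("Cox fit failed for covariate 'x': ",
                             conditionMessage(e)))
  if (!is.finite(fit$coefficients["x"]) ||
      abs(fit$coefficients["x"]) > 20)
    stop("monotone likelihood (perfect separation) for covariate 'x'")
  s <- summary(fit)
  structure(list(hr = unname(s$conf.int["x", "exp(coef)"]),
                 ci_low = unname(s$conf.int["x", "lower .95"]),
                 ci_high = unname(s$conf.int["x", "upper .95"]),
                 p_value = unname(s$coefficients["x", "Pr(>|z|)"]),
                 scale_note = note, adjusted_for = adjusted,
                 n = nrow(df), n_event = sum(df$event), fit = fit),
            class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, ...) {
  cat(sprintf("HR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s%s]\n",
              x$hr, x$ci_low, x$ci_high, x$p_value, x$scale_note,
              if (length(x$adjusted_for)) paste0("; adjusted for ",
                                                 paste(x$adjusted_for, collapse = ", "))
              else ""))
  invisible(x)
}

#' Kaplan-Meier curves per resistance category
#'
#' Product-limit survival estimates per category with event/at-risk tables.
#' Empty categories are omitted with a warning.
#'
#' @param cohort A [cohort_survival()] data.frame.
#' @param categories Factor of per-patient categories.
#' @return List with `table` (data.frame of group, time, n.risk, n.event,
#'   surv) and `fit` (the `survfit` object).
#' @export
km_curves <- function(cohort, categories) {
  df <- as.data.frame(cohort)
  if (!is.factor(categories)) categories <- factor(categories)
  empty <- levels(categories)[table(categories) == 0]
  if (length(empty) > 0) {
    warning("empty categories omitted: ", paste(empty, collapse = ", "))
    categories <- droplevels(categories)
  }
  df$grp <- categories
  fit <- survival::survfit(survival::Surv(time, event) ~ grp, data = df)
  strata <- if (is.null(fit$strata)) rep(levels(categories), length(fit$time))
            else rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  tab <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv,
                    stringsAsFactors = FALSE)
  list(table = tab, fit = fit)
}

#' Restricted cubic spline basis (Harrell's parameterisation)
#'
#' Truncated-power basis constrained to linearity beyond the boundary
#' knots, normalised by the squared span of the outer knots. With k knots
#' the basis has k - 1 columns (the first is the identity).
#'
#' @param x Numeric vector.
#' @param knots Knot locations (ascending).
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots")
  t1 <- knots[1]; tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- paste0("rcs", seq_len(k - 1))
  out
}

#' Nonlinear index-hazard relationship via restricted cubic splines
#'
#' Fits a Cox model on a restricted-cubic-spline expansion of a resistance
#' index (knots at the 0.05/0.35/0.65/0.95 quantiles for the default four
#' knots), optionally adjusted for IPI, and returns the log relative hazard
#' curve centred at the index median with pointwise 95% CI from the
#' coefficient covariance.
#'
#' @param cohort A [cohort_survival()] data.frame.
#' @param index Numeric resistance index per patient.
#' @param n_knots Number of knots (default 4).
#' @param adjust_ipi Adjust for the IPI score (linear).
#' @param grid_length Number of points of the returned curve.
#' @return List of class `rcs_cox`: `curve` (data.frame index, loghr, lo,
#'   hi), `knots`, `center`, `fit`.
#' @export
rcs_cox <- function(cohort, index, n_knots = 4, adjust_ipi = FALSE,
                    grid_length = 101) {
  df <- as.data.frame(cohort)
  if (length(unique(index)) < n_knots)
    stop("need at least as many distinct index values as knots")
  probs <- switch(as.character(n_knots),
                  "3" = c(0.1, 0.5, 0.9),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.5, 0.725, 0.95),
                  seq(0.05, 0.95, length.out = n_knots))
  knots <- unname(stats::quantile(index, probs, type = 7))
  if (anyDuplicated(knots)) stop("duplicated knots; try fewer knots")
  B <- rcs_basis(index, knots)
  dat <- data.frame(time = df$time, event = df$event)
  dat <- cbind(dat, B)
  terms <- colnames(B)
  if (adjust_ipi) {
    dat$ipi_cov <- as.numeric(df$ipi)
    terms <- c(terms, "ipi_cov")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (any(!is.finite(stats::coef(fit))))
    stop("singular spline basis; try fewer knots")
  center <- stats::median(index)
  grid <- seq(min(index), max(index), length.out = grid_length)
  Bg <- rcs_basis(grid, knots)
  B0 <- rcs_basis(center, knots)
  contrast <- sweep(Bg, 2, B0)
  beta <- stats::coef(fit)[colnames(B)]
  V <- stats::vcov(fit)[colnames(B), colnames(B)]
  loghr <- drop(contrast %*% beta)
  se <- sqrt(rowSums((contrast %*% V) * contrast))
  structure(list(curve = data.frame(index = grid, loghr = loghr,
                                    lo = loghr - 1.96 * se,
                                    hi = loghr + 1.96 * se),
                 knots = knots, center = center, fit = fit),
            class = "rcs_cox")
}

# Kaplan-Meier estimate of the censoring survivor function G(t) = P(C > t),
# returned as a left-continuous step-function evaluator for G(t-) and G(t)
.censoring_km <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  tt <- sf$time; ss <- sf$surv
  eval_at <- function(t, minus = FALSE) {
    sapply(t, function(ti) {
      idx <- if (minus) which(tt < ti) else which(tt <= ti)
      if (length(idx) == 0) 1 else ss[max(idx)]
    })
  }
  eval_at
}

#' IPCW time-dependent ROC for a censored outcome
#'
#' Cumulative-case / dynamic-control AUC(t): cases are patients with an
#' event by t, controls those event-free beyond t, weighted by the inverse
#' Kaplan-Meier censoring probabilities (weight `1/G(T_i-)` for a case with
#' event at `T_i`, `1/G(t)` for a control). Confidence intervals come from
#' the influence-function (iid) representation with the censoring weights
#' treated as fixed; with a second marker the paired AUC difference is
#' tested on the same representation.
#'
#' @param cohort A [cohort_survival()] data.frame.
#' @param marker Numeric risk marker (higher = more resistant / higher risk).
#' @param eval_times Times at which AUC(t) is computed (before the last
#'   observed time).
#' @param marker2 Optional competing marker measured on the same patients.
#' @return List of class `time_roc`: `auc` (data.frame time, auc, se, lo,
#'   hi, n_case, n_control; rows with no cases or controls carry NA and are
#'   flagged), and `comparison` (data.frame time, diff, se, lo, hi, p) when
#'   `marker2` is supplied.
#' @export
time_roc <- function(cohort, marker, eval_times, marker2 = NULL) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  if (any(eval_times >= max(df$time)))
    stop("eval_times must lie before the last observed time")
  G <- .censoring_km(df$time, df$event)

  auc_one <- function(m, t) {
    case <- df$time <= t & df$event == 1
    ctrl <- df$time > t
    if (!any(case) || !any(ctrl))
      return(list(auc = NA_real_, se = NA_real_, infl = rep(NA_real_, n),
                  n_case = sum(case), n_ctrl = sum(ctrl)))
    wc <- ifelse(case, 1 / G(df$time, minus = TRUE), 0)
    wd <- ifelse(ctrl, 1 / G(t), 0)
    W1 <- sum(wc); W0 <- sum(wd)
    ci <- which(case); di <- which(ctrl)
    cmp <- outer(m[ci], m[di], function(a, b) (a > b) + 0.5 * (a == b))
    num <- drop(wc[ci] %*% cmp %*% wd[di])
    theta <- num / (W1 * W0)
    # hajek-projection influence values (weights fixed)
    v10 <- drop(cmp %*% wd[di]) / W0          # per case
    v01 <- drop(wc[ci] %*% cmp) / W1          # per control
    infl <- numeric(n)
    infl[ci] <- wc[ci] * (v10 - theta) * n / W1
    infl[di] <- wd[di] * (v01 - theta) * n / W0
    se <- sqrt(sum(infl^2)) / n
    list(auc = theta, se = se, infl = infl,
         n_case = length(ci), n_ctrl = length(di))
  }

  rows <- lapply(eval_times, function(t) auc_one(marker, t))
  auc <- data.frame(time = eval_times,
                    auc = sapply(rows, `[[`, "auc"),
                    se = sapply(rows, `[[`, "se"),
                    n_case = sapply(rows, `[[`, "n_case"),
                    n_control = sapply(rows, `[[`, "n_ctrl"))
  auc$lo <- pmax(auc$auc - 1.96 * auc$se, 0)
  auc$hi <- pmin(auc$auc + 1.96 * auc$se, 1)
  auc$undefined <- !is.finite(auc$auc)
  out <- list(auc = auc, comparison = NULL)
  if (!is.null(marker2)) {
    rows2 <- lapply(eval_times, function(t) auc_one(marker2, t))
    cmp <- lapply(seq_along(eval_times), function(i) {
      d <- rows[[i]]$auc - rows2[[i]]$auc
      dd <- rows[[i]]$infl - rows2[[i]]$infl
      se <- sqrt(sum(dd^2)) / n
      c(diff = d, se = se)
    })
    cm <- as.data.frame(do.call(rbind, cmp))
    cm$time <- eval_times
    cm$lo <- cm$diff - 1.96 * cm$se
    cm$hi <- cm$diff + 1.96 * cm$se
    cm$p <- 2 * stats::pnorm(-abs(cm$diff / cm$se))
    out$comparison <- cm[, c("time", "diff", "se", "lo", "hi", "p")]
  }
  structure(out, class = "time_roc")
}

#' @export
print.time_roc <- function(x, ...) {
  cat("time-dependent ROC (IPCW, cumulative/dynamic):\n")
  print(format(x$auc[, c("time", "auc", "lo", "hi")], digits = 3),
        row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("paired AUC difference:\n")
    print(format(x$comparison, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' Likelihood-ratio test for cohort-origin effect
#'
#' Compares Cox models with and without cohort indicator(s), optionally on
#' top of an adjustment covariate, to check that merged cohorts are
#' homogeneous.
#'
#' @param cohort A [cohort_survival()] data.frame for the merged cohorts.
#' @param origin Factor of cohort origin per patient (>= 2 levels).
#' @param covariate Optional numeric adjustment covariate in both models.
#' @return List: `p_value`, `statistic`, `df`.
#' @export
cohort_homogeneity_test <- function(cohort, origin, covariate = NULL) {
  df <- as.data.frame(cohort)
  origin <- factor(origin)
  if (nlevels(origin) < 2) stop("need at least 2 cohorts")
  df$origin <- origin
  if (is.null(covariate)) {
    f0 <- survival::coxph(survival::Surv(time, event) ~ 1, data = df)
    f1 <- survival::coxph(survival::Surv(time, event) ~ origin, data = df)
    ll0 <- f0$loglik[1]
  } else {
    df$x <- as.numeric(covariate)
    f0 <- survival::coxph(survival::Surv(time, event) ~ x, data = df)
    f1 <- survival::coxph(survival::Surv(time, event) ~ x + origin, data = df)
    ll0 <- f0$loglik[2]
  }
  stat <- 2 * (f1$loglik[2] - ll0)
  dof <- nlevels(origin) - 1
  list(p_value = stats::pchisq(stat, dof, lower.tail = FALSE),
       statistic = stat, df = dof)
}
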