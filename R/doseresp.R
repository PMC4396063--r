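#' Dose-response plate for one cell line and drug
#'
#' Container for raw absorbance measurements of a viability screen plate:
#' one cell line exposed to a two-fold dilution series of one drug, with
#' untreated control wells, read at drug addition (0 h) and after a fixed
#' exposure (48 h by default).
#'
#' @param cell_line_id,drug_id Identifiers.
#' @param doses Numeric vector of concentrations (ug/ml), strictly decreasing
#'   by a constant ratio (default two-fold, 18 levels).
#' @param absorbance0,absorbance48 Replicate x dose matrices of optical
#'   density at 0 h and after `exposure_hours`.
#' @param control0,control48 Replicate vectors for untreated wells.
#' @param blank Scalar background OD subtracted from every well.
#' @param exposure_hours Drug exposure time in hours.
#' @param dilution_ratio Expected ratio between consecutive doses.
#' @return An object of class `dose_response_plate`.
#' @export
dose_response_plate <- function(cell_line_id, drug_id, doses,
                                absorbance0, absorbance48,
                                control0, control48,
                                blank = 0, exposure_hours = 48,
                                dilution_ratio = 2) {
  absorbance0 <- as.matrix(absorbance0)
  absorbance48 <- as.matrix(absorbance48)
  if (!identical(dim(absorbance0), dim(absorbance48)))
    stop("absorbance matrices must share dimensions")
  if (ncol(absorbance0) != length(doses))
    stop("number of dose columns must match length(doses)")
  if (length(control0) != length(control48))
    stop("control vectors must share length")
  if (any(doses <= 0)) stop("doses must be positive")
  if (length(doses) > 1) {
    ratios <- doses[-length(doses)] / doses[-1]
    if (any(diff(doses) >= 0) ||
        any(abs(ratios / dilution_ratio - 1) > 1e-6))
      stop("doses must be strictly decreasing by the stated dilution ratio")
  }
  if (any(absorbance0 < 0, na.rm = TRUE) || any(absorbance48 < 0, na.rm = TRUE) ||
      any(control0 < 0, na.rm = TRUE) || any(control48 < 0, na.rm = TRUE))
    stop("absorbances must be non-negative")
  if (exposure_hours <= 0) stop("exposure_hours must be positive")
  structure(list(cell_line_id = cell_line_id, drug_id = drug_id,
                 doses = as.numeric(doses),
                 absorbance0 = absorbance0, absorbance48 = absorbance48,
                 control0 = as.numeric(control0),
                 control48 = as.numeric(control48),
                 blank = blank, exposure_hours = exposure_hours),
            class = "dose_response_plate")
}

#' @export
print.dose_response_plate <- function(x, ...) {
  cat(sprintf("dose_response_plate: %s x %s; %d doses (%.3g-%.3g ug/ml), %d replicates\n",
              x$cell_line_id, x$drug_id, length(x$doses),
              min(x$doses), max(x$doses), nrow(x$absorbance0)))
  invisible(x)
}

#' Read dose-response plates from a long-format CSV
#'
#' Expects columns cell_line, drug, dose_ug_ml, replicate, time_h,
#' absorbance and optionally is_border. Rows with `dose_ug_ml == 0` are
#' untreated control wells; border wells (`is_border` true) are dropped
#' before analysis.
#'
#' @param path CSV file path.
#' @param blank Background OD applied to every plate.
#' @param exposure_hours Exposure duration matching the later timepoint.
#' @return A list of [dose_response_plate] objects, one per
#'   cell line x drug combination.
#' @export
read_plates <- function(path, blank = 0, exposure_hours = 48) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "dose_ug_ml", "replicate", "time_h", "absorbance")
  if (!all(need %in% names(df)))
    stop("plate file must contain columns: ", paste(need, collapse = ", "))
  if ("is_border" %in% names(df)) df <- df[!as.logical(df$is_border), ]
  split_keys <- interaction(df$cell_line, df$drug, drop = TRUE)
  lapply(split(df, split_keys), function(d) {
    doses <- sort(unique(d$dose_ug_ml[d$dose_ug_ml > 0]), decreasing = TRUE)
    reps <- sort(unique(d$replicate))
    grab <- function(time, dose_set) {
      sapply(dose_set, function(dd) {
        sapply(reps, function(r) {
          v <- d$absorbance[d$dose_ug_ml == dd & d$replicate == r & d$time_h == time]
          if (length(v) == 0) NA_real_ else v[1]
        })
      })
    }
    a0 <- matrix(grab(0, doses), nrow = length(reps))
    a48 <- matrix(grab(max(d$time_h), doses), nrow = length(reps))
    c0 <- as.numeric(grab(0, 0))
    c48 <- as.numeric(grab(max(d$time_h), 0))
    dose_response_plate(d$cell_line[1], d$drug[1], doses, a0, a48,
                        c0[!is.na(c0)], c48[!is.na(c48)],
                        blank = blank, exposure_hours = exposure_hours)
  })
}

#' Estimate per-dose growth rates from a plate
#'
#' Under exponential growth the per-well growth rate is
#' `(ln(A48 - blank) - ln(A0 - blank)) / exposure_hours`. Per dose the rate
#' is the mean over replicate wells; wells whose blank-corrected OD is not
#' positive at either timepoint are treated as missing. The untreated rate
#' `g0` is computed identically from the control wells.
#'
#' @param plate A [dose_response_plate].
#' @return An object of class `growth_rate_profile` with elements `g0`,
#'   `g0_se`, `g_at_dose`, `se_at_dose` and `doses`. Rates are per hour.
#' @export
estimate_growth_rates <- function(plate) {
  h <- plate$exposure_hours
  rate_well <- function(a0, a48) {
    x0 <- a0 - plate$blank
    x48 <- a48 - plate$blank
    # non-positive corrected ODs are flagged missing, so the NaN from the
    # log is expected and silenced
    out <- suppressWarnings((log(x48) - log(x0)) / h)
    out[!is.finite(out) | x0 <= 0 | x48 <= 0] <- NA_real_
    out
  }
  g_rep <- rate_well(plate$absorbance0, plate$absorbance48)
  g <- colMeans(g_rep, na.rm = TRUE)
  g[!is.finite(g)] <- NA_real_
  nrep <- colSums(!is.na(g_rep))
  se <- apply(g_rep, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(nrep, 1))
  se[nrep < 2] <- NA_real_
  g0_rep <- rate_well(plate$control0, plate$control48)
  if (all(is.na(g0_rep))) stop("no usable control wells after blank subtraction")
  g0 <- mean(g0_rep, na.rm = TRUE)
  if (!is.finite(g0) || g0 <= 0) stop("untreated culture not growing")
  n0 <- sum(!is.na(g0_rep))
  g0_se <- if (n0 >= 2) stats::sd(g0_rep, na.rm = TRUE) / sqrt(n0) else NA_real_
  structure(list(g0 = g0, g0_se = g0_se, g_at_dose = unname(g),
                 se_at_dose = unname(se), doses = plate$doses),
            class = "growth_rate_profile")
}

# Four-parameter logistic in log2 dose; descending from top to bottom for
# slope > 0. slope is per log2-dose unit.
four_pl <- function(x, top, bottom, log2_ec50, slope) {
  bottom + (top - bottom) / (1 + 2^(slope * (x - log2_ec50)))
}

#' Fit a four-parameter logistic dose-response curve to relative growth
#'
#' Relative growth at each dose is `R(d) = 100 * g(d) / g0` (percent of the
#' untreated growth rate). A four-parameter logistic in log2 dose is fitted
#' by weighted least squares (weights = inverse squared standard error when
#' available, else uniform), over a deterministic multistart grid:
#' slope in {0.5, 1, 2, 4} and log2 EC50 at the quartiles of the dose span.
#' Ties on the residual sum of squares keep the start with the smallest
#' slope.
#'
#' @param profile A `growth_rate_profile` from [estimate_growth_rates()].
#' @param doses Optional dose vector; defaults to `profile$doses`.
#' @return Object of class `dose_response_curve` with fields `top`, `bottom`,
#'   `log2_ec50`, `slope` (per log2 unit), `dose_span` (log2 of min and max
#'   dose) and `relative_growth` (the input points).
#' @export
fit_dose_response <- function(profile, doses = profile$doses) {
  keep <- is.finite(profile$g_at_dose)
  if (sum(keep) < 5) stop("need at least 5 non-missing doses to fit a curve")
  R <- 100 * profile$g_at_dose[keep] / profile$g0
  x <- log2(doses[keep])
  se <- profile$se_at_dose[keep]
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / (100 * se / profile$g0)^2
       else rep(1, length(R))
  span <- range(log2(doses))
  if (diff(range(R)) < 1e-8 * max(1, abs(mean(R)))) {
    # degenerate flat data: constant curve
    return(structure(list(top = mean(R), bottom = mean(R),
                          log2_ec50 = mean(span), slope = 0,
                          dose_span = span,
                          relative_growth = data.frame(log2_dose = x, R = R)),
                     class = "dose_response_curve"))
  }
  dat <- data.frame(x = x, R = R)
  starts <- expand.grid(slope = c(0.5, 1, 2, 4),
                        e = span[1] + diff(span) * c(0.25, 0.5, 0.75))
  starts <- starts[order(starts$slope, starts$e), ]
  best <- NULL
  best_sse <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        R ~ four_pl(x, top, bottom, e, s), data = dat, weights = w,
        start = list(top = max(R), bottom = min(R),
                     e = starts$e[i], s = starts$slope[i]),
        lower = c(top = -1000, bottom = -1000, e = span[1] - 8, s = 1e-4),
        upper = c(top = 1000, bottom = 1000, e = span[2] + 8, s = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(w * stats::residuals(fit)^2)
    if (sse < best_sse * (1 - 1e-10)) {
      best_sse <- sse
      best <- stats::coef(fit)
    }
  }
  if (is.null(best))
    stop(sprintf("dose-response fit failed to converge at all starts (best SSE %.3g)",
                 best_sse))
  structure(list(top = unname(best["top"]), bottom = unname(best["bottom"]),
                 log2_ec50 = unname(best["e"]), slope = unname(best["s"]),
                 dose_span = span,
                 relative_growth = data.frame(log2_dose = x, R = R)),
            class = "dose_response_curve")
}

#' Evaluate a fitted dose-response curve
#'
#' @param object A `dose_response_curve`.
#' @param log2_dose Numeric vector of log2 doses.
#' @param ... Ignored.
#' @return Relative growth (percent of untreated) at each log2 dose.
#' @export
predict.dose_response_curve <- function(object, log2_dose, ...) {
  four_pl(log2_dose, object$top, object$bottom, object$log2_ec50, object$slope)
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("dose_response_curve: top %.1f, bottom %.1f, log2 EC50 %.2f, slope %.2f\n",
              x$top, x$bottom, x$log2_ec50, x$slope))
  invisible(x)
}

#' Area under the positive part of a dose-response curve (AUC0)
#'
#' Integrates `max(R(x), 0)` over the log2-dose span of the experiment by
#' adaptive quadrature (relative tolerance 1e-8), splitting at the analytic
#' zero crossing of the logistic when the curve changes sign. Larger values
#' mean greater resistance. Units are percent x log2-dose.
#'
#' @param curve A `dose_response_curve`.
#' @return Object of class `resistance_summary` with `auc0`; bootstrap
#'   fields are `NA` (see [bootstrap_auc0()]).
#' @export
auc0 <- function(curve) {
  span <- curve$dose_span
  if (!is.finite(diff(span)) || diff(span) <= 0)
    stop("degenerate dose span")
  val <- .auc0_value(curve)
  structure(list(auc0 = val, ci_low = NA_real_, ci_high = NA_real_,
                 n_boot = 0L, seed = NA_integer_),
            class = "resistance_summary")
}

.auc0_value <- function(curve) {
  span <- curve$dose_span
  if (!is.null(curve$slope) && !is.null(curve$top) &&
      (curve$slope == 0 || isTRUE(curve$top == curve$bottom)))
    return(max(curve$top, 0) * diff(span))
  f <- function(x) stats::predict(curve, x)
  pos <- function(x) pmax(f(x), 0)
  # split the integral at sign changes so each piece is smooth
  grid <- seq(span[1], span[2], length.out = 1025L)
  fg <- f(grid)
  cuts <- span[1]
  for (i in seq_len(length(grid) - 1)) {
    if (is.finite(fg[i]) && is.finite(fg[i + 1]) &&
        sign(fg[i]) * sign(fg[i + 1]) < 0) {
      root <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      cuts <- c(cuts, root)
    }
  }
  cuts <- c(cuts, span[2])
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    if (cuts[i + 1] - cuts[i] < 1e-14) next
    piece <- stats::integrate(pos, cuts[i], cuts[i + 1],
                              rel.tol = 1e-8, subdivisions = 500L)
    total <- total + piece$value
  }
  total
}

#' @export
print.resistance_summary <- function(x, ...) {
  if (x$n_boot > 0)
    cat(sprintf("AUC0 = %.1f (95%% CI %.1f-%.1f, %d bootstrap replicates)\n",
                x$auc0, x$ci_low, x$ci_high, x$n_boot))
  else cat(sprintf("AUC0 = %.1f\n", x$auc0))
  invisible(x)
}

#' Bootstrap confidence interval for AUC0
#'
#' Resamples replicate wells with replacement within each dose (and within
#' the controls), re-runs the growth-rate estimation, curve fit and AUC0
#' quadrature, and reports the percentile 2.5/97.5 interval of the
#' successful replicates.
#'
#' @param plate A [dose_response_plate] with at least 2 replicates per dose.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return A `resistance_summary` whose point estimate comes from the
#'   original plate.
#' @export
bootstrap_auc0 <- function(plate, n_boot = 200, seed = 1) {
  if (nrow(plate$absorbance0) < 2) stop("need at least 2 replicates per dose")
  point <- .auc0_value(fit_dose_response(estimate_growth_rates(plate)))
  set.seed(seed)
  nrep <- nrow(plate$absorbance0)
  nctl <- length(plate$control0)
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- matrix(sample.int(nrep, nrep * ncol(plate$absorbance0), replace = TRUE),
                  nrow = nrep)
    a0 <- plate$absorbance0; a48 <- plate$absorbance48
    for (j in seq_len(ncol(a0))) {
      a0[, j] <- plate$absorbance0[idx[, j], j]
      a48[, j] <- plate$absorbance48[idx[, j], j]
    }
    ci <- sample.int(nctl, nctl, replace = TRUE)
    bp <- plate
    bp$absorbance0 <- a0; bp$absorbance48 <- a48
    bp$control0 <- plate$control0[ci]; bp$control48 <- plate$control48[ci]
    vals[b] <- tryCatch(
      .auc0_value(fit_dose_response(estimate_growth_rates(bp))),
      error = function(e) NA_real_)
  }
  ok <- vals[is.finite(vals)]
  if (length(ok) < n_boot / 2)
    stop(sprintf("bootstrap failed in %.0f%% of replicates",
                 100 * (1 - length(ok) / n_boot)))
  ci <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(list(auc0 = point, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "resistance_summary")
}

#' Summarise a set of plates into an AUC0 table
#'
#' Convenience wrapper running growth-rate estimation, curve fitting and
#' AUC0 (optionally bootstrapped) over a list of plates.
#'
#' @param plates List of [dose_response_plate] objects.
#' @param n_boot Bootstrap replicates per plate (0 skips the bootstrap).
#' @param seed Base seed; plate `i` uses `seed + i`.
#' @return A data.frame with cell_line, drug, auc0, ci_low, ci_high.
#' @export
auc0_table <- function(plates, n_boot = 0, seed = 1) {
  rows <- lapply(seq_along(plates), function(i) {
    p <- plates[[i]]
    s <- if (n_boot > 0) bootstrap_auc0(p, n_boot = n_boot, seed = seed + i)
         else auc0(fit_dose_response(estimate_growth_rates(p)))
    data.frame(cell_line = p$cell_line_id, drug = p$drug_id,
               auc0 = s$auc0, ci_low = s$ci_low, ci_high = s$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
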