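#' Ground truth for the synthetic study
#'
#' Fixes everything the generators need: the causal resistance genes and
#' their weights per drug, the disease-group shift/scale, the growth-rate
#' range and dose design of the plate forward model, the mapping from
#' latent resistance to drug potency (EC50), and the clinical linkage
#' (log-hazard per SD of true combined resistance, IPI effect, censoring).
#' Given a seed, all generated data are a pure function of this object.
#'
#' @param n_genes Number of genes on the synthetic platform.
#' @param n_causal Causal genes per drug (disjoint blocks).
#' @param drugs Drug identifiers.
#' @param weight Effect weight of each causal gene on latent resistance.
#' @param causal_cor Equicorrelation of each drug's causal genes: the
#'   working hypothesis is that resistance is driven by a coordinated
#'   expression program, so the causal genes of a drug form a co-expressed
#'   pathway module rather than independent markers.
#' @param latent_noise_sd Noise sd on latent resistance; the default gives
#'   a 3:1 effect-to-noise ratio (effect sd is
#'   `sqrt(n_causal + n_causal * (n_causal - 1) * causal_cor) * weight`).
#' @param disease_offset_sd Per-gene expression offset sd of the second
#'   disease group.
#' @param disease_var_ratio Expression variance ratio of the second group.
#' @param g0_range Untreated growth-rate range (per hour).
#' @param max_dose,n_doses,dilution_ratio Dose design (ug/ml, two-fold).
#' @param curve_top,curve_bottom,curve_slope True 4PL shape (percent
#'   relative growth; slope per log2 dose).
#' @param ec50_center,ec50_spread Map standardised latent resistance z to
#'   `log2 EC50 = ec50_center + ec50_spread * z` (default centre = middle
#'   of the dose span).
#' @param od_cv Multiplicative log-normal coefficient of variation of the
#'   absorbance measurements (0.05 = 5%; 0 for a noise-free plate).
#' @param seed_od,blank Seeding-level OD and plate background.
#' @param hazard_coefficient Log-hazard per SD of true combined resistance.
#' @param ipi_coefficient Log-hazard per IPI point.
#' @param baseline_hazard Exponential baseline hazard (per year).
#' @param censoring_rate Target fraction censored (independent uniform).
#' @param seed Seed for the random pieces of the truth (disease offsets).
#' @return List of class `simulation_truth`.
#' @export
simulation_truth <- function(n_genes = 5000, n_causal = 10,
                             drugs = c("C", "H", "O"),
                             weight = 1,
                             causal_cor = 0.5,
                             latent_noise_sd = sqrt(n_causal +
                               n_causal * (n_causal - 1) * causal_cor) *
                               weight / 3,
                             disease_offset_sd = 0.5,
                             disease_var_ratio = 1.3,
                             g0_range = c(0.02, 0.04),
                             max_dose = 20, n_doses = 18, dilution_ratio = 2,
                             curve_top = 100, curve_bottom = -20,
                             curve_slope = 1,
                             ec50_center = NULL, ec50_spread = 1.2,
                             od_cv = 0.05, seed_od = 0.3, blank = 0.05,
                             hazard_coefficient = log(2),
                             ipi_coefficient = 0.3,
                             baseline_hazard = log(2) / 3,
                             censoring_rate = 0.2,
                             seed = 1) {
  if (n_causal * length(drugs) > n_genes)
    stop("causal genes exceed n_genes")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must lie in [0, 1)")
  genes <- sprintf("g%05d", seq_len(n_genes))
  causal <- list()
  for (i in seq_along(drugs)) {
    idx <- ((i - 1) * n_causal + 1):(i * n_causal)
    w <- rep(weight, n_causal)
    names(w) <- genes[idx]
    causal[[drugs[i]]] <- w
  }
  doses <- max_dose * dilution_ratio^(-(seq_len(n_doses) - 1))
  span <- range(log2(doses))
  if (is.null(ec50_center)) ec50_center <- mean(span)
  set.seed(seed)
  structure(list(n_genes = n_genes, genes = genes, drugs = drugs,
                 causal_genes = causal, causal_cor = causal_cor,
                 disease_shift = list(offset = stats::rnorm(n_genes, 0,
                                                            disease_offset_sd),
                                      var_ratio = disease_var_ratio),
                 latent_noise_sd = latent_noise_sd,
                 g0_range = g0_range, doses = doses,
                 curve = list(top = curve_top, bottom = curve_bottom,
                              slope = curve_slope),
                 ec50_center = ec50_center, ec50_spread = ec50_spread,
                 od_cv = od_cv, seed_od = seed_od, blank = blank,
                 exposure_hours = 48,
                 hazard_coefficient = hazard_coefficient,
                 ipi_coefficient = ipi_coefficient,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 seed = seed),
            class = "simulation_truth")
}

# baseline biological expression: unit-variance normal everywhere, with each
# drug's causal genes forming an equicorrelated co-expression module
.draw_expression <- function(truth, ids) {
  n <- length(ids)
  X <- matrix(stats::rnorm(truth$n_genes * n), truth$n_genes, n,
              dimnames = list(truth$genes, ids))
  rho <- truth$causal_cor
  if (rho > 0) {
    for (w in truth$causal_genes) {
      u <- stats::rnorm(n)
      X[names(w), ] <- sqrt(rho) * matrix(u, length(w), n, byrow = TRUE) +
        sqrt(1 - rho) * X[names(w), ]
    }
  }
  X
}

# latent resistance of samples for one drug: X is genes x samples (biological
# N(0,1)-scale values), returns named vector
.latent_resistance <- function(truth, X, drug, noise_sd) {
  w <- truth$causal_genes[[drug]]
  drop(crossprod(X[names(w), , drop = FALSE], w)) +
    stats::rnorm(ncol(X), 0, noise_sd)
}

# forward plate model: exponential growth at rates suppressed by the true
# 4PL curve, multiplicative log-normal OD noise
.simulate_plate <- function(truth, cell_line, drug, log2_ec50, g0,
                            n_replicates = 3) {
  cv <- truth$od_cv
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  noise <- function(k) if (sdlog > 0) stats::rlnorm(k, -sdlog^2 / 2, sdlog)
                       else rep(1, k)
  doses <- truth$doses
  curve <- structure(list(top = truth$curve$top, bottom = truth$curve$bottom,
                          log2_ec50 = log2_ec50, slope = truth$curve$slope,
                          dose_span = range(log2(doses))),
                     class = "dose_response_curve")
  g <- g0 * stats::predict(curve, log2(doses)) / 100
  h <- truth$exposure_hours
  nd <- length(doses)
  a0_true <- truth$seed_od
  A0 <- matrix(a0_true * noise(n_replicates * nd), n_replicates, nd)
  A48 <- matrix(a0_true * rep(exp(g * h), each = n_replicates) *
                  noise(n_replicates * nd), n_replicates, nd)
  c0 <- a0_true * noise(n_replicates)
  c48 <- a0_true * exp(g0 * h) * noise(n_replicates)
  dose_response_plate(cell_line, drug, doses,
                      A0 + truth$blank, A48 + truth$blank,
                      c0 + truth$blank, c48 + truth$blank,
                      blank = truth$blank,
                      exposure_hours = h)
}

#' Simulate a two-disease cell-line panel with plates and true AUC0
#'
#' Generates baseline expression for DLBCL-like and MM-like cell lines
#' (standard-normal log2 values; the second group carries a per-gene offset
#' and a variance ratio), latent per-drug resistance as a weighted sum of
#' the causal genes plus noise, a true 4PL dose-response curve per cell
#' line and drug whose log2 EC50 increases with standardised latent
#' resistance, the exact AUC0 of that true curve, and raw absorbance plates
#' from the exponential-growth forward model. Running the dose-response
#' module on the plates recovers the true AUC0 ordering.
#'
#' @param n_dlbcl,n_mm Cell lines per disease group.
#' @param truth A [simulation_truth()].
#' @param seed Integer seed; identical seeds give identical output.
#' @param plates Set `FALSE` to skip plate generation (expression and true
#'   AUC0 only).
#' @return List: `panel` (an [expression_panel], collapsed), `auc0_table`
#'   (data.frame cell_line, drug, disease_group, latent, true_auc0,
#'   log2_ec50, g0), `plates` (named list, `cell_line.drug`), `truth`.
#' @export
simulate_cell_panel <- function(n_dlbcl = 12, n_mm = 12, truth = simulation_truth(),
                                seed = 1, plates = TRUE) {
  set.seed(seed)
  n <- n_dlbcl + n_mm
  ids <- c(sprintf("DLBCL-%02d", seq_len(n_dlbcl)),
           sprintf("MM-%02d", seq_len(n_mm)))
  group <- rep(c("DLBCL", "MM"), c(n_dlbcl, n_mm))
  X <- .draw_expression(truth, ids)
  mm <- group == "MM"
  X[, mm] <- X[, mm] * sqrt(truth$disease_shift$var_ratio) +
    truth$disease_shift$offset
  rows <- list()
  plate_list <- list()
  g0 <- stats::runif(n, truth$g0_range[1], truth$g0_range[2])
  for (drug in truth$drugs) {
    r <- .latent_resistance(truth, X, drug, truth$latent_noise_sd)
    z <- (r - mean(r)) / stats::sd(r)
    ec50 <- truth$ec50_center + truth$ec50_spread * z
    true_auc0 <- sapply(ec50, function(e) {
      .auc0_value(structure(list(top = truth$curve$top,
                                 bottom = truth$curve$bottom,
                                 log2_ec50 = e, slope = truth$curve$slope,
                                 dose_span = range(log2(truth$doses))),
                            class = "dose_response_curve"))
    })
    rows[[drug]] <- data.frame(cell_line = ids, drug = drug,
                               disease_group = group, latent = r,
                               true_auc0 = true_auc0, log2_ec50 = ec50,
                               g0 = g0, stringsAsFactors = FALSE)
    if (plates) {
      for (i in seq_len(n)) {
        plate_list[[paste(ids[i], drug, sep = ".")]] <-
          .simulate_plate(truth, ids[i], drug, ec50[i], g0[i])
      }
    }
  }
  panel <- expression_panel(X, group, id = "cell_panel", collapsed = TRUE)
  list(panel = panel, auc0_table = do.call(rbind, rows),
       plates = plate_list, truth = truth)
}

# calibrate a uniform censoring horizon so the expected censored fraction
# matches the target, then draw censoring times
.apply_censoring <- function(T, rate) {
  n <- length(T)
  if (rate == 0)
    return(list(time = T, event = rep(1L, n)))
  f <- function(u) mean(pmin(T / u, 1)) - rate
  u <- stats::uniroot(f, c(min(T) * 1e-6, max(T) * 1e6))$root
  C <- stats::runif(n, 0, u)
  list(time = pmin(T, C), event = as.integer(T <= C))
}

#' Simulate a patient cohort linked to the true resistance genes
#'
#' Patient expression is drawn on the same gene space as the cell panel
#' (with a cohort-level scale difference so that harmonisation matters);
#' survival times are exponential with log-hazard
#' `gamma * z + ipi_coefficient * (IPI - mean IPI)` where `z` is the
#' standardised true combined resistance (mean of the per-drug standardised
#' latent resistances); censoring is independent and uniform, calibrated
#' to the target rate.
#'
#' @param n_patients Cohort size.
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param gamma Log-hazard per SD of true combined resistance (defaults to
#'   `truth$hazard_coefficient`; 0 gives a null cohort).
#' @param cohort_id Panel/cohort identifier.
#' @param scale_factor Cohort-level expression scale relative to the cell
#'   panel's biological scale.
#' @return List: `panel` (an [expression_panel]), `survival` (a
#'   [cohort_survival()]), `true_combined` (the standardised truth z).
#' @export
simulate_cohort <- function(n_patients, truth = simulation_truth(), seed = 1,
                            gamma = truth$hazard_coefficient,
                            cohort_id = "cohort", scale_factor = 1.4) {
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_patients))
  Xraw <- .draw_expression(truth, ids)
  zs <- sapply(truth$drugs, function(d) {
    r <- .latent_resistance(truth, Xraw, d, truth$latent_noise_sd)
    (r - mean(r)) / stats::sd(r)
  })
  comb <- rowMeans(zs)
  z <- (comb - mean(comb)) / stats::sd(comb)
  ipi <- sample(0:5, n_patients, replace = TRUE,
                prob = c(0.10, 0.20, 0.25, 0.20, 0.15, 0.10))
  haz <- truth$baseline_hazard *
    exp(gamma * z + truth$ipi_coefficient * (ipi - mean(ipi)))
  T <- stats::rexp(n_patients, rate = haz)
  cens <- .apply_censoring(T, truth$censoring_rate)
  panel <- expression_panel(Xraw * scale_factor,
                            rep(cohort_id, n_patients),
                            id = cohort_id, collapsed = TRUE)
  surv <- cohort_survival(ids, cens$time, cens$event, endpoint = "PFS",
                          ipi = ipi)
  list(panel = panel, survival = surv, true_combined = z)
}

#' Simulate a negative-control cohort
#'
#' Same expression generation as [simulate_cohort()], but the hazard is
#' driven by an independent latent factor unrelated to the resistance
#' genes, so a correct pipeline must find no signal.
#'
#' @inheritParams simulate_cohort
#' @return As [simulate_cohort()]; `true_combined` is the (unused)
#'   resistance truth, `hazard_factor` the independent driver.
#' @export
negative_control_cohort <- function(n_patients, truth = simulation_truth(),
                                    seed = 1, cohort_id = "negative_control",
                                    scale_factor = 1.4) {
  set.seed(seed)
  ids <- sprintf("N%04d", seq_len(n_patients))
  Xraw <- .draw_expression(truth, ids)
  u <- stats::rnorm(n_patients)
  ipi <- sample(0:5, n_patients, replace = TRUE,
                prob = c(0.10, 0.20, 0.25, 0.20, 0.15, 0.10))
  haz <- truth$baseline_hazard *
    exp(truth$hazard_coefficient * u +
          truth$ipi_coefficient * (ipi - mean(ipi)))
  T <- stats::rexp(n_patients, rate = haz)
  cens <- .apply_censoring(T, truth$censoring_rate)
  zs <- sapply(truth$drugs, function(d) {
    r <- drop(crossprod(Xraw[names(truth$causal_genes[[d]]), , drop = FALSE],
                        truth$causal_genes[[d]]))
    (r - mean(r)) / stats::sd(r)
  })
  panel <- expression_panel(Xraw * scale_factor,
                            rep(cohort_id, n_patients),
                            id = cohort_id, collapsed = TRUE)
  surv <- cohort_survival(ids, cens$time, cens$event, endpoint = "OS",
                          ipi = ipi)
  list(panel = panel, survival = surv,
       true_combined = rowMeans(zs), hazard_factor = u)
}
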