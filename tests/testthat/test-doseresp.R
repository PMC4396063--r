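test_that("growth rates follow the exponential-growth arithmetic", {
  # A0 = A48 everywhere: no growth at any dose
  pl <- make_plate(rep(0, 6), g0 = 0.02)
  pl$control48 <- pl$control0 # also silence the controls
  expect_error(estimate_growth_rates(pl), "not growing")
  pl2 <- make_plate(rep(0, 6))
  prof <- estimate_growth_rates(pl2)
  expect_equal(prof$g_at_dose, rep(0, 6), tolerance = 1e-12)

  # single replicate, blank 0, 0.2 -> 0.8 in 48 h
  pl3 <- dose_response_plate("x", "d", 20 * 2^(-(0:4)),
                             matrix(0.2, 1, 5), matrix(0.8, 1, 5),
                             0.2, 0.8, blank = 0, exposure_hours = 48)
  expect_equal(estimate_growth_rates(pl3)$g_at_dose,
               rep(log(4) / 48, 5), tolerance = 1e-12)

  # uniform doubling everywhere equals the control rate
  pl4 <- make_plate(rep(100, 6), g0 = log(2) / 48)
  prof4 <- estimate_growth_rates(pl4)
  expect_equal(prof4$g_at_dose, rep(log(2) / 48, 6), tolerance = 1e-12)
  expect_equal(prof4$g0, log(2) / 48, tolerance = 1e-12)
})

test_that("non-positive blank-corrected wells are missing, not fabricated", {
  pl <- make_plate(rep(80, 6), blank = 0.1)
  pl$absorbance48[, 2] <- 0.05 # below blank at every replicate of dose 2
  prof <- estimate_growth_rates(pl)
  expect_true(is.na(prof$g_at_dose[2]))
  expect_true(all(is.finite(prof$g_at_dose[-2])))
})

test_that("4PL fit recovers noise-free parameters and resists noise", {
  doses <- 20 * 2^(-(0:17))
  span <- range(log2(doses))
  true <- list(top = 100, bottom = 0, log2_ec50 = mean(span), slope = 1)
  R <- true$bottom + (true$top - true$bottom) /
    (1 + 2^(true$slope * (log2(doses) - true$log2_ec50)))
  pl <- make_plate(R)
  fit <- fit_dose_response(estimate_growth_rates(pl))
  expect_equal(fit$top, true$top, tolerance = 1e-4)
  expect_equal(fit$bottom, true$bottom, tolerance = 1e-4)
  expect_equal(fit$log2_ec50, true$log2_ec50, tolerance = 1e-4)
  expect_equal(fit$slope, true$slope, tolerance = 1e-4)

  # monotone-decreasing data with sigma = 2 noise: residual RMS stays small
  set.seed(42)
  Rn <- R + rnorm(18, 0, 2)
  prof <- estimate_growth_rates(make_plate(Rn))
  fitn <- fit_dose_response(prof)
  resid <- fitn$relative_growth$R -
    predict(fitn, fitn$relative_growth$log2_dose)
  expect_lte(sqrt(mean(resid^2)), 3)

  # flat (inert drug) data: top ~ bottom ~ 100
  flat <- fit_dose_response(estimate_growth_rates(make_plate(rep(100, 18))))
  expect_equal(flat$top, 100, tolerance = 1e-6)
  expect_equal(flat$bottom, 100, tolerance = 1e-6)

  expect_error(fit_dose_response(estimate_growth_rates(make_plate(c(100, 80, 60, 40)))),
               "at least 5")
})

test_that("AUC0 matches closed forms and the dense-trapezoid oracle", {
  span <- c(0, 17)
  flat <- structure(list(top = 100, bottom = 100, log2_ec50 = 8, slope = 0,
                         dose_span = span), class = "dose_response_curve")
  expect_equal(auc0(flat)$auc0, 1700)

  neg <- structure(list(top = -5, bottom = -50, log2_ec50 = 8, slope = 1,
                        dose_span = span), class = "dose_response_curve")
  expect_equal(auc0(neg)$auc0, 0)

  # triangle: linear from 100 down to -100 over width W has AUC0 = 25 W
  linear_curve <- function(w) {
    structure(list(dose_span = c(0, w), slope_lin = -200 / w),
              class = c("linear_curve", "dose_response_curve"))
  }
  assign("predict.linear_curve",
         function(object, log2_dose, ...) 100 + object$slope_lin * log2_dose,
         envir = globalenv())
  on.exit(rm("predict.linear_curve", envir = globalenv()), add = TRUE)
  for (w in c(4, 17)) {
    expect_equal(auc0(linear_curve(w))$auc0, 25 * w, tolerance = 1e-8)
  }

  # adaptive quadrature vs 1e4-point trapezoid on a generic 4PL
  cv <- structure(list(top = 95, bottom = -30, log2_ec50 = 6, slope = 1.7,
                       dose_span = span), class = "dose_response_curve")
  expect_equal(auc0(cv)$auc0, trapezoid_auc0(cv, 1e4 + 1), tolerance = 1e-6)

  degen <- structure(list(top = 1, bottom = 0, log2_ec50 = 0, slope = 1,
                          dose_span = c(3, 3)), class = "dose_response_curve")
  expect_error(auc0(degen), "degenerate")
})

test_that("AUC0 is monotone in the curve and scale-invariant in absorbance", {
  span <- c(0, 17)
  base <- structure(list(top = 80, bottom = -10, log2_ec50 = 8, slope = 1,
                         dose_span = span), class = "dose_response_curve")
  higher <- base; higher$top <- 95; higher$bottom <- 5
  expect_gte(auc0(higher)$auc0, auc0(base)$auc0)

  set.seed(7)
  R <- 100 - cumsum(runif(18, 0, 8))
  pl <- make_plate(R, blank = 0)
  pls <- pl
  pls$absorbance0 <- pl$absorbance0 * 3.7
  pls$absorbance48 <- pl$absorbance48 * 3.7
  pls$control0 <- pl$control0 * 3.7
  pls$control48 <- pl$control48 * 3.7
  a1 <- auc0(fit_dose_response(estimate_growth_rates(pl)))$auc0
  a2 <- auc0(fit_dose_response(estimate_growth_rates(pls)))$auc0
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("bootstrap AUC0 is reproducible and collapses without variance", {
  tr <- small_truth()
  sim <- simulate_cell_panel(2, 1, tr, seed = 9)
  pl <- sim$plates[[1]]
  b1 <- bootstrap_auc0(pl, n_boot = 60, seed = 11)
  b2 <- bootstrap_auc0(pl, n_boot = 60, seed = 11)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$auc0)
  expect_gte(b1$ci_high, b1$auc0)

  nopl <- make_plate(100 - seq(0, 85, length.out = 18)) # zero replicate spread
  b <- bootstrap_auc0(nopl, n_boot = 30, seed = 1)
  expect_equal(b$ci_low, b$auc0, tolerance = 1e-10)
  expect_equal(b$ci_high, b$auc0, tolerance = 1e-10)

  single <- make_plate(rep(100, 18), n_rep = 1)
  expect_error(bootstrap_auc0(single, n_boot = 5), "2 replicates")
})

test_that("long-format plate CSV round-trips through read_plates", {
  tr <- small_truth()
  sim <- simulate_cell_panel(2, 1, tr, seed = 3)
  pl <- sim$plates[[1]]
  rows <- do.call(rbind, lapply(seq_along(pl$doses), function(j) {
    do.call(rbind, lapply(seq_len(nrow(pl$absorbance0)), function(r) {
      data.frame(cell_line = pl$cell_line_id, drug = pl$drug_id,
                 dose_ug_ml = pl$doses[j], replicate = r,
                 time_h = c(0, 48),
                 absorbance = c(pl$absorbance0[r, j], pl$absorbance48[r, j]),
                 is_border = FALSE)
    }))
  }))
  ctl <- do.call(rbind, lapply(seq_along(pl$control0), function(r) {
    data.frame(cell_line = pl$cell_line_id, drug = pl$drug_id,
               dose_ug_ml = 0, replicate = r, time_h = c(0, 48),
               absorbance = c(pl$control0[r], pl$control48[r]),
               is_border = FALSE)
  }))
  f <- tempfile(fileext = ".csv")
  write.csv(rbind(rows, ctl), f, row.names = FALSE)
  plates <- read_plates(f, blank = pl$blank)
  expect_length(plates, 1)
  expect_equal(plates[[1]]$doses, pl$doses)
  expect_equal(unname(plates[[1]]$absorbance48), unname(pl$absorbance48))
  a_orig <- auc0(fit_dose_response(estimate_growth_rates(pl)))$auc0
  a_read <- auc0(fit_dose_response(estimate_growth_rates(plates[[1]])))$auc0
  # CSV carries ~15 significant digits
  expect_equal(a_read, a_orig, tolerance = 1e-6)
})
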