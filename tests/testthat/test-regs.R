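test_that("tertile categorisation splits disease groups as the screen design", {
  mk <- function(n, grp) {
    set.seed(nchar(grp) + n)
    setNames(runif(n, 50, 400), sprintf("%s%02d", grp, seq_len(n)))
  }
  # two groups of 12: 8 sensitive and 8 resistant in total
  v <- c(mk(12, "D"), mk(12, "M"))
  lab <- categorise_tertiles(v, rep(c("DLBCL", "MM"), each = 12))
  expect_equal(as.integer(table(lab$category)), c(8L, 8L, 8L))
  # groups of 14 + 12: 9 and 9
  v2 <- c(mk(14, "D"), mk(12, "M"))
  lab2 <- categorise_tertiles(v2, rep(c("DLBCL", "MM"), c(14, 12)))
  expect_equal(sum(lab2$category == "sensitive"), 9)
  expect_equal(sum(lab2$category == "resistant"), 9)
  # block order follows the AUC0 ranking within group
  d <- lab2[lab2$disease_group == "DLBCL", ]
  expect_true(max(d$auc0[d$category == "sensitive"]) <
                min(d$auc0[d$category == "resistant"]))
  # a group of 3 gets exactly one per category
  lab3 <- categorise_tertiles(setNames(c(1, 2, 3), c("a", "b", "c")),
                              rep("G", 3))
  expect_equal(as.character(sort(lab3$category)),
               c("sensitive", "intermediate", "resistant"))
  # ties straddling a boundary are broken by id order, with a message
  expect_message(
    labt <- categorise_tertiles(setNames(c(1, 1, 1), c("b", "a", "c")),
                                rep("G", 3)), "ties")
  expect_equal(labt$category[labt$cell_line == "a"], factor("sensitive",
               levels = levels(labt$category)))
})

test_that("full shrinkage leaves only the expected intercepts", {
  set.seed(1)
  X <- matrix(rnorm(80), 20, 4)
  y <- rnorm(20, 5)
  f <- fit_elastic_net(X, y, "gaussian", alpha = 0.5, lambda = c(1e8, 1e7))
  cf <- coef(f, 1e8)
  expect_true(all(cf$beta == 0))
  expect_equal(cf$intercept, mean(y), tolerance = 1e-8)

  yb <- rep(c(0, 1), c(14, 6))
  fb <- fit_elastic_net(X, yb, "binomial", alpha = 0.5, lambda = c(1e8, 1e7))
  cfb <- coef(fb, 1e8)
  expect_true(all(cfb$beta == 0))
  expect_equal(cfb$intercept, qlogis(mean(yb)), tolerance = 1e-6)
})

test_that("lasso on a mean-zero orthonormal design equals soft-thresholding", {
  set.seed(2)
  n <- 8; p <- 4
  Q <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  X <- sqrt(n) * Q # t(X) %*% X == n * I, columns mean zero
  colnames(X) <- paste0("g", 1:p)
  y <- rnorm(n, 2)
  ols <- drop(crossprod(X, y)) / n
  for (lam in c(0.1, 0.5, 1.2)) {
    f <- fit_elastic_net(X, y, "gaussian", alpha = 1,
                         lambda = c(5, lam), standardize = FALSE)
    cf <- coef(f, lam)
    expected <- sign(ols) * pmax(abs(ols) - lam, 0)
    expect_equal(unname(cf$beta), unname(expected), tolerance = 1e-5)
    expect_equal(cf$intercept, mean(y), tolerance = 1e-5)
  }
})

test_that("elastic net agrees with an independent coordinate-descent oracle", {
  set.seed(3)
  for (rep in 1:3) {
    X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("g", 1:4)))
    y <- rnorm(6)
    lam <- c(0.7, 0.25, 0.05)[rep]
    f <- fit_elastic_net(X, y, "gaussian", alpha = 0.5, lambda = c(10, lam),
                         standardize = FALSE)
    cf <- coef(f, lam)
    orc <- cd_enet_oracle(X, y, alpha = 0.5, lambda = lam)
    expect_equal(unname(cf$beta), orc$beta, tolerance = 1e-5)
    expect_equal(cf$intercept, orc$intercept, tolerance = 1e-5)
  }
})

test_that("KKT conditions hold at the returned solution", {
  set.seed(4)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- drop(X[, 1] * 2 - X[, 2] + rnorm(20, 0, 0.5))
  alpha <- 0.6
  lams <- exp(seq(2, -5, length.out = 30))
  f <- fit_elastic_net(X, y, "gaussian", alpha = alpha, lambda = lams,
                       standardize = FALSE)
  for (lam in lams[c(5, 15, 25)]) {
    cf <- coef(f, lam)
    r <- y - cf$intercept - drop(X %*% cf$beta)
    grad <- drop(crossprod(X, r)) / nrow(X) - lam * (1 - alpha) * cf$beta
    nz <- cf$beta != 0
    expect_true(all(abs(grad[nz] - lam * alpha * sign(cf$beta[nz])) < 1e-6))
    expect_true(all(abs(grad[!nz]) <= lam * alpha + 1e-6))
  }
})

test_that("active-set size grows as the penalty relaxes along the path", {
  set.seed(5)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- drop(X[, 1:3] %*% c(3, -2, 1)) + rnorm(40)
  f <- fit_elastic_net(X, y, "gaussian", alpha = 0.8,
                       lambda = exp(seq(1.5, -4, length.out = 40)))
  nzero <- colSums(as.matrix(f$fit$beta) != 0) # path stored high -> low lambda
  expect_true(all(diff(nzero) >= -1)) # solver-tolerance slack of one gene
})

test_that("cross-validation selects by held-out loss with deterministic ties", {
  # pure-noise data under total shrinkage: the loss surface is flat, so the
  # smallest alpha and smallest lambda must be returned
  set.seed(6)
  X <- matrix(rnorm(24 * 6), 24, 6)
  y <- rep(c(0, 1), 12)
  cfg <- elastic_net_config("binomial", alpha_grid = c(0.2, 0.6, 1),
                            loglambda_range = c(6, 8), n_lambda = 5,
                            cv = "loo")
  sel <- cv_select(X, y, cfg)
  expect_equal(sel$alpha, 0.2)
  expect_equal(sel$lambda, exp(6))

  # a perfectly separating gene: some grid point attains 0 misclassifications
  Xs <- X
  Xs[, 1] <- ifelse(y == 1, 3, -3) + rnorm(24, 0, 0.05)
  cfg2 <- elastic_net_config("binomial", alpha_grid = c(0.5, 1),
                             loglambda_range = c(-6, 1), n_lambda = 20,
                             cv = "loo")
  sel2 <- cv_select(Xs, y, cfg2)
  expect_equal(min(sel2$loss), 0)
})

test_that("leave-one-out CV equals a brute-force n-refit oracle", {
  set.seed(7)
  n <- 12
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- rep(c(0, 1), each = 6)
  X[y == 1, 1] <- X[y == 1, 1] + 1.5
  alphas <- c(0.5, 1)
  lambdas <- sort(exp(seq(-4, 1, length.out = 8)), decreasing = TRUE)
  cfg <- elastic_net_config("binomial", alpha_grid = alphas,
                            loglambda_range = c(-4, 1), n_lambda = 8,
                            cv = "loo")
  sel <- cv_select(X, y, cfg)
  oracle <- matrix(0, length(alphas), length(lambdas))
  for (i in seq_len(n)) {
    for (a in seq_along(alphas)) {
      f <- fit_elastic_net(X[-i, ], y[-i], "binomial", alpha = alphas[a],
                           lambda = lambdas)
      for (l in seq_along(lambdas)) {
        cf <- coef(f, lambdas[l])
        eta <- cf$intercept + sum(X[i, ] * cf$beta)
        oracle[a, l] <- oracle[a, l] + as.integer((plogis(eta) > 0.5) != (y[i] == 1))
      }
    }
  }
  expect_equal(unname(sel$loss), oracle)
})

test_that("gaussian CV beats the intercept-only model on causal data", {
  set.seed(8)
  n <- 40; p <- 200
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%03d", 1:p)))
  beta <- numeric(p); beta[1:10] <- 2
  y <- drop(X %*% beta) + rnorm(n)
  cfg <- elastic_net_config("gaussian", alpha_grid = c(0.1, 0.5, 1),
                            loglambda_range = c(-2, 5), n_lambda = 25,
                            cv = 5)
  sel <- cv_select(X, y, cfg)
  null_mspe <- mean(sapply(seq_len(n), function(i) (mean(y[-i]) - y[i])^2))
  expect_lt(min(sel$loss), null_mspe)
})

test_that("signature predictions obey the linear-model identities", {
  set.seed(9)
  # a compact, strongly-driven truth so the identities are exercised on a
  # non-empty signature
  tr <- simulation_truth(n_genes = 200, n_causal = 5, weight = 2, seed = 1)
  sim <- simulate_cell_panel(10, 10, tr, seed = 2, plates = FALSE)
  tab <- sim$auc0_table[sim$auc0_table$drug == "C", ]
  hp <- median_center(sim$panel)
  cfg <- elastic_net_config("gaussian", alpha_grid = c(0.3, 1),
                            loglambda_range = c(-0.17, 7.63), n_lambda = 30,
                            cv = "loo")
  m <- train_regs(hp, setNames(tab$true_auc0, tab$cell_line), "C", cfg)
  expect_gt(length(m$coefficients), 0)

  genes <- names(m$coefficients)
  zero <- matrix(0, length(genes), 2,
                 dimnames = list(genes, c("s1", "s2")))
  expect_equal(unname(predict_index(m, zero, disease_indicator = 0)),
               rep(m$intercept, 2))
  expect_equal(unname(predict_index(m, zero, disease_indicator = 1)),
               rep(m$intercept + m$disease_coefficient, 2))
  # linearity: a bump of +delta on one signature gene moves the index by
  # coefficient * delta
  bump <- zero
  bump[1, 1] <- 2.5
  di <- predict_index(m, bump) - predict_index(m, zero)
  expect_equal(unname(di), unname(c(m$coefficients[1] * 2.5, 0)))

  # on low-noise training data the re-predicted index tracks the truth
  z <- as.integer(hp$disease_group == "MM")
  idx <- predict_index(m, hp, disease_indicator = z)
  expect_gte(cor(idx, tab$true_auc0), 0.9)
})

test_that("classifier probabilities separate labelled groups and handle missing genes", {
  set.seed(10)
  tr <- simulation_truth(n_genes = 200, n_causal = 5, weight = 2, seed = 1)
  sim <- simulate_cell_panel(12, 12, tr, seed = 4, plates = FALSE)
  tab <- sim$auc0_table[sim$auc0_table$drug == "H", ]
  hp <- median_center(sim$panel)
  lab <- categorise_tertiles(setNames(tab$true_auc0, tab$cell_line),
                             tab$disease_group)
  cfg <- elastic_net_config("binomial", alpha_grid = c(0.1, 0.5),
                            loglambda_range = c(-6, 3), n_lambda = 30,
                            cv = "loo")
  m <- train_regs(hp, lab, "H", cfg)
  p <- predict_probability(m, hp)
  expect_true(all(p > 0 & p < 1))
  expect_gt(mean(p[lab$cell_line[lab$category == "resistant"]]),
            mean(p[lab$cell_line[lab$category == "sensitive"]]))
  # all-zero expression gives the intercept probability
  genes <- names(m$coefficients)
  zero <- matrix(0, length(genes), 1, dimnames = list(genes, "s"))
  expect_equal(unname(predict_probability(m, zero)), plogis(m$intercept))

  if (length(genes) >= 5) {
    # a few missing signature genes contribute zero, with a warning
    few <- hp$values[setdiff(rownames(hp$values), genes[1]), , drop = FALSE]
    expect_warning(pm <- predict_probability(m, few), "imputed")
    mhat <- m; mhat$coefficients[1] <- 0
    expect_equal(unname(pm), unname(predict_probability(mhat, hp)),
                 tolerance = 1e-12)
  }
  # more than 20% missing is not transferable
  strip <- hp$values[setdiff(rownames(hp$values),
                             genes[seq_len(ceiling(0.3 * length(genes)))]), ,
                     drop = FALSE]
  expect_error(suppressWarnings(predict_probability(m, strip)),
               "not transferable")
})

test_that("models survive a JSON round trip", {
  set.seed(11)
  tr <- simulation_truth(n_genes = 200, n_causal = 5, weight = 2, seed = 1)
  sim <- simulate_cell_panel(10, 10, tr, seed = 5, plates = FALSE)
  tab <- sim$auc0_table[sim$auc0_table$drug == "O", ]
  hp <- median_center(sim$panel)
  cfg <- elastic_net_config("gaussian", alpha_grid = 0.5,
                            loglambda_range = c(0, 6), n_lambda = 15,
                            cv = "loo")
  m <- train_regs(hp, setNames(tab$true_auc0, tab$cell_line), "O", cfg)
  f <- tempfile(fileext = ".json")
  write_regs_model(m, f)
  m2 <- read_regs_model(f)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(predict_index(m2, hp, 0), predict_index(m, hp, 0))
  other <- tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), other)
  expect_error(read_regs_model(other), "not a regsig model")
})
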