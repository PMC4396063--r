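#' Tertile sensitivity labels within disease groups
#'
#' Ranks cell lines by AUC0 separately within each disease group and splits
#' each group into three contiguous blocks as equal as possible, allotting
#' remainders to the sensitive and resistant extremes first (12 -> 4/4/4,
#' 14 -> 5/4/5). The lowest-AUC0 block is sensitive; the intermediate block
#' is conventionally excluded from classifier training. Ties straddling a
#' block boundary are broken by cell-line id order (messaged).
#'
#' @param auc0 Named numeric vector of AUC0 values (names = cell line ids),
#'   or a data.frame from [auc0_table()] for a single drug.
#' @param disease_group Character vector of group labels aligned with `auc0`.
#' @return data.frame with cell_line, disease_group, auc0 and a `category`
#'   factor with levels sensitive, intermediate, resistant.
#' @export
categorise_tertiles <- function(auc0, disease_group) {
  if (is.data.frame(auc0)) {
    ids <- auc0$cell_line
    vals <- auc0$auc0
  } else {
    ids <- names(auc0)
    vals <- as.numeric(auc0)
  }
  if (is.null(ids)) stop("auc0 values must carry cell-line ids")
  if (any(!is.finite(vals))) stop("AUC0 values must be finite")
  if (length(disease_group) != length(vals))
    stop("disease_group must align with auc0")
  out <- data.frame(cell_line = ids, disease_group = as.character(disease_group),
                    auc0 = vals, category = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in unique(out$disease_group)) {
    sel <- which(out$disease_group == g)
    n <- length(sel)
    if (n < 3) stop("need at least 3 cell lines per disease group")
    if (anyDuplicated(out$auc0[sel]))
      message("AUC0 ties in group ", g, " broken by cell-line id order")
    ord <- sel[order(out$auc0[sel], out$cell_line[sel])]
    q <- n %/% 3
    r <- n %% 3
    sizes <- c(sensitive = q + (r >= 1), intermediate = q,
               resistant = q + (r == 2))
    out$category[ord] <- rep(c("sensitive", "intermediate", "resistant"),
                             times = sizes)
  }
  out$category <- factor(out$category,
                         levels = c("sensitive", "intermediate", "resistant"))
  out
}

#' Elastic-net configuration
#'
#' Grids and cross-validation scheme for signature training. The penalty is
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)` added to
#' the (1/2n) residual sum of squares (gaussian) or the mean negative
#' log-likelihood (binomial). The lambda grid is log-spaced (natural log)
#' across `loglambda_range`, which defaults to [-6, 3] for classifiers and
#' [-0.17, 7.63] for predictors.
#'
#' @param family "binomial" (classifier) or "gaussian" (predictor).
#' @param alpha_grid Mixing parameters in (0, 1].
#' @param loglambda_range Interval for log(lambda).
#' @param n_lambda Number of log-spaced lambda values.
#' @param cv "loo" or an integer number of folds.
#' @return A list of class `elastic_net_config`.
#' @export
elastic_net_config <- function(family = c("binomial", "gaussian"),
                               alpha_grid = seq(0.1, 1, by = 0.05),
                               loglambda_range = NULL,
                               n_lambda = 100,
                               cv = "loo") {
  family <- match.arg(family)
  if (is.null(loglambda_range))
    loglambda_range <- if (family == "binomial") c(-6, 3) else c(-0.17, 7.63)
  if (length(alpha_grid) == 0 || any(alpha_grid <= 0 | alpha_grid > 1))
    stop("alpha_grid values must lie in (0, 1]")
  if (n_lambda < 1) stop("n_lambda must be positive")
  structure(list(family = family, alpha_grid = sort(alpha_grid),
                 loglambda_range = loglambda_range,
                 lambda_grid = exp(seq(loglambda_range[1], loglambda_range[2],
                                       length.out = n_lambda)),
                 cv = cv),
            class = "elastic_net_config")
}

# standardise columns with the fitting software's convention (1/n variance);
# returns list(x, center, scale)
.standardise <- function(X) {
  center <- colMeans(X)
  xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(xc^2))
  list(x = sweep(xc, 2, scale, "/"), center = center, scale = scale)
}

#' Fit an elastic-net path at a fixed mixing parameter
#'
#' Thin wrapper around the coordinate-descent solver: predictors are
#' standardised internally (mean 0, variance 1; disable with
#' `standardize = FALSE`), an optional covariate can be left unpenalised
#' (the disease indicator of the predictor models), and coefficients are
#' reported on the original predictor scale.
#'
#' @param X n x p predictor matrix with column names (genes).
#' @param y Response: numeric (gaussian) or two-level factor/0-1 (binomial).
#' @param family "gaussian" or "binomial".
#' @param alpha Elastic-net mixing parameter in (0, 1].
#' @param lambda Decreasingly sorted or unsorted vector of penalties; the
#'   path is fitted at exactly these values.
#' @param unpenalised Optional numeric covariate (length n) carrying no
#'   penalty and no standardisation.
#' @param standardize Standardise predictor columns internally.
#' @return Object of class `enet_fit`.
#' @export
fit_elastic_net <- function(X, y, family = c("gaussian", "binomial"),
                            alpha, lambda, unpenalised = NULL,
                            standardize = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("non-finite entries in predictor matrix")
  dropped <- character(0)
  if (standardize) {
    v <- apply(X, 2, stats::var)
    dropped <- colnames(X)[v == 0]
    if (length(dropped) > 0) {
      message(length(dropped), " zero-variance genes dropped before fitting")
      X <- X[, v > 0, drop = FALSE]
    }
    std <- .standardise(X)
  } else {
    std <- list(x = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    names(std$center) <- names(std$scale) <- colnames(X)
  }
  xin <- std$x
  pf <- rep(1, ncol(xin))
  if (!is.null(unpenalised)) {
    xin <- cbind(xin, .disease_ = as.numeric(unpenalised))
    pf <- c(pf, 0)
  }
  lam <- sort(unique(lambda), decreasing = TRUE)
  # a single-lambda fit is ill-advised for coordinate descent; prepend a
  # stronger penalty and read coefficients off the grid node
  if (length(lam) == 1) lam <- c(lam * 1000, lam)
  # The solver standardises a gaussian response internally, which silently
  # rescales the ridge part of the penalty by 1/sd(y). Fitting y/s with
  # alpha_g = alpha / (s (1 - alpha) + alpha) and lambda_g = lambda *
  # ((1 - alpha) + alpha / s) makes it minimise exactly
  # (1/2n) RSS + lambda ((1-alpha)/2 ||b||_2^2 + alpha ||b||_1)
  # in the original response units (coefficients scale back by s).
  if (family == "gaussian") {
    yv <- as.numeric(y)
    s <- sqrt(mean((yv - mean(yv))^2))
    if (!is.finite(s) || s == 0) s <- 1
    cfac <- (1 - alpha) + alpha / s
    alpha_g <- min(alpha / (s * cfac), 1)
    yfit <- yv / s
    lam_g <- cfac * lam
  } else {
    s <- 1; cfac <- 1; alpha_g <- alpha; yfit <- y; lam_g <- lam
  }
  # small panels are the norm here; glmnet warns on every binomial fit with
  # < 8 observations per class, which would swamp the cross-validation loop
  fit <- withCallingHandlers(
    glmnet::glmnet(xin, yfit, family = family, alpha = alpha_g,
                   lambda = lam_g, standardize = FALSE,
                   penalty.factor = pf, thresh = 1e-12, maxit = 1e6),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(fit = fit, family = family, alpha = alpha, lambda = lam,
                 lambda_glmnet = lam_g, y_scale = s, lambda_factor = cfac,
                 center = std$center, scale = std$scale,
                 genes = colnames(X), dropped = dropped,
                 has_unpenalised = !is.null(unpenalised)),
            class = "enet_fit")
}

#' Coefficients of an elastic-net path at one penalty
#'
#' @param object An `enet_fit` from [fit_elastic_net()].
#' @param lambda Penalty at which to report coefficients (a grid node).
#' @param ... Ignored.
#' @return List with `intercept`, `beta` (named, original predictor scale)
#'   and `disease_coefficient`.
#' @export
coef.enet_fit <- function(object, lambda, ...) coef_at(object, lambda)

# coefficients at a single lambda (user scale), on the original predictor
# and response scales
coef_at <- function(object, lambda) {
  stopifnot(inherits(object, "enet_fit"))
  idx <- match(lambda, object$lambda)
  s_g <- if (!is.na(idx)) object$lambda_glmnet[idx]
         else object$lambda_factor * lambda
  cf <- as.matrix(glmnet::coef.glmnet(object$fit, s = s_g, exact = FALSE))[, 1]
  cf <- cf * object$y_scale
  a0 <- cf[1]
  beta_std <- cf[object$genes]
  delta <- if (object$has_unpenalised) cf[".disease_"] else 0
  beta <- beta_std / object$scale
  intercept <- a0 - sum(beta_std * object$center / object$scale)
  list(intercept = unname(intercept), beta = beta,
       disease_coefficient = unname(delta))
}

# linear predictor for new data on the original scale
.enet_linear_predictor <- function(object, lambda, Xnew, unpenalised = NULL) {
  cf <- coef_at(object, lambda)
  eta <- drop(Xnew[, object$genes, drop = FALSE] %*% cf$beta) + cf$intercept
  if (object$has_unpenalised) {
    if (is.null(unpenalised)) stop("model has an unpenalised covariate; supply it")
    eta <- eta + cf$disease_coefficient * as.numeric(unpenalised)
  }
  eta
}

# deterministic fold assignment: stratified round-robin for binomial,
# response-ordered round-robin for gaussian
.make_folds <- function(y, family, k) {
  n <- length(y)
  fold <- integer(n)
  if (family == "binomial") {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[order(y)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Cross-validated selection of (alpha, lambda)
#'
#' For every point of the alpha x lambda grid the held-out loss is computed
#' under the configured scheme (leave-one-out by default): the number of
#' misclassifications at probability threshold 0.5 for classifiers, the mean
#' squared prediction error for predictors. The argmin is returned, ties
#' resolved towards the smallest alpha and then the smallest lambda, and the
#' final model is refitted on all data at the chosen pair.
#'
#' @param X,y,unpenalised As in [fit_elastic_net()].
#' @param config An [elastic_net_config()].
#' @return Object of class `cv_enet`: `alpha`, `lambda`, `cv_loss` (the
#'   attained minimum), `loss` (alpha x lambda matrix), `model` (the refit
#'   `enet_fit`).
#' @export
cv_select <- function(X, y, config, unpenalised = NULL) {
  stopifnot(inherits(config, "elastic_net_config"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  n <- nrow(X)
  family <- config$family
  yv <- if (family == "binomial") {
    if (is.factor(y)) as.integer(y == levels(y)[2]) else as.integer(y)
  } else as.numeric(y)
  folds <- if (identical(config$cv, "loo")) seq_len(n)
           else .make_folds(yv, family, as.integer(config$cv))
  alphas <- config$alpha_grid
  lambdas <- sort(config$lambda_grid, decreasing = TRUE)
  loss <- matrix(0, length(alphas), length(lambdas),
                 dimnames = list(alpha = signif(alphas, 4),
                                 lambda = signif(lambdas, 4)))
  used_folds <- 0
  for (f in sort(unique(folds))) {
    test <- which(folds == f)
    train <- setdiff(seq_len(n), test)
    if (family == "binomial" && length(unique(yv[train])) < 2) {
      warning("fold ", f, " skipped: training data has a single class")
      next
    }
    used_folds <- used_folds + 1
    for (a in seq_along(alphas)) {
      fit <- fit_elastic_net(X[train, , drop = FALSE], yv[train],
                             family = family, alpha = alphas[a],
                             lambda = lambdas,
                             unpenalised = unpenalised[train])
      xt <- X[test, fit$genes, drop = FALSE]
      xt <- sweep(sweep(xt, 2, fit$center), 2, fit$scale, "/")
      if (fit$has_unpenalised)
        xt <- cbind(xt, .disease_ = as.numeric(unpenalised[test]))
      eta <- stats::predict(fit$fit, newx = xt, type = "link") * fit$y_scale
      # the path is fitted at exactly `lambdas`; if the solver truncated
      # the path, carry the smallest fitted penalty forward
      idx <- match(fit$lambda_glmnet, fit$fit$lambda)
      idx[is.na(idx)] <- length(fit$fit$lambda)
      eta <- eta[, idx, drop = FALSE]
      if (family == "binomial") {
        pred <- stats::plogis(eta) > 0.5
        loss[a, ] <- loss[a, ] + colSums(pred != matrix(yv[test] == 1,
                                                        length(test),
                                                        length(lambdas)))
      } else {
        loss[a, ] <- loss[a, ] + colSums((eta - yv[test])^2)
      }
    }
  }
  if (used_folds == 0) stop("all cross-validation folds were degenerate")
  if (family == "gaussian") loss <- loss / n
  # argmin with ties towards smallest alpha, then smallest lambda;
  # lambdas are stored descending so scan columns from the right
  best <- which(loss == min(loss), arr.ind = TRUE)
  best <- best[order(best[, 1], -best[, 2]), , drop = FALSE]
  a_star <- alphas[best[1, 1]]
  l_star <- lambdas[best[1, 2]]
  model <- fit_elastic_net(X, yv, family = family, alpha = a_star,
                           lambda = lambdas, unpenalised = unpenalised)
  structure(list(alpha = a_star, lambda = l_star, cv_loss = min(loss),
                 loss = loss, model = model, family = family),
            class = "cv_enet")
}

#' Train a resistance gene signature for one drug
#'
#' High-level wrapper: assembles the design matrix from a harmonised
#' expression panel, runs [cv_select()] and packages the refitted model. For
#' classifiers (`family = "binomial"`) supply the tertile labels from
#' [categorise_tertiles()]; intermediate cell lines are excluded and
#' resistance is the positive class. For predictors (`family = "gaussian"`)
#' supply the AUC0 values; the disease indicator (0 = first group level,
#' 1 = second) is included unpenalised.
#'
#' @param panel Harmonised [expression_panel] of the training cell lines.
#' @param outcome For binomial, the data.frame from [categorise_tertiles()];
#'   for gaussian, a named numeric vector of AUC0 values.
#' @param drug Drug identifier stored in the model.
#' @param config An [elastic_net_config()]; family must match the outcome.
#' @param disease_baseline Disease-group label coded 0 in the indicator
#'   (defaults to the first group of the panel).
#' @return Object of class `regs_model`.
#' @export
train_regs <- function(panel, outcome, drug, config,
                       disease_baseline = panel$disease_group[1]) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(config, "elastic_net_config"))
  X <- t(panel$values)
  if (config$family == "binomial") {
    stopifnot(is.data.frame(outcome))
    keep <- outcome$category != "intermediate"
    labs <- outcome[keep, , drop = FALSE]
    X <- X[labs$cell_line, , drop = FALSE]
    y <- as.integer(labs$category == "resistant")
    cv <- cv_select(X, y, config)
    delta <- 0
  } else {
    ids <- names(outcome)
    X <- X[ids, , drop = FALSE]
    z <- as.integer(panel$disease_group[match(ids, colnames(panel$values))] !=
                      disease_baseline)
    cv <- cv_select(X, as.numeric(outcome), config, unpenalised = z)
  }
  cf <- coef_at(cv$model, cv$lambda)
  nz <- cf$beta[cf$beta != 0]
  structure(list(drug_id = drug, family = config$family,
                 alpha = cv$alpha, lambda = cv$lambda,
                 intercept = cf$intercept, coefficients = nz,
                 disease_coefficient = cf$disease_coefficient,
                 gene_order = names(nz),
                 standardisation = list(center = cv$model$center[names(nz)],
                                        scale = cv$model$scale[names(nz)]),
                 cv_loss = cv$cv_loss, cv = cv),
            class = "regs_model")
}

#' @export
print.regs_model <- function(x, ...) {
  cat(sprintf("regs_model (%s) for %s: %d genes, alpha %.2f, log(lambda) %.2f\n",
              if (x$family == "binomial") "classifier" else "predictor",
              x$drug_id, length(x$coefficients), x$alpha, log(x$lambda)))
  invisible(x)
}

# gather the signature genes' expression for new samples, imputing missing
# genes at zero (= the reference median after centring)
.signature_matrix <- function(model, panel) {
  vals <- if (inherits(panel, "expression_panel")) panel$values else as.matrix(panel)
  need <- names(model$coefficients)
  if (length(need) == 0)
    return(matrix(0, 0, ncol(vals), dimnames = list(NULL, colnames(vals))))
  missing <- setdiff(need, rownames(vals))
  if (length(missing) / max(length(need), 1) > 0.2)
    stop(sprintf("signature not transferable: %d of %d signature genes missing",
                 length(missing), length(need)))
  if (length(missing) > 0)
    warning("missing signature genes imputed at the reference median (0): ",
            paste(missing, collapse = ", "))
  x <- matrix(0, length(need), ncol(vals),
              dimnames = list(need, colnames(vals)))
  present <- intersect(need, rownames(vals))
  x[present, ] <- vals[present, , drop = FALSE]
  x
}

#' Predict per-sample resistance probabilities
#'
#' Applies a binomial signature to a cohort panel harmonised to the training
#' reference (median-centred, variance-matched):
#' `p = plogis(intercept + x' beta)`. Genes absent from the cohort
#' contribute zero (warned; more than 20% missing is an error).
#'
#' @param model A `regs_model` with family binomial.
#' @param panel An [expression_panel] or gene x sample matrix.
#' @return Named vector of probabilities of resistance in (0, 1).
#' @export
predict_probability <- function(model, panel) {
  stopifnot(inherits(model, "regs_model"))
  if (model$family != "binomial") stop("probabilities require a classifier model")
  x <- .signature_matrix(model, panel)
  contrib <- if (length(model$coefficients))
    drop(crossprod(x, model$coefficients)) else stats::setNames(
      rep(0, ncol(x)), colnames(x))
  stats::plogis(model$intercept + contrib)
}

#' Predict per-sample resistance indices (AUC0 scale)
#'
#' Applies a gaussian signature: `index = intercept + delta * z + x' beta`,
#' where `z` is the disease indicator of the cohort's origin (0 for
#' cohorts matching the training baseline group).
#'
#' @param model A `regs_model` with family gaussian.
#' @param panel An [expression_panel] or gene x sample matrix.
#' @param disease_indicator 0 or 1 (scalar or per-sample vector).
#' @return Named vector of predicted resistance indices.
#' @export
predict_index <- function(model, panel, disease_indicator = 0) {
  stopifnot(inherits(model, "regs_model"))
  if (model$family != "gaussian") stop("indices require a predictor model")
  x <- .signature_matrix(model, panel)
  contrib <- if (length(model$coefficients))
    drop(crossprod(x, model$coefficients)) else stats::setNames(
      rep(0, ncol(x)), colnames(x))
  model$intercept + model$disease_coefficient * disease_indicator + contrib
}

#' Write a signature model to versioned JSON
#'
#' @param model A `regs_model`.
#' @param path Output file.
#' @export
write_regs_model <- function(model, path) {
  stopifnot(inherits(model, "regs_model"))
  obj <- list(format = "regsig-model", version = 1L,
              drug = model$drug_id, family = model$family,
              alpha = model$alpha, lambda = model$lambda,
              intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              disease_coefficient = model$disease_coefficient,
              standardisation = lapply(model$standardisation, as.list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature model written by [write_regs_model()]
#'
#' @param path JSON file.
#' @return A `regs_model`.
#' @export
read_regs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "regsig-model"))
    stop("not a regsig model file")
  cf <- unlist(obj$coefficients)
  if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
  structure(list(drug_id = obj$drug, family = obj$family,
                 alpha = obj$alpha, lambda = obj$lambda,
                 intercept = obj$intercept,
                 coefficients = cf,
                 disease_coefficient = obj$disease_coefficient,
                 gene_order = names(unlist(obj$coefficients)),
                 standardisation = lapply(obj$standardisation, unlist)),
            class = "regs_model")
}
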