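# Independent oracles and small fixture builders used across the suite.

# Build a plate whose relative growth at each dose is exactly `R` (percent of
# untreated growth): absorbances follow the exponential forward model with
# no measurement noise.
make_plate <- function(R, doses = 20 * 2^(-(0:(length(R) - 1))),
                       g0 = 0.02, n_rep = 3, blank = 0, a0 = 0.3,
                       hours = 48, cell_line = "CL", drug = "D") {
  g <- g0 * R / 100
  A0 <- matrix(a0, n_rep, length(doses))
  A48 <- matrix(rep(a0 * exp(g * hours), each = n_rep), n_rep, length(doses))
  dose_response_plate(cell_line, drug, doses, A0 + blank, A48 + blank,
                      rep(a0, n_rep) + blank,
                      rep(a0 * exp(g0 * hours), n_rep) + blank,
                      blank = blank, exposure_hours = hours)
}

# Dense-grid trapezoid integration of the positive part of a curve.
trapezoid_auc0 <- function(curve, n = 1e4) {
  x <- seq(curve$dose_span[1], curve$dose_span[2], length.out = n)
  y <- pmax(stats::predict(curve, x), 0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# Plain coordinate descent for the elastic net (gaussian, intercept, no
# standardisation) minimising (1/2n)||y - b0 - Xb||^2 + lambda*((1-a)/2||b||^2
# + a||b||_1). Written independently of the package's solver.
cd_enet_oracle <- function(X, y, alpha, lambda, iters = 5000, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  beta <- rep(0, p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  xsq <- colMeans(X^2)
  for (it in seq_len(iters)) {
    old <- c(b0, beta)
    r <- y - b0 - drop(X %*% beta)
    b0 <- b0 + mean(r)
    for (j in seq_len(p)) {
      r <- y - b0 - drop(X %*% beta)
      z <- mean(X[, j] * r) + xsq[j] * beta[j]
      beta[j] <- soft(z, lambda * alpha) / (xsq[j] + lambda * (1 - alpha))
    }
    if (max(abs(c(b0, beta) - old)) < tol) break
  }
  list(intercept = b0, beta = beta)
}

# Empirical pairwise-count AUC for (event by t) cases vs (event-free at t)
# controls, no censoring: brute-force double loop.
pairwise_auc_oracle <- function(time, event, marker, t) {
  case <- which(time <= t & event == 1)
  ctrl <- which(time > t)
  tot <- 0
  for (i in case) for (j in ctrl)
    tot <- tot + (marker[i] > marker[j]) + 0.5 * (marker[i] == marker[j])
  tot / (length(case) * length(ctrl))
}

# Explicit Kaplan-Meier product formula at time t.
km_product_oracle <- function(time, event, t) {
  dt <- sort(unique(time[event == 1 & time <= t]))
  s <- 1
  for (u in dt) {
    d <- sum(time == u & event == 1)
    r <- sum(time >= u)
    s <- s * (1 - d / r)
  }
  s
}

# Breslow log partial likelihood for a single covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Shared small-scale truth for module tests (kept small for speed).
small_truth <- function(...) simulation_truth(n_genes = 200, seed = 1, ...)
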