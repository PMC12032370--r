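# Independent oracles and small fixture builders shared across the suite.

# Eigen-decomposition PLS1 oracle: per component, the covariance-maximising
# weight vector is the dominant eigenvector of X'c y y' Xc; scores, loadings
# and deflation are carried out explicitly. Same sign convention as the
# package (largest-magnitude weight element positive).
pls1_oracle <- function(X, y, A) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  W <- matrix(0, ncol(X), A); TT <- matrix(0, nrow(X), A)
  P <- matrix(0, ncol(X), A); Q <- numeric(A); ssy <- numeric(A)
  for (a in seq_len(A)) {
    M <- crossprod(Xc, yc) %*% crossprod(yc, Xc)
    ev <- eigen(M, symmetric = TRUE)
    w <- ev$vectors[, 1]
    j <- which.max(abs(w)); if (w[j] < 0) w <- -w
    t <- Xc %*% w; t2 <- sum(t^2)
    p <- crossprod(Xc, t) / t2
    q <- sum(yc * t) / t2
    Xc <- Xc - t %*% t(p); yc <- yc - q * t
    W[, a] <- w; TT[, a] <- t; P[, a] <- p; Q[a] <- q; ssy[a] <- q^2 * t2
  }
  list(W = W, scores = TT, P = P, Q = Q, ssy = ssy)
}

# Spreadsheet-style VIP re-evaluation from exported weights and explained
# class variance.
vip_oracle <- function(W, ssy) {
  p <- nrow(W)
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  sqrt(p * as.vector(Wn^2 %*% ssy) / sum(ssy))
}

# Two separable Gaussian clouds with optional pure-noise features.
make_clouds <- function(n_per = 20, p_signal = 4, p_noise = 6, d = 4) {
  n <- 2 * n_per
  X <- matrix(rnorm(n * (p_signal + p_noise)), n)
  X[seq_len(n_per), seq_len(p_signal)] <- X[seq_len(n_per), seq_len(p_signal)] + d
  colnames(X) <- c(sprintf("sig%d", seq_len(p_signal)),
                   sprintf("noise%d", seq_len(p_noise)))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}

# Explicit GLS oracle for the crossover mixed model: builds the marginal
# covariance per subject (random-intercept block shared across the two
# treatment series, AR(1) within each series) and solves the generalised
# least squares equations directly.
gls_oracle <- function(formula, data, sigma_b, sigma_e, rho) {
  mm <- model.matrix(formula, data)
  y <- model.response(model.frame(formula, data))
  subjects <- unique(data$subject)
  n <- nrow(mm)
  Vinv_X <- matrix(0, n, ncol(mm)); Vinv_y <- numeric(n)
  XtVX <- matrix(0, ncol(mm), ncol(mm)); XtVy <- numeric(ncol(mm))
  for (s in subjects) {
    idx <- which(data$subject == s)
    d <- data[idx, ]
    Vs <- matrix(sigma_b^2, length(idx), length(idx))
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (d$treatment[i] == d$treatment[j])
        Vs[i, j] <- Vs[i, j] + sigma_e^2 * rho^abs(d$tidx[i] - d$tidx[j])
    }
    Vi <- solve(Vs)
    XtVX <- XtVX + t(mm[idx, , drop = FALSE]) %*% Vi %*% mm[idx, , drop = FALSE]
    XtVy <- XtVy + t(mm[idx, , drop = FALSE]) %*% Vi %*% y[idx]
  }
  beta <- solve(XtVX, XtVy)
  list(beta = drop(beta), vcov = solve(XtVX))
}

# Wald chi-square for a coefficient subset.
wald_stat <- function(beta, V, idx) {
  drop(crossprod(beta[idx], solve(V[idx, idx, drop = FALSE], beta[idx])))
}

# Simulate one metabolite's log-scale crossover data directly: subject
# intercepts, optional log-scale treatment effects per post-dose time,
# AR(1) within-series noise.
sim_kinetics <- function(n_subj = 12, times = c(0, 10, 30, 50, 70),
                         effect = NULL, rho = 0.4, sigma_b = 0.3,
                         sigma_e = 0.12, mu = 5) {
  trt <- c("placebo", "cannabis")
  b <- rnorm(n_subj, 0, sigma_b)
  rows <- list()
  for (i in seq_len(n_subj)) for (s in trt) {
    e <- metabocross:::ar1_noise(1, length(times), rho, sigma_e)[1, ]
    v <- mu + b[i] + e
    if (s == "cannabis" && !is.null(effect))
      v[-1] <- v[-1] + effect
    rows[[length(rows) + 1]] <- data.frame(
      subject = sprintf("s%02d", i), treatment = s, time = times, value = v)
  }
  do.call(rbind, rows)
}

# A small, fast study configuration for pipeline-level tests.
small_study_config <- function(seed, n_occ = 6, n_chr = 6, with_effects = TRUE) {
  panel <- default_metabolite_panel()[c(1:16, 25:34)]
  if (!with_effects)
    panel <- lapply(panel, function(s) { s$treatment_effect <- NULL; s })
  study_config(n_occasional = n_occ, n_chronic = n_chr,
               metabolites = panel,
               ratio_definitions = default_ratio_definitions()[c(4, 7), ],
               behavior_coupling = if (with_effects) default_behavior_coupling() else NULL,
               seed = seed)
}
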