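# Internal PLS1 NIPALS on pre-centred data. For a single response the NIPALS
# weight step is closed-form per component: w_a ~ X'y (unit norm), followed
# by score/loading computation and deflation of both X and y. Returns the
# pieces the VIP formula and the predictor need:
#   W (p x A, unit-norm weights, sign-fixed), P (p x A loadings),
#   Q (A y-loadings), tt (A score norms t'_a t_a), ssy (A explained class
#   variance: SSY_a = q_a^2 t'_a t_a, i.e. the drop in y'y at deflation a).
pls1_fit <- function(Xc, yc, A, keep_scores = FALSE) {
  p <- ncol(Xc)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- numeric(A); tt <- numeric(A); ssy <- numeric(A)
  TT <- if (keep_scores) matrix(0, nrow(Xc), A) else NULL
  a_used <- 0L
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w * w))
    if (wn < 1e-12) break                       # X carries no further class info
    w <- w / wn
    j <- which.max(abs(w))                      # sign convention: largest
    if (w[j] < 0) w <- -w                       # element positive
    t <- Xc %*% w
    t2 <- sum(t * t)
    if (t2 < 1e-12) break
    pl <- crossprod(Xc, t) / t2
    q <- sum(yc * t) / t2
    Xc <- Xc - t %*% t(pl)
    yc <- yc - q * t
    W[, a] <- w; P[, a] <- pl; Q[a] <- q; tt[a] <- t2; ssy[a] <- q * q * t2
    if (keep_scores) TT[, a] <- t
    a_used <- a
  }
  list(W = W, P = P, Q = Q, tt = tt, ssy = ssy, scores = TT, A = a_used)
}

# Regression coefficients of the fitted PLS1 model using a components:
# B = W (P'W)^-1 Q. Small a, so the solve is cheap.
pls1_coef <- function(fit, a = fit$A) {
  if (a < 1) stop_data("model has no usable components")
  Wa <- fit$W[, seq_len(a), drop = FALSE]
  R <- crossprod(fit$P[, seq_len(a), drop = FALSE], Wa)
  drop(Wa %*% solve(R, fit$Q[seq_len(a)]))
}

# VIP from the internal fit pieces (weights already unit-norm).
pls1_vip <- function(fit, a = fit$A) {
  ssy <- fit$ssy[seq_len(a)]
  tot <- sum(ssy)
  if (tot <= 0) stop_data("zero explained class variance; model uninformative")
  W2 <- fit$W[, seq_len(a), drop = FALSE]^2
  sqrt(nrow(W2) * drop(W2 %*% ssy) / tot)
}

#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a two-class PLS-DA model by regressing the numeric class coding
#' (first level -1, second level +1; `occasional` / `chronic` keep that
#' order regardless of factor level sorting) on the feature matrix via
#' NIPALS deflation. Columns of `X` are mean-centred; the coded response is
#' mean-centred (unweighted). Each weight vector is sign-fixed so its
#' largest-magnitude element is positive, making fits reproducible.
#'
#' @param X Numeric matrix (samples x features) or an
#'   [`analysis_matrix`][preprocess_study()] (its `groups` then supply `y`).
#' @param y Class labels: factor or character with exactly two levels.
#' @param n_components Number of latent components (capped at the usable
#'   rank with a warning).
#' @return Object of class `"plsda"` with weights, loadings, scores,
#'   y-loadings, the class coding, per-component explained class variance
#'   `SSY`, and the centring constants.
#' @seealso [vip()], [predict.plsda()], [rdcv_plsda()]
#' @export
plsda <- function(X, y = NULL, n_components = 2) {
  if (inherits(X, "analysis_matrix")) {
    y <- y %||% X$groups
    X <- X$values
  }
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_data("need at least 2 samples")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2)
    stop_data("exactly two classes required, got %d", nlevels(y))
  lev <- levels(y)
  if (setequal(lev, c("occasional", "chronic"))) lev <- c("occasional", "chronic")
  coding <- stats::setNames(c(-1, 1), lev)
  yn <- coding[as.character(y)]
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    n_components <- min(nrow(X) - 1, ncol(X))
    warning(sprintf("n_components reduced to %d", n_components))
  }
  xm <- colMeans(X); ym <- mean(yn)
  fit <- pls1_fit(sweep(X, 2, xm), yn - ym, n_components, keep_scores = TRUE)
  if (fit$A < n_components)
    warning(sprintf("only %d informative component(s) extracted", fit$A))
  if (fit$A == 0) stop_data("no informative components; X is orthogonal to the classes")
  a <- seq_len(fit$A)
  fnames <- colnames(X) %||% as.character(seq_len(ncol(X)))
  dimnames(fit$W) <- dimnames(fit$P) <- list(fnames, NULL)
  structure(list(
    n_components = fit$A,
    x_weights = fit$W[, a, drop = FALSE],
    x_loadings = fit$P[, a, drop = FALSE],
    x_scores = fit$scores[, a, drop = FALSE],
    y_loadings = fit$Q[a],
    score_norms = fit$tt[a],
    SSY = fit$ssy[a],
    explained_y_variance = fit$ssy[a] / sum((yn - ym)^2),
    class_coding = coding,
    majority_class = names(coding)[which.max(tabulate(match(as.character(y), names(coding))))],
    x_center = xm, y_center = ym,
    feature_names = colnames(X) %||% as.character(seq_len(ncol(X))),
    y = y, call = match.call()),
    class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %d components over %d features, n = %d\n",
              x$n_components, length(x$feature_names), nrow(x$x_scores)))
  cat(sprintf("  classes: %s (-1) vs %s (+1)\n",
              names(x$class_coding)[1], names(x$class_coding)[2]))
  cat("  explained class variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_y_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.plsda <- function(object, n_components = object$n_components, ...) {
  fit <- list(W = object$x_weights, P = object$x_loadings, Q = object$y_loadings,
              A = object$n_components)
  b <- pls1_coef(fit, n_components)
  stats::setNames(c(object$y_center - sum(object$x_center * b), b),
                  c("(Intercept)", object$feature_names))
}

#' Predict classes from a fitted PLS-DA model
#'
#' The continuous prediction is the regression prediction of the +/-1 class
#' coding; the label is its sign (exact zeros fall to the majority training
#' class).
#'
#' @param object A `"plsda"` fit.
#' @param newdata Matrix with the training features (matched by name when
#'   both are named).
#' @param type `"class"`, `"response"` (continuous score), or `"both"`.
#' @param n_components Components to use (default: all fitted).
#' @param ... Unused.
#' @return Factor of labels, numeric scores, or a data frame with both.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("class", "response", "both"),
                          n_components = object$n_components, ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    if (!setequal(colnames(newdata), object$feature_names))
      stop_data("newdata features do not match the training features")
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop_data("newdata has %d features; model expects %d",
              ncol(newdata), length(object$feature_names))
  }
  cf <- coef(object, n_components)
  resp <- drop(newdata %*% cf[-1]) + unname(cf[1])
  if (type == "response") return(resp)
  lab <- ifelse(resp > 0, names(object$class_coding)[2],
                ifelse(resp < 0, names(object$class_coding)[1], object$majority_class))
  lab <- factor(lab, levels = names(object$class_coding))
  if (type == "class") lab else data.frame(class = lab, response = resp)
}

#' Variable Importance in Projection
#'
#' VIP for feature j over the A fitted components:
#' \deqn{VIP_j = \sqrt{p \, \sum_a SSY_a w_{aj}^2 / \sum_a SSY_a}}
#' with unit-norm weight vectors \eqn{w_a}, feature count \eqn{p}, and
#' \eqn{SSY_a} the class variance explained by component a (the drop in the
#' deflated response's sum of squares, \eqn{q_a^2 t_a' t_a}). The squared
#' scores average to 1 over features.
#'
#' @param model A fitted `"plsda"` model.
#' @param ... Passed to methods.
#' @return Named numeric vector of VIP scores (all non-negative).
#' @export
vip <- function(model, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.plsda <- function(model, ...) {
  fit <- list(W = model$x_weights, ssy = model$SSY, A = model$n_components)
  stats::setNames(pls1_vip(fit), model$feature_names)
}
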