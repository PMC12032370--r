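#' Append ratio features to a study
#'
#' Ratio features are computed per sample on the raw concentration scale,
#' before any transformation, as numerator / denominator. A ratio is missing
#' whenever either side is missing; non-positive denominators yield a missing
#' value and a warning reporting how many were hit.
#'
#' @param tables A `"study_tables"` object.
#' @param ratio_definitions Data frame with columns `name`, `numerator`,
#'   `denominator`; defaults to the definitions carried in `tables$config`.
#' @return `tables` with ratio rows appended to the measurement table.
#' @export
compute_ratios <- function(tables, ratio_definitions = NULL) {
  defs <- ratio_definitions %||% tables$config$ratio_definitions
  if (is.null(defs) || !nrow(defs)) return(tables)
  m <- tables$measurements
  mets <- unique(m$metabolite)
  bad <- setdiff(c(defs$numerator, defs$denominator), mets)
  if (length(bad)) stop_config("ratio definition references unknown metabolite '%s'", bad[1])
  if (any(defs$name %in% mets))
    stop_config("ratio name '%s' collides with an existing feature",
                intersect(defs$name, mets)[1])

  key <- paste(m$subject, m$treatment, m$time, sep = "\r")
  ukey <- unique(key)
  n_bad_den <- 0L
  blocks <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    num <- m[m$metabolite == defs$numerator[i], ]
    den <- m[m$metabolite == defs$denominator[i], ]
    knum <- paste(num$subject, num$treatment, num$time, sep = "\r")
    kden <- paste(den$subject, den$treatment, den$time, sep = "\r")
    nv <- num$concentration[match(ukey, knum)]
    dv <- den$concentration[match(ukey, kden)]
    nonpos <- !is.na(dv) & dv <= 0
    n_bad_den <- n_bad_den + sum(nonpos & !is.na(nv))
    dv[nonpos] <- NA_real_
    val <- nv / dv
    uk <- num[match(ukey, knum), c("subject", "treatment", "time")]
    blocks[[i]] <- data.frame(uk, metabolite = defs$name[i], concentration = val,
                              missing = is.na(val), stringsAsFactors = FALSE,
                              row.names = NULL)
  }
  extra <- do.call(rbind, blocks)
  if (!is.null(m$truth)) extra$truth <- NA_real_
  if (n_bad_den > 0)
    warning(sprintf("%d ratio values dropped (non-positive denominator)", n_bad_den))
  tables$measurements <- rbind(m, extra[names(m)])
  tables$ratios <- defs
  tables
}

# Long measurement table -> samples x features matrix (raw scale), with a
# sample-key data frame. Feature order follows first appearance.
measurements_to_matrix <- function(m) {
  feats <- unique(m$metabolite)
  key <- paste(m$subject, m$treatment, m$time, sep = "\r")
  ukey <- unique(key)
  parts <- m[match(ukey, key), c("subject", "treatment", "time")]
  rownames(parts) <- NULL
  dup <- duplicated(paste(key, m$metabolite, sep = "\r"))
  if (any(dup))
    stop_schema("duplicate (subject, treatment, time, metabolite) entries (e.g. row %d)",
                which(dup)[1])
  x <- matrix(NA_real_, length(ukey), length(feats),
              dimnames = list(NULL, feats))
  x[cbind(match(key, ukey), match(m$metabolite, feats))] <- m$concentration
  list(values = x, sample_keys = parts)
}

#' Elementwise natural-log transform
#'
#' Missing entries stay missing; zeros are treated as below-quantification
#' artefacts and set to missing (with a message); negative values are a data
#' error naming the offending cell.
#'
#' @param x Numeric matrix (samples x features).
#' @return The log-transformed matrix.
#' @export
log_transform <- function(x) {
  neg <- which(!is.na(x) & x < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    cn <- colnames(x) %||% as.character(seq_len(ncol(x)))
    stop_data("negative concentration at sample %d, feature '%s'",
              neg[1, 1], cn[neg[1, 2]])
  }
  zero <- !is.na(x) & x == 0
  if (any(zero)) {
    message(sprintf("%d zero values treated as missing before log transform", sum(zero)))
    x[zero] <- NA_real_
  }
  log(x)
}

#' Pareto scaling
#'
#' Centres each feature by its mean and divides by the square root of its
#' standard deviation (computed with the usual n-1 denominator, ignoring
#' missing entries). Gentler than autoscaling: high-abundance features are
#' shrunk less aggressively.
#'
#' @param x Numeric matrix (samples x features), at least 2 rows.
#' @param drop_zero_variance Drop constant features with a warning instead of
#'   erroring (the pipeline default).
#' @return Scaled matrix with attributes `center` and `scale` recording the
#'   per-feature mean and sqrt-SD, sufficient to invert the scaling.
#' @export
pareto_scale <- function(x, drop_zero_variance = FALSE) {
  if (nrow(x) < 2) stop_data("Pareto scaling needs at least 2 samples")
  ctr <- colMeans(x, na.rm = TRUE)
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sds) | sds == 0
  if (any(const)) {
    nm <- (colnames(x) %||% as.character(seq_len(ncol(x))))[const]
    if (!drop_zero_variance)
      stop_data("zero-variance feature(s): %s", paste(nm, collapse = ", "))
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    sum(const), paste(nm, collapse = ", ")))
    x <- x[, !const, drop = FALSE]; ctr <- ctr[!const]; sds <- sds[!const]
  }
  sc <- sqrt(sds)
  out <- sweep(sweep(x, 2, ctr), 2, sc, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sc
  out
}

#' EM-PCA imputation of missing values
#'
#' Fills missing cells by expectation-maximisation around a truncated
#' singular value decomposition: the E-step replaces missing cells with their
#' current rank-`n_components` reconstruction, the M-step re-fits the SVD on
#' the completed matrix. Observed cells are never altered. Intended to run on
#' log-transformed, Pareto-scaled data.
#'
#' @param x Numeric matrix with `NA`s marking missing cells.
#' @param n_components Rank of the reconstruction (default 5); must be
#'   smaller than both dimensions.
#' @param max_iter,tol Convergence control: stop when the root-mean-square
#'   change of the imputed cells falls below `tol`, or after `max_iter`
#'   sweeps (the result then carries `converged = FALSE`).
#' @return The completed matrix, with attribute `convergence` (list:
#'   `converged`, `iterations`, `delta`, `n_imputed`).
#' @export
impute_ppca <- function(x, n_components = 5, max_iter = 200, tol = 1e-6) {
  if (n_components >= min(dim(x)))
    stop_config("n_components (%d) must be below min(dim) = %d",
                n_components, min(dim(x)))
  miss <- is.na(x)
  if (!any(miss)) {
    attr(x, "convergence") <- list(converged = TRUE, iterations = 0L,
                                   delta = 0, n_imputed = 0L)
    return(x)
  }
  if (any(rowSums(!miss) == 0)) stop_data("row with no observed values")
  if (any(colSums(!miss) == 0)) stop_data("column with no observed values")

  filled <- x
  ctr <- colMeans(x, na.rm = TRUE)
  filled[miss] <- ctr[col(x)[miss]]
  delta <- Inf; it <- 0L
  while (it < max_iter && delta >= tol) {
    it <- it + 1L
    mu <- colMeans(filled)
    sv <- svd(sweep(filled, 2, mu), nu = n_components, nv = n_components)
    recon <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
    recon <- sweep(recon, 2, mu, "+")
    new_vals <- recon[miss]
    delta <- sqrt(mean((new_vals - filled[miss])^2))
    filled[miss] <- new_vals
  }
  out <- x                       # observed cells bit-exact from the input
  out[miss] <- filled[miss]
  attr(out, "convergence") <- list(converged = delta < tol, iterations = it,
                                   delta = delta, n_imputed = sum(miss))
  out
}

#' Principal component overview of a complete matrix
#'
#' Quality-control PCA: singular value decomposition of the column-centred
#' matrix, returning component scores and explained-variance fractions.
#'
#' @param x Complete numeric matrix (samples x features).
#' @param n_components Number of components (truncated to the matrix rank
#'   with a warning if larger).
#' @return List with `scores` (samples x components) and `explained`
#'   (non-increasing fractions summing to at most 1).
#' @export
qc_pca <- function(x, n_components = 2) {
  if (anyNA(x)) stop_data("qc_pca requires a complete matrix; impute first")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  pos <- sum(sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1])
  if (n_components > pos) {
    warning(sprintf("n_components reduced to the matrix rank (%d)", pos))
    n_components <- pos
  }
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  explained <- (sv$d^2 / sum(sv$d^2))[seq_len(n_components)]
  list(scores = scores, explained = explained)
}

#' Build the analysis matrix from a study
#'
#' Runs the fixed preprocessing pipeline: ratio features (raw scale), wide
#' reshaping, zeros-to-missing + natural log, Pareto scaling (constant
#' features dropped with a warning), and EM-PCA imputation of whatever is
#' missing. The applied transforms are recorded so that observed cells can be
#' mapped back to the raw scale.
#'
#' With `samples = "baseline"` the two sessions' pre-dose (time 0) draws are
#' averaged per subject on the raw scale, giving one fingerprint per subject
#' -- the input of the user-group classifier.
#'
#' @param tables A `"study_tables"` object.
#' @param samples `"all"` (every subject x treatment x time sample) or
#'   `"baseline"` (one averaged pre-dose sample per subject).
#' @param include_ratios Append the configured ratio features first.
#' @param n_components,max_iter,tol Passed to [impute_ppca()].
#' @return An object of class `"analysis_matrix"`: list with `values`
#'   (transformed samples x features), `sample_keys`, `feature_names`,
#'   `groups` (per-sample user group), and `transform_record`.
#' @export
preprocess_study <- function(tables, samples = c("all", "baseline"),
                             include_ratios = TRUE,
                             n_components = 5, max_iter = 200, tol = 1e-6) {
  samples <- match.arg(samples)
  if (include_ratios && is.null(tables$ratios))
    tables <- compute_ratios(tables)
  wide <- measurements_to_matrix(tables$measurements)
  x <- wide$values; keys <- wide$sample_keys

  if (samples == "baseline") {
    base <- keys$time == min(keys$time)
    x <- x[base, , drop = FALSE]; keys <- keys[base, , drop = FALSE]
    subj <- unique(keys$subject)
    xb <- matrix(NA_real_, length(subj), ncol(x), dimnames = list(NULL, colnames(x)))
    for (i in seq_along(subj))
      xb[i, ] <- colMeans(x[keys$subject == subj[i], , drop = FALSE], na.rm = TRUE)
    xb[is.nan(xb)] <- NA_real_
    x <- xb
    keys <- data.frame(subject = subj, treatment = "baseline", time = min(tables$measurements$time),
                       stringsAsFactors = FALSE)
  }

  lx <- log_transform(x)
  sx <- pareto_scale(lx, drop_zero_variance = TRUE)
  dropped <- setdiff(colnames(x), colnames(sx))
  vals <- impute_ppca(sx, n_components = min(n_components, min(dim(sx)) - 1),
                      max_iter = max_iter, tol = tol)
  conv <- attr(vals, "convergence")
  attr(vals, "convergence") <- NULL

  groups <- tables$subjects$group[match(keys$subject, tables$subjects$subject)]
  structure(list(
    values = vals,
    sample_keys = keys,
    feature_names = colnames(vals),
    groups = groups,
    transform_record = list(
      steps = c(if (include_ratios) "ratios", "log", "pareto", "impute"),
      center = attr(sx, "center"), scale = attr(sx, "scale"),
      dropped_features = dropped, impute = conv,
      samples = samples)),
    class = "analysis_matrix")
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat("<analysis_matrix>\n")
  cat(sprintf("  %d samples x %d features (%s)\n", nrow(x$values), ncol(x$values),
              x$transform_record$samples))
  cat(sprintf("  transforms: %s; %d cells imputed\n",
              paste(x$transform_record$steps, collapse = " -> "),
              x$transform_record$impute$n_imputed))
  invisible(x)
}

#' Map an analysis matrix back to the raw concentration scale
#'
#' Inverts the recorded Pareto scaling and log transform. Only meaningful for
#' cells that were observed (imputed cells come back on the concentration
#' scale of the model reconstruction).
#'
#' @param am An `"analysis_matrix"`.
#' @return Matrix of raw-scale concentrations.
#' @export
invert_transforms <- function(am) {
  r <- am$transform_record
  exp(sweep(sweep(am$values, 2, r$scale, "*"), 2, r$center, "+"))
}
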