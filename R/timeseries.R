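#' Mixed-effects model of one metabolite's post-dose kinetics
#'
#' Fits, within one user group, the crossover kinetics model for a single
#' metabolite: fixed effects for Treatment, (categorical) post-dose Time and
#' their interaction, a subject random intercept, and a first-order
#' autoregressive correlation structure within each subject-by-treatment
#' series, estimated by REML (via [nlme::lme()]). Two baseline handling
#' modes are available: the pre-dose (time 0) value of each series as a
#' covariate (`"covariate"`), or subtracting it from the series
#' (`"subtract"`, a baseline-corrected response). Each fixed term is
#' summarised by a Wald chi-square
#' \eqn{W = \hat\beta' V^{-1} \hat\beta} over its coefficients.
#'
#' @param data Long data frame for one metabolite and one group, with
#'   columns `subject`, `treatment`, `time`, `value`. The response is
#'   expected on the log-concentration scale; rows with missing values are
#'   dropped.
#' @param baseline_mode `"covariate"` or `"subtract"`.
#' @param treatments Treatment labels, reference first; defaults to the
#'   order of appearance.
#' @return Object of class `"metabolite_mixed"`: `coefficients`, `vcov`,
#'   `wald` (term, W, df, p), `rho`, `sigma_subject`, `sigma_resid`,
#'   `converged`, plus bookkeeping for [posthoc_per_timepoint()].
#' @export
fit_metabolite_mixed <- function(data, baseline_mode = c("covariate", "subtract"),
                                 treatments = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  need <- c("subject", "treatment", "time", "value")
  if (!all(need %in% names(data))) stop_schema("data must have columns %s",
                                               paste(need, collapse = ", "))
  data <- data[!is.na(data$value), , drop = FALSE]
  treatments <- treatments %||% unique(data$treatment)
  t0 <- min(data$time)
  post_times <- sort(unique(data$time[data$time > t0]))
  if (length(post_times) < 1) stop_data("no post-dose timepoints")

  base <- data[data$time == t0, ]
  key <- function(d) paste(d$subject, d$treatment, sep = "\r")
  post <- data[data$time > t0, , drop = FALSE]
  post$baseline <- base$value[match(key(post), key(base))]
  n_drop <- length(unique(post$subject[is.na(post$baseline)]))
  if (n_drop > 0) {
    warning(sprintf("%d subject series dropped (missing baseline)", n_drop))
    post <- post[!is.na(post$baseline), , drop = FALSE]
  }
  both <- tapply(post$treatment, post$subject, function(t) length(unique(t)))
  if (sum(both == 2, na.rm = TRUE) < 2)
    stop_data("need at least 2 subjects observed under both treatments")

  post$treatment <- factor(post$treatment, levels = treatments)
  post$time_f <- factor(post$time, levels = post_times)
  post$tidx <- match(post$time, post_times)
  post$subject <- factor(post$subject)
  one_time <- length(post_times) == 1   # no Time terms with a single level
  if (baseline_mode == "covariate") {
    post$baseline_c <- post$baseline - mean(post$baseline)
    fixed <- if (one_time) value ~ treatment + baseline_c
             else value ~ treatment * time_f + baseline_c
  } else {
    post$value <- post$value - post$baseline
    fixed <- if (one_time) value ~ treatment else value ~ treatment * time_f
  }

  corr <- if (one_time) NULL else           # AR(1) needs >= 2 points per series
    nlme::corAR1(form = ~ tidx | subject / treatment)
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | subject, correlation = corr,
              data = post, method = "REML",
              control = nlme::lmeControl(maxIter = 100, msMaxIter = 100,
                                         returnObject = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(converged = FALSE, message = conditionMessage(fit),
                          baseline_mode = baseline_mode, post_times = post_times,
                          treatments = treatments),
                     class = "metabolite_mixed"))
  }

  beta <- nlme::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  asg <- attr(stats::model.matrix(fixed, post), "assign")
  labels <- attr(stats::terms(fixed), "term.labels")
  wald <- do.call(rbind, lapply(seq_along(labels), function(i) {
    idx <- which(asg == i)
    W <- drop(crossprod(beta[idx], solve(V[idx, idx, drop = FALSE], beta[idx])))
    data.frame(term = labels[i], W = W, df = length(idx),
               p = stats::pchisq(W, length(idx), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  # readable term names: treatment / time / treatment:time / baseline
  wald$term <- sub("^treatment:time_f$", "treatment:time", wald$term)
  wald$term <- sub("^time_f$", "time", wald$term)
  wald$term <- sub("^baseline_c$", "baseline", wald$term)
  rownames(wald) <- NULL

  vc <- nlme::VarCorr(fit)
  structure(list(
    coefficients = beta, vcov = V, wald = wald,
    rho = if (one_time) NA_real_ else
      unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE)),
    sigma_subject = suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"])),
    sigma_resid = fit$sigma,
    logLik = as.numeric(stats::logLik(fit)),
    converged = TRUE,
    baseline_mode = baseline_mode,
    post_times = post_times, treatments = treatments,
    n_subjects = nlevels(post$subject), n_obs = nrow(post)),
    class = "metabolite_mixed")
}

#' @export
print.metabolite_mixed <- function(x, ...) {
  cat("<metabolite_mixed>")
  if (!x$converged) {
    cat(" NOT CONVERGED:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(" %d subjects, %d observations, baseline mode '%s'\n",
              x$n_subjects, x$n_obs, x$baseline_mode))
  cat(sprintf("  AR(1) rho = %.3f; sd(subject) = %.3g; sd(resid) = %.3g\n",
              x$rho, x$sigma_subject, x$sigma_resid))
  print(x$wald, digits = 3)
  invisible(x)
}

#' Treatment contrasts per post-dose timepoint
#'
#' Active-minus-reference treatment difference at each post-dose timepoint,
#' with Wald standard errors from the coefficient covariance: the contrast
#' at time t combines the treatment main effect with the t-specific
#' interaction coefficient.
#'
#' @param result A converged [fit_metabolite_mixed()] result.
#' @return Data frame with `time`, `estimate`, `se`, `p`.
#' @export
posthoc_per_timepoint <- function(result) {
  if (!inherits(result, "metabolite_mixed")) stop_data("not a metabolite_mixed result")
  if (!isTRUE(result$converged)) stop_data("model did not converge; no contrasts")
  beta <- result$coefficients; V <- result$vcov
  nm <- names(beta)
  trt_col <- paste0("treatment", result$treatments[2])
  out <- lapply(result$post_times, function(t) {
    cvec <- stats::setNames(numeric(length(beta)), nm)
    cvec[trt_col] <- 1
    int_col <- paste0(trt_col, ":time_f", t)
    if (int_col %in% nm) cvec[int_col] <- 1
    est <- sum(cvec * beta)
    se <- sqrt(drop(crossprod(cvec, V %*% cvec)))
    data.frame(time = t, estimate = est, se = se,
               p = 2 * stats::pnorm(-abs(est / se)))
  })
  do.call(rbind, out)
}

#' Per-metabolite kinetics screen within a user group
#'
#' Fits the AR(1) crossover mixed model to every metabolite of one user
#' group (on log concentrations), collects Wald statistics for the
#' Treatment main effect and the Treatment-by-Time interaction, and adjusts
#' both across metabolites with the two-level hierarchical FDR over the
#' panel's chemical families. Metabolites whose fit fails are recorded with
#' `converged = FALSE` and excluded from the adjustment (with a warning);
#' they never abort the screen.
#'
#' @param tables A `"study_tables"` object.
#' @param group `"occasional"` or `"chronic"`.
#' @param baseline_mode Passed to [fit_metabolite_mixed()].
#' @param q FDR level (default 0.05).
#' @param family_map Optional data frame (`feature`, `family`) overriding
#'   the families carried by the panel configuration.
#' @param metabolites Optional subset of metabolites to screen.
#' @param contrasts Attach per-timepoint contrasts for metabolites whose
#'   adjusted interaction p-value falls below `q`.
#' @return Data frame sorted by adjusted Treatment p-value, one row per
#'   metabolite: `W_treatment`, `p_treatment`, `p_adj_treatment`,
#'   `W_interaction`, `p_interaction`, `p_adj_interaction`, `rho`,
#'   `converged`. Contrast tables, if requested, are in attribute
#'   `"contrasts"`.
#' @export
run_timeseries_screen <- function(tables, group,
                                  baseline_mode = c("covariate", "subtract"),
                                  q = 0.05, family_map = NULL,
                                  metabolites = NULL, contrasts = FALSE) {
  baseline_mode <- match.arg(baseline_mode)
  subj <- tables$subjects$subject[tables$subjects$group == group]
  m <- tables$measurements[tables$measurements$subject %in% subj, ]
  mets <- metabolites %||% unique(m$metabolite)
  if (!length(mets))
    return(data.frame(metabolite = character(), W_treatment = numeric(),
                      p_treatment = numeric(), p_adj_treatment = numeric(),
                      W_interaction = numeric(), p_interaction = numeric(),
                      p_adj_interaction = numeric(), rho = numeric(),
                      converged = logical()))

  fam <- panel_family_map(tables, family_map)
  fits <- vector("list", length(mets))
  names(fits) <- mets
  for (met in mets) {
    d <- m[m$metabolite == met & !is.na(m$concentration) & m$concentration > 0, ]
    d <- data.frame(subject = d$subject, treatment = d$treatment,
                    time = d$time, value = log(d$concentration))
    fits[[met]] <- tryCatch(
      fit_metabolite_mixed(d, baseline_mode, treatments = tables$config$treatments),
      error = function(e) structure(list(converged = FALSE,
                                         message = conditionMessage(e)),
                                    class = "metabolite_mixed"))
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!ok))
    warning(sprintf("%d metabolite fit(s) failed and are excluded from FDR: %s",
                    sum(!ok), paste(utils::head(mets[!ok], 5), collapse = ", ")))

  pick <- function(f, term, col) {
    if (!isTRUE(f$converged)) return(NA_real_)
    f$wald[[col]][f$wald$term == term]
  }
  out <- data.frame(
    metabolite = mets,
    W_treatment = vapply(fits, pick, numeric(1), "treatment", "W"),
    p_treatment = vapply(fits, pick, numeric(1), "treatment", "p"),
    p_adj_treatment = NA_real_,
    W_interaction = vapply(fits, pick, numeric(1), "treatment:time", "W"),
    p_interaction = vapply(fits, pick, numeric(1), "treatment:time", "p"),
    p_adj_interaction = NA_real_,
    rho = vapply(fits, function(f) if (isTRUE(f$converged)) f$rho else NA_real_,
                 numeric(1)),
    converged = ok, stringsAsFactors = FALSE)
  rownames(out) <- NULL

  if (any(ok)) {
    fam_ok <- fam[match(mets[ok], fam$feature), "family"]
    fam_ok[is.na(fam_ok)] <- "other"
    out$p_adj_treatment[ok] <-
      hierarchical_fdr(out$p_treatment[ok], fam_ok, q = q)$hypotheses$p_adj
    out$p_adj_interaction[ok] <-
      hierarchical_fdr(out$p_interaction[ok], fam_ok, q = q)$hypotheses$p_adj
  }
  out <- out[order(out$p_adj_treatment, out$p_treatment), ]
  rownames(out) <- NULL
  if (contrasts) {
    sig <- out$metabolite[!is.na(out$p_adj_interaction) & out$p_adj_interaction < q]
    attr(out, "contrasts") <- lapply(stats::setNames(sig, sig), function(met)
      posthoc_per_timepoint(fits[[met]]))
  }
  out
}

# feature -> chemical family lookup, from an explicit map or the panel config
panel_family_map <- function(tables, family_map = NULL) {
  if (!is.null(family_map)) {
    names(family_map)[1:2] <- c("feature", "family")
    return(family_map)
  }
  if (!is.null(tables$config)) {
    specs <- tables$config$metabolites
    fam <- data.frame(
      feature = vapply(specs, function(s) s$name, character(1)),
      family = vapply(specs, function(s) s$family, character(1)),
      stringsAsFactors = FALSE)
    if (!is.null(tables$ratios))
      fam <- rbind(fam, data.frame(feature = tables$ratios$name, family = "Ratio"))
    return(fam)
  }
  feats <- unique(tables$measurements$metabolite)
  data.frame(feature = feats, family = "all", stringsAsFactors = FALSE)
}
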