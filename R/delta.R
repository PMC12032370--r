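#' Change scores linking behaviour to metabolite shifts
#'
#' Behavioural change scores are active-minus-placebo differences at matched
#' timepoints (attentional lapses at 10 and 30 min, subjective high at 20
#' and 40 min). Metabolite change scores are post-dose minus baseline within
#' the active session at 10 and 30 min; with
#' `baseline = "placebo_corrected"` the same difference computed in the
#' placebo session is additionally subtracted. Subjects missing any needed
#' sample are excluded from the affected score with a logged reason.
#'
#' @param tables A `"study_tables"` object.
#' @param baseline `"cannabis"` (the active session's own baseline, the
#'   default) or `"placebo_corrected"`.
#' @return Object of class `"delta_table"`: data frames `behavior`
#'   (`subject`, `behavior`, `time`, `delta`), `metabolites` (`subject`,
#'   `metabolite`, `time`, `delta`), and `covariates` (`subject`, `group`,
#'   `age`, `sex`, `thc_baseline`), plus the behaviour-to-metabolite
#'   timepoint pairing.
#' @export
compute_deltas <- function(tables, baseline = c("cannabis", "placebo_corrected")) {
  baseline <- match.arg(baseline)
  trt <- tables$config$treatments %||% unique(tables$measurements$treatment)
  if (setequal(trt, c("placebo", "cannabis"))) trt <- c("placebo", "cannabis")
  active <- trt[2]; placebo <- trt[1]
  beh <- tables$behavior

  one_beh <- function(col, times) {
    out <- list()
    for (t in times) {
      a <- beh[beh$time == t & beh$treatment == active, ]
      p <- beh[beh$time == t & beh$treatment == placebo, ]
      subj <- union(a$subject, p$subject)
      av <- a[[col]][match(subj, a$subject)]
      pv <- p[[col]][match(subj, p$subject)]
      d <- av - pv
      keep <- !is.na(d)
      out[[length(out) + 1]] <- data.frame(subject = subj[keep], behavior = col,
                                           time = t, delta = d[keep],
                                           stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  lapse_times <- intersect(c(10, 30), unique(beh$time))
  high_times <- intersect(c(20, 40), unique(beh$time))
  behavior <- rbind(one_beh("lapses", lapse_times), one_beh("high", high_times))

  m <- tables$measurements
  t0 <- min(m$time)
  met_times <- intersect(c(10, 30), unique(m$time))
  key <- function(d) paste(d$subject, d$metabolite, sep = "\r")
  session_delta <- function(session, t) {
    b <- m[m$treatment == session & m$time == t0, ]
    x <- m[m$treatment == session & m$time == t, ]
    d <- x$concentration - b$concentration[match(key(x), key(b))]
    data.frame(subject = x$subject, metabolite = x$metabolite, delta = d,
               stringsAsFactors = FALSE)
  }
  mets <- list()
  for (t in met_times) {
    d <- session_delta(active, t)
    if (baseline == "placebo_corrected") {
      dp <- session_delta(placebo, t)
      d$delta <- d$delta - dp$delta[match(paste(d$subject, d$metabolite),
                                          paste(dp$subject, dp$metabolite))]
    }
    keep <- !is.na(d$delta)
    mets[[length(mets) + 1]] <- data.frame(d[keep, c("subject", "metabolite")],
                                           time = t, delta = d$delta[keep])
  }
  metabolites <- do.call(rbind, mets)
  if (!nrow(behavior) && !nrow(metabolites %||% data.frame()))
    stop_data("no complete subjects: no change score could be formed")

  covariates <- data.frame(
    subject = tables$subjects$subject, group = tables$subjects$group,
    age = tables$subjects$age, sex = tables$subjects$sex,
    thc_baseline = tables$subjects$thc_baseline_cannabis,
    stringsAsFactors = FALSE)

  structure(list(behavior = behavior, metabolites = metabolites,
                 covariates = covariates,
                 pairing = c("10" = 10, "30" = 30, "20" = 10, "40" = 30),
                 baseline = baseline),
            class = "delta_table")
}

#' @export
print.delta_table <- function(x, ...) {
  cat("<delta_table>\n")
  cat(sprintf("  %d behavioural change scores (%s)\n", nrow(x$behavior),
              paste(unique(x$behavior$behavior), collapse = ", ")))
  cat(sprintf("  %d metabolite change scores over %d features (baseline: %s)\n",
              nrow(x$metabolites), length(unique(x$metabolites$metabolite)),
              x$baseline))
  invisible(x)
}

#' Association model of one metabolite's change with one behavioural change
#'
#' Gaussian identity-link model within one stratum (user group x behaviour
#' x timepoint): behavioural change score regressed on the metabolite change
#' score with age, sex, and baseline THC as covariates. Constant covariates
#' (e.g. THC in occasional users, zero by design) are dropped automatically
#' and recorded; a constant metabolite change score yields a flagged
#' degenerate result rather than an error. Strata with fewer than
#' `min_cases` complete cases are reported as not estimable.
#'
#' @param deltas A [compute_deltas()] result.
#' @param metabolite,behavior,group,timepoint Stratum selectors; `timepoint`
#'   is the behavioural timepoint (10/30 for lapses, 20/40 for high), paired
#'   with the metabolite change at the nearest preceding blood draw.
#' @param min_cases Minimum complete cases (default 6).
#' @return Object of class `"delta_association"`: `estimate`, `se`, `p` for
#'   the metabolite-change coefficient, covariate coefficients, `n`, and
#'   flags `estimable` / `degenerate` / `dropped_covariates`.
#' @export
fit_delta_association <- function(deltas, metabolite, behavior, group,
                                  timepoint, min_cases = 6) {
  met_time <- deltas$pairing[[as.character(timepoint)]]
  if (is.null(met_time)) stop_config("unknown behavioural timepoint %s", timepoint)
  b <- deltas$behavior[deltas$behavior$behavior == behavior &
                         deltas$behavior$time == timepoint, ]
  m <- deltas$metabolites[deltas$metabolites$metabolite == metabolite &
                            deltas$metabolites$time == met_time, ]
  cov <- deltas$covariates[deltas$covariates$group == group, ]
  df <- data.frame(subject = cov$subject,
                   y = b$delta[match(cov$subject, b$subject)],
                   x = m$delta[match(cov$subject, m$subject)],
                   age = cov$age,
                   sex = as.numeric(factor(cov$sex)) - 1,
                   thc = cov$thc_baseline)
  df <- df[stats::complete.cases(df), ]
  base <- list(metabolite = metabolite, behavior = behavior, group = group,
               timepoint = timepoint, met_time = met_time, n = nrow(df))
  if (nrow(df) < min_cases)
    return(structure(c(base, list(estimable = FALSE, degenerate = FALSE,
                                  estimate = NA_real_, se = NA_real_, p = NA_real_,
                                  dropped_covariates = character())),
                     class = "delta_association"))
  if (stats::sd(df$x) == 0)
    return(structure(c(base, list(estimable = FALSE, degenerate = TRUE,
                                  estimate = NA_real_, se = NA_real_, p = NA_real_,
                                  dropped_covariates = character())),
                     class = "delta_association"))
  covars <- c("age", "sex", "thc")
  dropped <- covars[vapply(covars, function(v) stats::sd(df[[v]]) == 0, logical(1))]
  covars <- setdiff(covars, dropped)
  form <- stats::reformulate(c("x", covars), response = "y")
  fit <- stats::lm(form, data = df)
  sm <- summary(fit)$coefficients
  est <- if ("x" %in% rownames(sm)) sm["x", ] else rep(NA_real_, 4)
  structure(c(base, list(
    estimable = is.finite(est[4]), degenerate = !("x" %in% rownames(sm)) || !is.finite(est[4]),
    estimate = unname(est[1]), se = unname(est[2]), p = unname(est[4]),
    covariate_coefficients = stats::coef(fit)[covars],
    dropped_covariates = dropped)),
    class = "delta_association")
}

#' @export
print.delta_association <- function(x, ...) {
  cat(sprintf("<delta_association> %s ~ d[%s] | %s, %d min (n = %d)\n",
              x$behavior, x$metabolite, x$group, x$timepoint, x$n))
  if (!x$estimable) cat("  not estimable",
                        if (x$degenerate) "(degenerate predictor)", "\n")
  else cat(sprintf("  coefficient %.4g (se %.3g), p = %.3g\n", x$estimate, x$se, x$p))
  invisible(x)
}

#' Full change-score association screen
#'
#' Iterates every stratum (user group x behaviour x behavioural timepoint)
#' over all metabolites, fits the Gaussian association model, and adjusts
#' p-values within each stratum with the two-level hierarchical FDR over
#' chemical families. Not-estimable or degenerate strata are emitted with
#' `NA` p-values and excluded from the adjustment.
#'
#' @param deltas A [compute_deltas()] result.
#' @param tables The originating `"study_tables"` (for family labels);
#'   optional if `family_map` is given.
#' @param q FDR level.
#' @param family_map Optional `feature`/`family` data frame.
#' @param metabolites Optional subset of metabolites.
#' @param min_cases Passed to [fit_delta_association()].
#' @return Tidy data frame, one row per test: stratum identifiers,
#'   `estimate`, `se`, `p`, `p_adj`, `n`, `estimable`.
#' @export
run_delta_screen <- function(deltas, tables = NULL, q = 0.05,
                             family_map = NULL, metabolites = NULL,
                             min_cases = 6) {
  mets <- metabolites %||% unique(deltas$metabolites$metabolite)
  fam <- if (!is.null(tables) || !is.null(family_map))
    panel_family_map(tables %||% list(measurements = data.frame(metabolite = mets)),
                     family_map)
  else data.frame(feature = mets, family = "all", stringsAsFactors = FALSE)

  strata <- expand.grid(group = unique(deltas$covariates$group),
                        behavior = unique(deltas$behavior$behavior),
                        stringsAsFactors = FALSE)
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    bt <- unique(deltas$behavior$time[deltas$behavior$behavior == strata$behavior[s]])
    for (t in bt) {
      res <- lapply(mets, function(met)
        fit_delta_association(deltas, met, strata$behavior[s], strata$group[s],
                              t, min_cases = min_cases))
      p <- vapply(res, `[[`, numeric(1), "p")
      ok <- is.finite(p)
      p_adj <- rep(NA_real_, length(p))
      if (any(ok)) {
        f <- fam$family[match(mets[ok], fam$feature)]
        f[is.na(f)] <- "other"
        p_adj[ok] <- hierarchical_fdr(p[ok], f, q = q)$hypotheses$p_adj
      }
      rows[[length(rows) + 1]] <- data.frame(
        metabolite = mets, group = strata$group[s], behavior = strata$behavior[s],
        timepoint = t,
        estimate = vapply(res, `[[`, numeric(1), "estimate"),
        se = vapply(res, `[[`, numeric(1), "se"),
        p = p, p_adj = p_adj,
        n = vapply(res, `[[`, numeric(1), "n"),
        estimable = vapply(res, `[[`, logical(1), "estimable"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
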