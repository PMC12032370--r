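#' Describe one metabolite of a synthetic study panel
#'
#' A metabolite specification carries the per-group baseline distribution
#' (mean and SD of the concentration in ng/mL), an optional kinetic
#' treatment-effect profile (additive shifts of the log concentration at
#' post-dose timepoints under active treatment), and an optional lower limit
#' of quantification.
#'
#' @param name Metabolite identifier.
#' @param family Chemical family label (e.g. `"TRP metabolism"`,
#'   `"Ceramide"`); used as the grouping level of the hierarchical FDR.
#' @param mean,sd Baseline concentration mean and SD in ng/mL. Either single
#'   numbers (both groups identical, a "null" metabolite) or named vectors
#'   with entries `occasional` and `chronic`.
#' @param treatment_effect `NULL`, or a named list `group -> named numeric`
#'   giving additive log-scale shifts under the active treatment, names being
#'   post-dose timepoints in minutes (e.g. `list(occasional = c("10" = 0.3))`).
#' @param lloq Optional lower limit of quantification (ng/mL); generated
#'   values below it are flagged missing.
#' @return An object of class `"metabolite_spec"`.
#' @seealso [study_config()], [generate_study()]
#' @export
metabolite_spec <- function(name, family, mean, sd,
                            treatment_effect = NULL, lloq = NULL) {
  groups <- c("occasional", "chronic")
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, 2), groups)
    if (!all(groups %in% names(x)))
      stop_config("metabolite '%s': %s must name both groups", name, what)
    x[groups]
  }
  mean <- expand(mean, "mean"); sd <- expand(sd, "sd")
  if (any(sd <= 0)) stop_config("metabolite '%s': SDs must be strictly positive", name)
  if (any(mean < 0)) stop_config("metabolite '%s': means must be non-negative", name)
  if (!is.null(treatment_effect)) {
    if (!is.list(treatment_effect) || is.null(names(treatment_effect)))
      stop_config("metabolite '%s': treatment_effect must be a named list by group", name)
    bad <- setdiff(names(treatment_effect), groups)
    if (length(bad)) stop_config("metabolite '%s': unknown group '%s'", name, bad[1])
  }
  structure(list(name = name, family = family,
                 mean_by_group = mean, sd_by_group = sd,
                 treatment_effect = treatment_effect, lloq = lloq),
            class = "metabolite_spec")
}

#' @export
print.metabolite_spec <- function(x, ...) {
  cat(sprintf("<metabolite_spec> %s [%s]\n", x$name, x$family))
  cat(sprintf("  occasional %.4g +/- %.4g ng/mL; chronic %.4g +/- %.4g ng/mL\n",
              x$mean_by_group["occasional"], x$sd_by_group["occasional"],
              x$mean_by_group["chronic"], x$sd_by_group["chronic"]))
  if (!is.null(x$treatment_effect))
    cat("  kinetic treatment effect on:", paste(names(x$treatment_effect), collapse = ", "), "\n")
  invisible(x)
}

# The 14 discriminant metabolites with their published per-group baseline
# means and SDs (ng/mL). These are the only non-synthetic panel parameters.
discriminant_panel <- function() {
  t1 <- list(
    # name, family, chronic mean, chronic sd, occasional mean, occasional sd
    list("tyrosine",        "AAA metabolism",       9120.561, 2380.824, 11893.329, 2150.541),
    list("phenylalanine",   "AAA metabolism",       8691.477, 1702.35,  10246.299, 1089.711),
    list("Cer(d18:1/14:0)", "Ceramide",             17.391,   7.164,    12.825,    4.917),
    list("kynurenine",      "TRP metabolism",       298.725,  56.794,   365.111,   75.766),
    list("kynurenic acid",  "TRP metabolism",       6.663,    2.064,    8.999,     2.663),
    list("2-AG",            "Endocannabinoid",      0.553,    0.319,    0.744,     0.219),
    list("2-OG",            "Endocannabinoid",      3.642,    1.613,    4.626,     1.827),
    list("TMAO",            "Amine oxide",          28.396,   16.148,   48.527,    30.33),
    list("creatine",        "Protein metabolism",   1727.957, 1263.148, 2959.971,  1702.267),
    list("valine",          "BCAA metabolism",      20920.237, 8692.164, 30634.526, 12981.122),
    list("5HIAA",           "TRP metabolism",       2.55,     1.935,    4.241,     3.799),
    list("leucine",         "BCAA metabolism",      16703.03, 4198.31,  19634.586, 4386.404),
    list("hexanoic acid",   "Saturated fatty acid", 9.299,    3.548,    7.151,     2.164),
    list("5b-THF",          "Steroid",              0.466,    0.254,    0.732,     0.448))
  chronic_amino_effect <- c("10" = 0.04, "30" = 0.08, "50" = 0.16, "70" = 0.22)
  lapply(t1, function(r) {
    eff <- if (r[[1]] %in% c("tyrosine", "leucine"))
      list(chronic = chronic_amino_effect) else NULL
    metabolite_spec(r[[1]], r[[2]],
                    mean = c(occasional = r[[5]], chronic = r[[3]]),
                    sd   = c(occasional = r[[6]], chronic = r[[4]]),
                    treatment_effect = eff)
  })
}

# Named stand-in metabolites (synthetic parameters throughout): the organic
# acids that respond to the active treatment in occasional users, the amino
# acid responding in chronic users, and the lipids that couple to behaviour.
named_standin_panel <- function() {
  occ_acid_effect <- function(scale = 1)
    list(occasional = c("10" = 0.22, "30" = 0.30, "50" = 0.22, "70" = 0.12) * scale)
  specs <- list(
    metabolite_spec("beta-hydroxybutyrate", "Organic acid", 5200, 1800,
                    treatment_effect = list(occasional = c("10" = 0.35, "30" = 0.45,
                                                           "50" = 0.40, "70" = 0.30))),
    metabolite_spec("lactic acid",           "Organic acid", 90000, 25000, treatment_effect = occ_acid_effect()),
    metabolite_spec("malic acid",            "Organic acid", 280,   80,    treatment_effect = occ_acid_effect()),
    metabolite_spec("succinic acid",         "Organic acid", 520,   150,   treatment_effect = occ_acid_effect(0.9)),
    metabolite_spec("isocitric acid",        "Organic acid", 610,   170,   treatment_effect = occ_acid_effect(0.9)),
    metabolite_spec("glutaric acid",         "Organic acid", 45,    14,    treatment_effect = occ_acid_effect(1.1)),
    metabolite_spec("alpha-hydroxybutyrate", "Organic acid", 3100,  900,   treatment_effect = occ_acid_effect()),
    metabolite_spec("alpha-hydroxyglutarate","Organic acid", 160,   45,    treatment_effect = occ_acid_effect(0.9)),
    metabolite_spec("isoleucine", "BCAA metabolism", 7800, 2100,
                    treatment_effect = list(chronic = c("10" = 0.05, "30" = 0.10,
                                                        "50" = 0.20, "70" = 0.25))),
    metabolite_spec("tryptophan",          "TRP metabolism", 13000, 2600),
    metabolite_spec("HexCer(d18:1/22:0)",  "Hexosylceramide", 62,   18),
    metabolite_spec("HexCer(d18:1/24:0)",  "Hexosylceramide", 48,   15),
    metabolite_spec("HexCer(d18:1/24:1)",  "Hexosylceramide", 38,   12),
    metabolite_spec("Cer(d18:1/20:0)",     "Ceramide",        8.4,  2.6),
    metabolite_spec("LPC(16:0)",           "Lysophospholipid", 52000, 12000),
    metabolite_spec("LPC(18:0)",           "Lysophospholipid", 21000, 6000),
    metabolite_spec("2-LG",                "Endocannabinoid",  11.5, 4.2),
    metabolite_spec("PEA",                 "Endocannabinoid",  3.3,  1.1),
    metabolite_spec("DEA",                 "Endocannabinoid",  0.9,  0.3),
    metabolite_spec("cortexolone",         "Steroid",          1.8,  0.7))
  specs
}

#' Default 91-metabolite panel
#'
#' The 14 discriminant metabolites carry their published per-group baseline
#' means/SDs; all remaining panel members are synthetic stand-ins (the
#' published supplementary panel is not reproduced): named stand-ins for the
#' kinetically responsive organic acids / amino acids and the
#' behaviour-coupled lipids, plus generic null biomarkers whose common
#' (group-independent) mean and CV are drawn once from a hyperrange under a
#' fixed panel seed, so the default panel is a constant.
#'
#' @param n_total Total panel size (default 91).
#' @param panel_seed Seed for the one-off draw of the generic null
#'   parameters; fixed by default so the default panel never changes.
#' @return List of [metabolite_spec()] objects.
#' @export
default_metabolite_panel <- function(n_total = 91, panel_seed = 104729L) {
  fixed <- c(discriminant_panel(), named_standin_panel())
  n_null <- n_total - length(fixed)
  if (n_null < 0) stop_config("n_total smaller than the fixed panel (%d)", length(fixed))
  nulls <- with_seed(panel_seed, {
    fams <- c("Lipid", "Organic acid", "Amine", "Steroid", "Carboxylic acid",
              "Nucleoside", "Acylcarnitine", "Bile acid")
    lapply(seq_len(n_null), function(i) {
      m <- 10^stats::runif(1, 0, 4)          # 1 .. 10,000 ng/mL, log-uniform
      cv <- stats::runif(1, 0.2, 0.6)
      metabolite_spec(sprintf("biomarker_%02d", i), fams[(i - 1) %% length(fams) + 1],
                      mean = m, sd = cv * m)
    })
  })
  c(fixed, nulls)
}

#' Default ratio feature definitions
#'
#' 22 numerator/denominator pairs over the default panel. Synthetic
#' stand-ins: the published ratio list is not reproduced.
#'
#' @return Data frame with columns `name`, `numerator`, `denominator`.
#' @export
default_ratio_definitions <- function() {
  pairs <- list(
    c("kynurenine", "tryptophan"), c("kynurenic acid", "kynurenine"),
    c("5HIAA", "tryptophan"), c("tyrosine", "phenylalanine"),
    c("leucine", "isoleucine"), c("valine", "leucine"),
    c("2-AG", "2-OG"), c("2-LG", "2-AG"),
    c("LPC(16:0)", "LPC(18:0)"),
    c("HexCer(d18:1/22:0)", "Cer(d18:1/14:0)"),
    c("HexCer(d18:1/24:0)", "Cer(d18:1/14:0)"),
    c("beta-hydroxybutyrate", "alpha-hydroxybutyrate"),
    c("lactic acid", "malic acid"), c("succinic acid", "malic acid"),
    c("isocitric acid", "succinic acid"), c("glutaric acid", "succinic acid"),
    c("creatine", "tyrosine"), c("TMAO", "creatine"),
    c("5b-THF", "cortexolone"), c("PEA", "DEA"),
    c("Cer(d18:1/20:0)", "Cer(d18:1/14:0)"), c("hexanoic acid", "lactic acid"))
  data.frame(name = vapply(pairs, function(p) paste(p, collapse = "/"), character(1)),
             numerator = vapply(pairs, `[`, character(1), 1),
             denominator = vapply(pairs, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Default behaviour coupling
#'
#' Couples the change in the two hexosylceramide stand-ins (active-session
#' post-dose minus active-session baseline, ng/mL) to attentional lapses at
#' 10 and 30 min and to subjective high at 20 min, in occasional users only.
#' Coefficients are per ng/mL of metabolite change, additive on the expected
#' count (lapses) or on the rating (high).
#'
#' @return Data frame with columns `metabolite`, `behavior`, `time`,
#'   `group`, `beta`.
#' @export
default_behavior_coupling <- function() {
  hex <- c("HexCer(d18:1/22:0)", "HexCer(d18:1/24:0)")
  rbind(
    data.frame(metabolite = hex, behavior = "lapses", time = 10, group = "occasional", beta = 0.5),
    data.frame(metabolite = hex, behavior = "lapses", time = 30, group = "occasional", beta = 0.4),
    data.frame(metabolite = hex, behavior = "high",   time = 20, group = "occasional", beta = 0.15))
}

#' Declarative configuration of a synthetic crossover study
#'
#' Defaults mirror the emulated trial: 18 occasional and 17 chronic users,
#' a placebo-controlled crossover with blood draws at 0/10/30/50/70 min,
#' 91 metabolites (14 carrying the published group differences) plus 22
#' ratio features, attentional lapses measured at 10/30 min and subjective
#' high at 20/40 min, and residual baseline THC in chronic users only.
#'
#' @param n_occasional,n_chronic Group sizes (default 18 / 17).
#' @param metabolites List of [metabolite_spec()]s (default
#'   [default_metabolite_panel()]).
#' @param ratio_definitions Data frame of ratio features
#'   (default [default_ratio_definitions()]); `NULL` for none.
#' @param timepoints Blood-draw times in minutes, strictly increasing,
#'   starting at 0.
#' @param treatments Treatment labels; the second is the active one.
#' @param ar1_rho Lag-1 autocorrelation of within-series log-scale noise,
#'   in `[0, 1)`.
#' @param residual_cv Within-subject (measurement-to-measurement)
#'   coefficient of variation of the concentration.
#' @param between_subject_cv Random-intercept CV used where a metabolite's
#'   configured total SD leaves no room for the within-subject part.
#' @param missing_rate MCAR missingness applied by [generate_study()]
#'   (default 0; see [inject_missingness()] for explicit control).
#' @param behavior_coupling Data frame coupling metabolite changes to
#'   behaviour (default [default_behavior_coupling()]); `NULL` for none.
#' @param thc_baseline_chronic Mean and SD (ng/mL) of residual baseline THC
#'   in chronic users.
#' @param seed Integer seed; `NULL` draws from the ambient RNG.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(n_occasional = 18, n_chronic = 17,
                         metabolites = default_metabolite_panel(),
                         ratio_definitions = default_ratio_definitions(),
                         timepoints = c(0, 10, 30, 50, 70),
                         treatments = c("placebo", "cannabis"),
                         ar1_rho = 0.4, residual_cv = 0.1,
                         between_subject_cv = 0.2,
                         missing_rate = 0,
                         behavior_coupling = default_behavior_coupling(),
                         thc_baseline_chronic = c(mean = 2.99, sd = 2.42),
                         seed = NULL) {
  cfg <- structure(list(n_occasional = n_occasional, n_chronic = n_chronic,
                        metabolites = metabolites, ratio_definitions = ratio_definitions,
                        timepoints = timepoints, treatments = treatments,
                        ar1_rho = ar1_rho, residual_cv = residual_cv,
                        between_subject_cv = between_subject_cv,
                        missing_rate = missing_rate,
                        behavior_coupling = behavior_coupling,
                        thc_baseline_chronic = thc_baseline_chronic,
                        seed = seed),
                   class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  n_occasional <- cfg$n_occasional; n_chronic <- cfg$n_chronic
  metabolites <- cfg$metabolites; ratio_definitions <- cfg$ratio_definitions
  timepoints <- cfg$timepoints; treatments <- cfg$treatments
  ar1_rho <- cfg$ar1_rho; missing_rate <- cfg$missing_rate
  behavior_coupling <- cfg$behavior_coupling
  if (n_occasional < 2 || n_chronic < 2)
    stop_config("each group needs at least 2 subjects (design error)")
  if (ar1_rho < 0 || ar1_rho >= 1) stop_config("ar1_rho must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop_config("missing_rate must lie in [0, 1)")
  if (length(timepoints) < 1 || timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE))
    stop_config("timepoints must be strictly increasing and start at 0")
  if (length(treatments) != 2) stop_config("exactly two treatment labels required")
  if (!length(metabolites)) stop_config("metabolite panel is empty")
  nm <- vapply(metabolites, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop_config("duplicate metabolite name '%s'", nm[duplicated(nm)][1])
  post <- as.character(timepoints[-1])
  for (s in metabolites) {
    for (g in names(s$treatment_effect)) {
      bad <- setdiff(names(s$treatment_effect[[g]]), post)
      if (length(bad))
        stop_config("metabolite '%s': treatment effect at non-post-dose time %s",
                    s$name, bad[1])
    }
  }
  if (!is.null(ratio_definitions) && nrow(ratio_definitions)) {
    missing_ref <- setdiff(c(ratio_definitions$numerator, ratio_definitions$denominator), nm)
    if (length(missing_ref))
      stop_config("ratio definition references unknown metabolite '%s'", missing_ref[1])
  }
  if (!is.null(behavior_coupling) && nrow(behavior_coupling)) {
    bad <- setdiff(behavior_coupling$metabolite, nm)
    if (length(bad)) stop_config("behavior coupling references unknown metabolite '%s'", bad[1])
  }
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  groups: %d occasional, %d chronic\n", x$n_occasional, x$n_chronic))
  cat(sprintf("  panel: %d metabolites + %d ratios\n", length(x$metabolites),
              if (is.null(x$ratio_definitions)) 0L else nrow(x$ratio_definitions)))
  cat(sprintf("  timepoints (min): %s; treatments: %s\n",
              paste(x$timepoints, collapse = ", "), paste(x$treatments, collapse = " / ")))
  cat(sprintf("  ar1_rho = %.3g, residual_cv = %.3g, missing_rate = %.3g, seed = %s\n",
              x$ar1_rho, x$residual_cv, x$missing_rate,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

# Log-scale variance decomposition for one metabolite/group: total variance
# from the configured concentration CV, within-subject part from
# residual_cv; whatever is left is the between-subject intercept variance.
# If the configured total leaves no room, the between-subject CV takes over.
variance_split <- function(mean, sd, residual_cv, between_subject_cv) {
  s_tot2 <- log(1 + (sd / mean)^2)
  s_e2 <- log(1 + residual_cv^2)
  if (s_e2 < s_tot2) {
    s_b2 <- s_tot2 - s_e2
  } else {
    s_b2 <- log(1 + between_subject_cv^2)
    s_tot2 <- s_b2 + s_e2
  }
  mu <- log(mean) - s_tot2 / 2
  c(mu = mu, sigma_b = sqrt(s_b2), sigma_e = sqrt(s_e2))
}

#' Generate a complete synthetic crossover study
#'
#' Draws subject demographics, per-metabolite concentration time series under
#' both treatments, and behavioural outcomes, following the configured study
#' design. Baseline concentrations are log-normal with moments matched to
#' each metabolite's configured per-group mean/SD; post-dose series add the
#' configured log-scale treatment effects and stationary AR(1) within-series
#' noise; attentional lapses are Poisson counts and subjective high a
#' truncated linear rating, both optionally coupled to metabolite changes.
#' Deterministic given `config$seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `"study_tables"`: list with data frames
#'   `subjects`, `measurements` (long format), `behavior`, plus the `config`.
#' @examples
#' cfg <- study_config(n_occasional = 4, n_chronic = 4,
#'                     metabolites = default_metabolite_panel()[1:5],
#'                     ratio_definitions = NULL, seed = 1)
#' tab <- generate_study(cfg)
#' head(tab$measurements)
#' @export
generate_study <- function(config) {
  if (!inherits(config, "study_config")) stop_config("config must be a study_config")
  validate_study_config(config)
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(config) {
  groups <- c(rep("occasional", config$n_occasional), rep("chronic", config$n_chronic))
  n <- length(groups)
  subject <- c(sprintf("occ%02d", seq_len(config$n_occasional)),
               sprintf("chr%02d", seq_len(config$n_chronic)))
  tp <- config$timepoints; ntp <- length(tp)
  trt <- config$treatments; active <- trt[2]

  ## -- subjects ------------------------------------------------------------
  age <- sample(18:28, n, replace = TRUE)
  sex <- rep_len(c("M", "F"), n)[sample.int(n)]
  thc <- matrix(0, n, 2, dimnames = list(NULL, trt))
  chr <- which(groups == "chronic")
  lp <- lognormal_params(config$thc_baseline_chronic[["mean"]],
                         config$thc_baseline_chronic[["sd"]])
  for (s in trt) thc[chr, s] <- stats::rlnorm(length(chr), lp["mu"], lp["sigma"])
  subjects <- data.frame(subject = subject, group = groups, age = age, sex = sex,
                         thc_baseline_placebo = thc[, 1],
                         thc_baseline_cannabis = thc[, 2],
                         stringsAsFactors = FALSE)

  ## -- metabolite series ---------------------------------------------------
  # one row per subject x treatment x time, metabolite-major blocks
  n_series <- n * 2                      # subject x treatment
  series_subj <- rep(seq_len(n), times = 2)
  series_trt <- rep(trt, each = n)
  specs <- config$metabolites
  p <- length(specs)
  conc_all <- matrix(NA_real_, n_series * ntp, p)
  for (j in seq_len(p)) {
    s <- specs[[j]]
    pars <- vapply(c("occasional", "chronic"), function(g)
      variance_split(s$mean_by_group[[g]], s$sd_by_group[[g]],
                     config$residual_cv, config$between_subject_cv),
      numeric(3))
    mu_i <- pars["mu", groups] + pars["sigma_b", groups] * stats::rnorm(n)
    e <- ar1_noise(n_series, ntp, config$ar1_rho, 1)
    e <- e * pars["sigma_e", groups[series_subj]]     # scale rows by group
    lx <- matrix(mu_i[series_subj], n_series, ntp) + e
    # additive log-scale kinetic effects under the active treatment
    for (g in names(s$treatment_effect)) {
      eff <- s$treatment_effect[[g]]
      rows <- which(series_trt == active & groups[series_subj] == g)
      cols <- match(as.numeric(names(eff)), tp)
      for (k in seq_along(cols)) lx[rows, cols[k]] <- lx[rows, cols[k]] + eff[k]
    }
    conc_all[, j] <- as.vector(exp(lx))   # series-major within metabolite
  }

  # index layout: for metabolite j, rows are (series, time) with series fastest
  idx_series <- rep(seq_len(n_series), times = ntp)
  idx_time <- rep(tp, each = n_series)
  measurements <- data.frame(
    subject = rep(subject[series_subj[idx_series]], times = p),
    treatment = rep(series_trt[idx_series], times = p),
    time = rep(idx_time, times = p),
    metabolite = rep(vapply(specs, function(s) s$name, character(1)), each = n_series * ntp),
    concentration = as.vector(conc_all),
    stringsAsFactors = FALSE)
  measurements$missing <- FALSE

  # LLOQ censoring, if any metabolite declares one
  for (s in specs) {
    if (is.null(s$lloq)) next
    rows <- measurements$metabolite == s$name & measurements$concentration < s$lloq
    measurements$concentration[rows] <- NA_real_
    measurements$missing[rows] <- TRUE
  }

  ## -- behaviour -----------------------------------------------------------
  behavior <- generate_behavior(config, subjects, measurements)

  tables <- structure(list(subjects = subjects, measurements = measurements,
                           behavior = behavior, config = config),
                      class = "study_tables")

  if (config$missing_rate > 0)
    tables <- inject_missingness(tables, config$missing_rate, "mcar")
  tables
}

# Expected behavioural levels, before subject heterogeneity and coupling.
# Lapses: Poisson means (multiplicative treatment/time structure); high:
# 0-10 rating means. Values are synthetic design choices emulating an
# attentional deficit + strong subjective high in occasional users under the
# active treatment and a blunted response in chronic users.
behavior_baseline_levels <- function() {
  list(
    lapses = list(placebo = c("10" = 3.0, "30" = 3.0),
                  occasional = c("10" = 2.5, "30" = 2.2),   # multipliers
                  chronic = c("10" = 1.15, "30" = 1.1)),
    high = list(placebo = c("20" = 0.3, "40" = 0.3),
                occasional = c("20" = 6.0, "40" = 5.0),     # additive means
                chronic = c("20" = 4.5, "40" = 3.5)))
}

generate_behavior <- function(config, subjects, measurements) {
  tp <- config$timepoints
  lapse_times <- intersect(c(10, 30), tp[-1])
  high_times <- c(20, 40)[c(10, 30) %in% tp[-1]]   # paired with draws at 10/30
  if (!length(lapse_times) && !length(high_times))
    return(data.frame(subject = character(), treatment = character(),
                      time = numeric(), lapses = integer(), high = numeric()))
  lev <- behavior_baseline_levels()
  n <- nrow(subjects); trt <- config$treatments; active <- trt[2]
  b_lapse <- stats::rnorm(n, 0, sqrt(log(1 + config$between_subject_cv^2)))
  b_high <- stats::rnorm(n, 0, 0.4)

  # metabolite deltas (active session, post minus baseline) for coupling
  coup <- config$behavior_coupling
  delta_lookup <- function(met, t) {
    m <- measurements[measurements$metabolite == met &
                        measurements$treatment == active &
                        measurements$time %in% c(0, t), ]
    base <- m$concentration[match(paste(subjects$subject, 0), paste(m$subject, m$time))]
    post <- m$concentration[match(paste(subjects$subject, t), paste(m$subject, m$time))]
    post - base
  }

  rows <- list()
  for (s in trt) {
    for (t in c(lapse_times, high_times)) {
      is_lapse <- t %in% lapse_times
      key <- as.character(t)
      if (is_lapse) {
        lam <- lev$lapses$placebo[key] * exp(b_lapse)
        if (s == active)
          lam <- lam * ifelse(subjects$group == "occasional",
                              lev$lapses$occasional[key], lev$lapses$chronic[key])
      } else {
        mu <- lev$high$placebo[key] + b_high
        if (s == active)
          mu <- ifelse(subjects$group == "occasional",
                       lev$high$occasional[key], lev$high$chronic[key]) + b_high
      }
      # additive coupling to metabolite change, active session only
      if (s == active && !is.null(coup) && nrow(coup)) {
        sel <- coup[coup$behavior == ifelse(is_lapse, "lapses", "high") & coup$time == t, ]
        met_time <- if (is_lapse) t else c("20" = 10, "40" = 30)[key]
        for (k in seq_len(nrow(sel))) {
          d <- delta_lookup(sel$metabolite[k], met_time)
          contrib <- ifelse(subjects$group == sel$group[k], sel$beta[k] * d, 0)
          contrib[is.na(contrib)] <- 0
          if (is_lapse) lam <- lam + contrib else mu <- mu + contrib
        }
      }
      if (is_lapse) {
        val <- stats::rpois(n, pmax(lam, 0.05))
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects$subject, treatment = s, time = t,
          lapses = val, high = NA_real_, stringsAsFactors = FALSE)
      } else {
        val <- round(pmin(10, pmax(0, mu + stats::rnorm(n, 0, 0.8))), 1)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects$subject, treatment = s, time = t,
          lapses = NA_integer_, high = val, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$subject, out$treatment, out$time), , drop = FALSE]
}

#' @export
print.study_tables <- function(x, ...) {
  cat("<study_tables>\n")
  cat(sprintf("  %d subjects (%d occasional / %d chronic)\n", nrow(x$subjects),
              sum(x$subjects$group == "occasional"), sum(x$subjects$group == "chronic")))
  cat(sprintf("  %d measurements over %d features, %d flagged missing\n",
              nrow(x$measurements), length(unique(x$measurements$metabolite)),
              sum(x$measurements$missing)))
  cat(sprintf("  %d behavioural records\n", nrow(x$behavior)))
  invisible(x)
}

#' Flag measurements as missing
#'
#' Applies missing-completely-at-random or left-censoring missingness to the
#' measurement table, retaining the original value in a `truth` column so
#' imputation accuracy can be evaluated against it. With `rate = 0` the input
#' is returned unchanged.
#'
#' @param tables A `"study_tables"` object.
#' @param rate Proportion in `[0, 1)`.
#' @param mode `"mcar"` (each cell independently) or `"left_censor"` (the
#'   lowest `rate` quantile per metabolite).
#' @return The modified `"study_tables"`.
#' @export
inject_missingness <- function(tables, rate, mode = c("mcar", "left_censor")) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1) stop_config("missingness rate must lie in [0, 1)")
  if (rate == 0) return(tables)
  m <- tables$measurements
  if (is.null(m$truth)) m$truth <- m$concentration
  if (mode == "mcar") {
    hit <- stats::runif(nrow(m)) < rate & !m$missing
  } else {
    hit <- logical(nrow(m))
    for (met in unique(m$metabolite)) {
      rows <- which(m$metabolite == met & !m$missing)
      k <- floor(rate * length(rows))
      if (k > 0) hit[rows[order(m$concentration[rows])[seq_len(k)]]] <- TRUE
    }
  }
  m$concentration[hit] <- NA_real_
  m$missing <- m$missing | hit
  tables$measurements <- m
  tables
}
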