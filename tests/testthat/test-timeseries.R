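test_that("the REML fit agrees with an explicit GLS oracle at its estimates", {
  set.seed(101)
  d <- sim_kinetics(n_subj = 14, rho = 0.3)
  fit <- fit_metabolite_mixed(d, "covariate", treatments = c("placebo", "cannabis"))
  expect_true(fit$converged)

  # rebuild the post-dose frame exactly as the model sees it
  base <- d[d$time == 0, ]
  post <- d[d$time > 0, ]
  post$baseline <- base$value[match(paste(post$subject, post$treatment),
                                    paste(base$subject, base$treatment))]
  post$baseline_c <- post$baseline - mean(post$baseline)
  post$treatment <- factor(post$treatment, c("placebo", "cannabis"))
  post$time_f <- factor(post$time)
  post$tidx <- as.integer(post$time_f)
  oracle <- gls_oracle(value ~ treatment * time_f + baseline_c, post,
                       sigma_b = fit$sigma_subject, sigma_e = fit$sigma_resid,
                       rho = fit$rho)
  expect_equal(unname(fit$coefficients), unname(oracle$beta), tolerance = 1e-4)
  asg <- attr(model.matrix(value ~ treatment * time_f + baseline_c, post), "assign")
  for (term_i in unique(asg[asg > 0])) {
    idx <- which(asg == term_i)
    W_oracle <- wald_stat(oracle$beta, oracle$vcov, idx)
    expect_equal(fit$wald$W[term_i], W_oracle, tolerance = 1e-4)
  }
})

test_that("serially uncorrelated data yields a near-zero rho estimate", {
  # build data for which the covariate model is correctly specified: the
  # baseline is an independent covariate, not a noisy draw of the series
  set.seed(102)
  n_subj <- 20; times <- c(0, 10, 30, 50, 70)
  rows <- list()
  b <- rnorm(n_subj, 0, 0.3)
  for (i in seq_len(n_subj)) for (s in c("placebo", "cannabis")) {
    base <- rnorm(1, 5, 0.3)
    v <- c(base, 5 + b[i] + 0.6 * (base - 5) + rnorm(length(times) - 1, 0, 0.12))
    rows[[length(rows) + 1]] <- data.frame(subject = sprintf("s%02d", i),
                                           treatment = s, time = times, value = v)
  }
  fit <- fit_metabolite_mixed(do.call(rbind, rows), "covariate",
                              c("placebo", "cannabis"))
  expect_true(fit$converged)
  expect_lt(abs(fit$rho), 0.35)
})

test_that("duplicating subjects leaves estimates unchanged and shrinks SEs", {
  set.seed(103)
  d <- sim_kinetics(n_subj = 10, effect = c(0.2, 0.3, 0.2, 0.1))
  d2 <- d; d2$subject <- paste0(d2$subject, "_dup")
  fit1 <- fit_metabolite_mixed(d, "covariate", c("placebo", "cannabis"))
  fit2 <- fit_metabolite_mixed(rbind(d, d2), "covariate", c("placebo", "cannabis"))
  # REML variance estimates move slightly with n, so agreement is close but
  # not exact
  expect_equal(unname(fit2$coefficients), unname(fit1$coefficients),
               tolerance = 5e-3)
  expect_true(all(sqrt(diag(fit2$vcov)) < sqrt(diag(fit1$vcov))))
})

test_that("per-timepoint contrasts equal model cell-mean differences", {
  set.seed(104)
  d <- sim_kinetics(n_subj = 10, effect = c(0.4, 0.3, 0.2, 0.1))
  fit <- fit_metabolite_mixed(d, "covariate", c("placebo", "cannabis"))
  ct <- posthoc_per_timepoint(fit)
  expect_equal(ct$time, c(10, 30, 50, 70))
  # independent oracle: predicted cell means from explicit design rows
  beta <- fit$coefficients
  for (k in seq_along(ct$time)) {
    t <- ct$time[k]
    row_can <- row_pla <- setNames(numeric(length(beta)), names(beta))
    row_can["(Intercept)"] <- row_pla["(Intercept)"] <- 1
    if (paste0("time_f", t) %in% names(beta)) {
      row_can[paste0("time_f", t)] <- row_pla[paste0("time_f", t)] <- 1
    }
    row_can["treatmentcannabis"] <- 1
    ia <- paste0("treatmentcannabis:time_f", t)
    if (ia %in% names(beta)) row_can[ia] <- 1
    expect_equal(ct$estimate[k], sum((row_can - row_pla) * beta),
                 tolerance = 1e-10)
  }
  # the injected profile is recovered within its confidence bands
  expect_true(all(abs(ct$estimate - c(0.4, 0.3, 0.2, 0.1)) < 4 * ct$se))
})

test_that("a null treatment keeps the Treatment Wald test calibrated", {
  set.seed(105)
  ps <- replicate(60, {
    d <- sim_kinetics(n_subj = 10)
    f <- fit_metabolite_mixed(d, "covariate", c("placebo", "cannabis"))
    if (f$converged) f$wald$p[f$wald$term == "treatment"] else NA_real_
  })
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 50)
  expect_lt(abs(mean(ps) - 0.5), 3 * 0.29 / sqrt(length(ps)))
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / length(ps)) + 0.02)
})

test_that("with one timepoint the Treatment W equals the squared paired t", {
  set.seed(106)
  d <- sim_kinetics(n_subj = 12, times = c(0, 10), rho = 0,
                    effect = 0.25)
  fit <- fit_metabolite_mixed(d, "subtract", c("placebo", "cannabis"))
  resp <- d[d$time == 10, ]
  base <- d[d$time == 0, ]
  resp$value <- resp$value - base$value[match(paste(resp$subject, resp$treatment),
                                              paste(base$subject, base$treatment))]
  diffs <- resp$value[resp$treatment == "cannabis"][order(resp$subject[resp$treatment == "cannabis"])] -
    resp$value[resp$treatment == "placebo"][order(resp$subject[resp$treatment == "placebo"])]
  t_stat <- t.test(diffs)$statistic
  expect_equal(fit$wald$W[fit$wald$term == "treatment"], unname(t_stat^2),
               tolerance = 1e-4)
})

test_that("the screen recovers injected kinetics and stays quiet under the null", {
  panel <- default_metabolite_panel()[c(15:22, 35:46)]  # 8 responders + 12 nulls
  responders <- vapply(panel[1:8], function(s) s$name, character(1))
  tp <- integer(3)
  for (k in 1:3) {
    cfg <- study_config(n_occasional = 18, n_chronic = 2, metabolites = panel,
                        ratio_definitions = NULL, behavior_coupling = NULL,
                        seed = 200 + k)
    tab <- generate_study(cfg)
    scr <- run_timeseries_screen(tab, "occasional")
    hits <- scr$metabolite[!is.na(scr$p_adj_treatment) & scr$p_adj_treatment < 0.05]
    tp[k] <- length(intersect(hits, responders))
  }
  expect_gte(median(tp), 6)

  # all-null panel: few adjusted discoveries on average
  nulls <- lapply(panel, function(s) { s$treatment_effect <- NULL; s })
  disc <- integer(3)
  for (k in 1:3) {
    cfg <- study_config(n_occasional = 18, n_chronic = 2, metabolites = nulls,
                        ratio_definitions = NULL, behavior_coupling = NULL,
                        seed = 300 + k)
    tab <- generate_study(cfg)
    scr <- run_timeseries_screen(tab, "occasional")
    disc[k] <- sum(scr$p_adj_treatment < 0.05, na.rm = TRUE)
  }
  expect_lte(mean(disc), 0.05 * length(nulls) + 1)
})

test_that("an empty metabolite set yields an empty screen, not an error", {
  tab <- generate_study(small_study_config(seed = 1))
  out <- run_timeseries_screen(tab, "occasional", metabolites = character())
  expect_equal(nrow(out), 0)
})
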