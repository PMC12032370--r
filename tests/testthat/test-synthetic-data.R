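test_that("generation is reproducible given a seed and sensitive to it", {
  cfg <- small_study_config(seed = 11)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$behavior, b$behavior)
  cfg2 <- cfg; cfg2$seed <- 12
  expect_false(identical(generate_study(cfg2)$measurements$concentration,
                         a$measurements$concentration))
})

test_that("baseline draws match the configured moments at large n", {
  cfg <- study_config(n_chronic = 10000, n_occasional = 2,
                      metabolites = default_metabolite_panel()[1:3],
                      ratio_definitions = NULL, behavior_coupling = NULL,
                      seed = 7)
  tab <- generate_study(cfg)
  m <- tab$measurements
  for (met in c("tyrosine", "phenylalanine")) {
    spec <- Filter(function(s) s$name == met, cfg$metabolites)[[1]]
    v <- m$concentration[m$metabolite == met & m$time == 0 &
                           m$treatment == "placebo" &
                           m$subject %in% tab$subjects$subject[tab$subjects$group == "chronic"]]
    mu <- spec$mean_by_group[["chronic"]]; s <- spec$sd_by_group[["chronic"]]
    expect_equal(mean(v), mu, tolerance = 3 * s / sqrt(10000) / mu)
    # log-normal SD of the sample SD, roughly; generous 4-sigma band
    expect_lt(abs(sd(v) - s), 4 * s / sqrt(5000))
  }
})

test_that("within-series noise carries the configured lag-1 autocorrelation", {
  set.seed(31)
  e <- metabocross:::ar1_noise(10000, 5, 0.6, 1)
  ac <- cor(as.vector(e[, -5]), as.vector(e[, -1]))
  expect_equal(ac, 0.6, tolerance = 0.02 / 0.6)
  expect_equal(sd(as.vector(e)), 1, tolerance = 0.02)
  # time reversal leaves the lag-1 autocorrelation invariant
  er <- e[, 5:1]
  expect_equal(cor(as.vector(er[, -5]), as.vector(er[, -1])), ac, tolerance = 1e-12)
})

test_that("null effects make the two treatments exchangeable", {
  cfg <- study_config(n_occasional = 150, n_chronic = 150,
                      metabolites = default_metabolite_panel()[c(3, 6)],
                      ratio_definitions = NULL, behavior_coupling = NULL,
                      seed = 5)
  # panel members 3 and 6 carry no kinetic effect
  tab <- generate_study(cfg)
  m <- tab$measurements[tab$measurements$time > 0, ]
  for (met in unique(m$metabolite)) {
    a <- log(m$concentration[m$metabolite == met & m$treatment == "cannabis"])
    p <- log(m$concentration[m$metabolite == met & m$treatment == "placebo"])
    expect_lt(abs(mean(a) - mean(p)), 4 * sd(c(a, p)) / sqrt(length(a)))
  }
})

test_that("behavioural outcomes respect their ranges and structure", {
  tab <- generate_study(small_study_config(seed = 2, n_occ = 20, n_chr = 20))
  b <- tab$behavior
  lp <- b$lapses[!is.na(b$lapses)]
  expect_true(all(lp >= 0 & lp == round(lp)))
  hi <- b$high[!is.na(b$high)]
  expect_true(all(hi >= 0 & hi <= 10))
  expect_setequal(unique(b$time[!is.na(b$lapses)]), c(10, 30))
  expect_setequal(unique(b$time[!is.na(b$high)]), c(20, 40))
  # occasional users lapse more under the active treatment
  occ <- tab$subjects$subject[tab$subjects$group == "occasional"]
  can <- b$lapses[b$subject %in% occ & b$treatment == "cannabis" & !is.na(b$lapses)]
  pla <- b$lapses[b$subject %in% occ & b$treatment == "placebo" & !is.na(b$lapses)]
  expect_gt(mean(can), mean(pla))
})

test_that("chronic users carry positive baseline THC, occasional users none", {
  tab <- generate_study(small_study_config(seed = 9))
  s <- tab$subjects
  expect_true(all(s$thc_baseline_cannabis[s$group == "chronic"] > 0))
  expect_true(all(s$thc_baseline_cannabis[s$group == "occasional"] == 0))
})

test_that("behaviour coupling is recoverable by least squares at large n", {
  # one coupled metabolite, large occasional group, modest coupling so the
  # Poisson mean never gets floored
  met <- metabolite_spec("coupled", "Lipid", mean = 50, sd = 10)
  coup <- data.frame(metabolite = "coupled", behavior = "lapses", time = 10,
                     group = "occasional", beta = 0.3)
  cfg <- study_config(n_occasional = 400, n_chronic = 2,
                      metabolites = list(met), ratio_definitions = NULL,
                      behavior_coupling = coup, seed = 17)
  tab <- generate_study(cfg)
  occ <- tab$subjects$subject[tab$subjects$group == "occasional"]
  m <- tab$measurements
  d_met <- with(list(), {
    can <- m[m$treatment == "cannabis" & m$metabolite == "coupled", ]
    can$concentration[match(paste(occ, 10), paste(can$subject, can$time))] -
      can$concentration[match(paste(occ, 0), paste(can$subject, can$time))]
  })
  b <- tab$behavior
  d_lapse <- b$lapses[match(paste(occ, "cannabis", 10), paste(b$subject, b$treatment, b$time))] -
    b$lapses[match(paste(occ, "placebo", 10), paste(b$subject, b$treatment, b$time))]
  fit <- lm(d_lapse ~ d_met)
  ci <- confint(fit)["d_met", ]
  expect_gt(0.3, ci[1]); expect_lt(0.3, ci[2])
})

test_that("configuration invariants are enforced", {
  expect_error(study_config(n_occasional = 1), class = "mc_config_error")
  expect_error(study_config(ar1_rho = 1), class = "mc_config_error")
  expect_error(study_config(missing_rate = 1), class = "mc_config_error")
  expect_error(study_config(timepoints = c(10, 30)), class = "mc_config_error")
  expect_error(study_config(
    metabolites = default_metabolite_panel()[1:3],
    ratio_definitions = data.frame(name = "r", numerator = "tyrosine",
                                   denominator = "nonexistent")),
    class = "mc_config_error")
  expect_error(metabolite_spec("m", "f", mean = 1, sd = 0),
               class = "mc_config_error")
})

test_that("missingness injection behaves as configured", {
  tab <- generate_study(small_study_config(seed = 21, n_occ = 12, n_chr = 12))
  expect_identical(inject_missingness(tab, 0, "mcar"), tab)

  set.seed(4)
  mc <- inject_missingness(tab, 0.1, "mcar")
  frac <- mean(is.na(mc$measurements$concentration))
  n <- nrow(mc$measurements)
  expect_equal(frac, 0.1, tolerance = 3 * sqrt(0.1 * 0.9 / n) / 0.1)
  # hidden truth column retains every censored value
  expect_true(all(!is.na(mc$measurements$truth)))

  lc <- inject_missingness(tab, 0.1, "left_censor")
  m <- lc$measurements
  for (met in unique(m$metabolite)[1:5]) {
    rows <- m$metabolite == met
    censored <- m$truth[rows][m$missing[rows]]
    retained <- m$concentration[rows][!m$missing[rows]]
    expect_true(all(min(retained) >= max(censored)))
  }
  expect_error(inject_missingness(tab, 1, "mcar"), class = "mc_config_error")
})
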