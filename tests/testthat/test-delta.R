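# Minimal hand-built study for arithmetic checks.
tiny_study <- function() {
  subjects <- data.frame(subject = c("s1", "s2"), group = "occasional",
                         age = c(20, 24), sex = c("M", "F"),
                         thc_baseline_placebo = 0, thc_baseline_cannabis = 0)
  grid <- expand.grid(subject = c("s1", "s2"),
                      treatment = c("placebo", "cannabis"),
                      time = c(0, 10, 30), stringsAsFactors = FALSE)
  grid$metabolite <- "m1"
  grid$concentration <- c(10, 20, 10, 20,   # t0
                          12, 19, 15, 26,   # t10
                          11, 21, 13, 24)   # t30
  grid$missing <- FALSE
  behavior <- rbind(
    data.frame(subject = c("s1", "s2"), treatment = "placebo", time = 10,
               lapses = c(3L, 2L), high = NA_real_),
    data.frame(subject = c("s1", "s2"), treatment = "cannabis", time = 10,
               lapses = c(7L, 2L), high = NA_real_),
    data.frame(subject = c("s1", "s2"), treatment = "placebo", time = 20,
               lapses = NA_integer_, high = c(0.5, 1)),
    data.frame(subject = c("s1", "s2"), treatment = "cannabis", time = 20,
               lapses = NA_integer_, high = c(6, 1)))
  structure(list(subjects = subjects, measurements = grid, behavior = behavior,
                 config = NULL), class = "study_tables")
}

test_that("change scores are plain differences at matched timepoints", {
  d <- compute_deltas(tiny_study())
  dl <- d$behavior[d$behavior$behavior == "lapses" & d$behavior$time == 10, ]
  expect_equal(dl$delta[dl$subject == "s1"], 4)   # 7 - 3
  expect_equal(dl$delta[dl$subject == "s2"], 0)   # identical sessions
  dh <- d$behavior[d$behavior$behavior == "high", ]
  expect_equal(dh$delta[dh$subject == "s2"], 0)
  dm <- d$metabolites
  expect_equal(dm$delta[dm$subject == "s1" & dm$time == 10], 15 - 10)
  expect_equal(dm$delta[dm$subject == "s2" & dm$time == 30], 24 - 20)
})

test_that("swapping treatment labels negates every behavioural delta", {
  tab <- tiny_study()
  d1 <- compute_deltas(tab)
  tab2 <- tab
  tab2$behavior$treatment <- ifelse(tab2$behavior$treatment == "placebo",
                                    "cannabis", "placebo")
  tab2$measurements$treatment <- ifelse(tab2$measurements$treatment == "placebo",
                                        "cannabis", "placebo")
  d2 <- compute_deltas(tab2)
  m <- match(paste(d1$behavior$subject, d1$behavior$behavior, d1$behavior$time),
             paste(d2$behavior$subject, d2$behavior$behavior, d2$behavior$time))
  expect_equal(d2$behavior$delta[m], -d1$behavior$delta)
})

test_that("placebo-corrected metabolite deltas subtract the placebo drift", {
  tab <- tiny_study()
  d <- compute_deltas(tab, baseline = "placebo_corrected")
  dm <- d$metabolites
  # s1, 10 min: (15 - 10) - (12 - 10) = 3
  expect_equal(dm$delta[dm$subject == "s1" & dm$time == 10], 3)
})

test_that("the association model recovers an injected coupling with honest CIs", {
  met <- metabolite_spec("coupled", "Lipid", mean = 50, sd = 10)
  coup <- data.frame(metabolite = "coupled", behavior = "lapses", time = 10,
                     group = "occasional", beta = 0.3)
  covered <- logical(200)
  set.seed(55)
  for (r in seq_len(200)) {
    cfg <- study_config(n_occasional = 30, n_chronic = 2,
                        metabolites = list(met), ratio_definitions = NULL,
                        behavior_coupling = coup, seed = sample.int(1e6, 1))
    tab <- generate_study(cfg)
    d <- compute_deltas(tab)
    f <- fit_delta_association(d, "coupled", "lapses", "occasional", 10)
    ci <- f$estimate + c(-1, 1) * qt(0.975, f$n - 4) * f$se
    covered[r] <- ci[1] <= 0.3 && 0.3 <= ci[2]
  }
  expect_gt(mean(covered), 0.89)
  expect_lt(mean(covered), 0.995)
})

test_that("degenerate strata are flagged, never fatal", {
  tab <- tiny_study()
  tab$measurements$concentration[tab$measurements$time > 0] <-
    tab$measurements$concentration[tab$measurements$time == 0]
  d <- compute_deltas(tab)
  # constant (all-zero) metabolite delta -> degenerate, and n < 6 anyway
  f <- fit_delta_association(d, "m1", "lapses", "occasional", 10, min_cases = 2)
  expect_false(f$estimable)
  f2 <- fit_delta_association(d, "m1", "lapses", "occasional", 10)
  expect_false(f2$estimable)
  expect_equal(f2$n, 2)
})

test_that("constant covariates are dropped and recorded", {
  met <- metabolite_spec("m", "Lipid", mean = 50, sd = 10)
  cfg <- study_config(n_occasional = 12, n_chronic = 2, metabolites = list(met),
                      ratio_definitions = NULL, behavior_coupling = NULL,
                      seed = 5)
  tab <- generate_study(cfg)
  d <- compute_deltas(tab)
  f <- fit_delta_association(d, "m", "lapses", "occasional", 10)
  # occasional users have zero baseline THC by design
  expect_true("thc" %in% f$dropped_covariates)
  expect_true(f$estimable)
})

test_that("a single-metabolite screen reduces to the raw p-value", {
  met <- metabolite_spec("m", "Lipid", mean = 50, sd = 10)
  cfg <- study_config(n_occasional = 12, n_chronic = 12, metabolites = list(met),
                      ratio_definitions = NULL, behavior_coupling = NULL,
                      seed = 6)
  tab <- generate_study(cfg)
  d <- compute_deltas(tab)
  scr <- run_delta_screen(d, tab)
  ok <- scr$estimable
  expect_equal(scr$p_adj[ok], scr$p[ok])
  # accounting: strata x metabolites records
  expect_equal(nrow(scr), 2 * 2 * 2 * 1)  # groups x behaviours x timepoints
})

test_that("coupled lipids top their stratum and the chronic strata stay null", {
  hex <- c("HexCer(d18:1/22:0)", "HexCer(d18:1/24:0)")
  panel <- default_metabolite_panel()[c(1:14, 25:34)]
  # moderate coupling: strong enough to dominate, weak enough that the
  # non-negative count floor stays out of play
  coup <- data.frame(metabolite = hex, behavior = "lapses", time = 10,
                     group = "occasional", beta = 0.45)
  top2 <- chronic_hits <- integer(3)
  for (k in 1:3) {
    cfg <- study_config(n_occasional = 40, n_chronic = 17, metabolites = panel,
                        ratio_definitions = NULL, behavior_coupling = coup,
                        seed = 400 + k)
    tab <- generate_study(cfg)
    d <- compute_deltas(tab)
    scr <- run_delta_screen(d, tab)
    s <- scr[scr$group == "occasional" & scr$behavior == "lapses" &
               scr$timepoint == 10 & scr$estimable, ]
    top2[k] <- length(intersect(s$metabolite[order(s$p_adj)][1:2], hex))
    chronic_hits[k] <- sum(scr$p_adj[scr$group == "chronic"] < 0.05, na.rm = TRUE)
  }
  expect_gte(median(top2), 2)
  expect_lte(median(chronic_hits), 1)
})
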