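test_that("log transform: closed forms, zero handling, negative rejection", {
  x <- matrix(exp(0:5), 2, 3)
  expect_equal(log_transform(x), matrix(0:5, 2, 3))
  expect_equal(log_transform(matrix(exp(1), 1, 1))[1, 1], 1)
  xm <- matrix(c(1, NA, 0, 2), 2, 2)
  expect_message(out <- log_transform(xm), "zero")
  expect_true(is.na(out[1, 2]) && is.na(out[2, 1]))
  expect_error(log_transform(matrix(c(1, -2), 1, 2)), class = "mc_data_error")
})

test_that("Pareto scaling centres and scales by sqrt of the sample SD", {
  expect_equal(as.vector(pareto_scale(matrix(c(1, 2, 3)))), c(-1, 0, 1))
  # hand oracle on an arbitrary matrix, including tied values
  x <- cbind(a = c(0, 0, 4, 4), b = c(1.5, 2.5, 10, -3))
  manual <- sweep(sweep(x, 2, colMeans(x)), 2, sqrt(apply(x, 2, sd)), "/")
  expect_equal(unclass(pareto_scale(x)), manual, ignore_attr = TRUE)
  # centring identity
  expect_equal(max(abs(colMeans(pareto_scale(x)))), 0, tolerance = 1e-12)
  # zero-variance column: error by default, droppable on request
  xz <- cbind(x, z = c(2, 2, 2, 2))
  expect_error(pareto_scale(xz), class = "mc_data_error")
  expect_warning(out <- pareto_scale(xz, drop_zero_variance = TRUE), "zero-variance")
  expect_equal(colnames(out), c("a", "b"))
})

test_that("EM-PCA imputation: identity, exact low-rank completion, accuracy", {
  x <- matrix(rnorm(60), 10, 6)
  expect_identical(impute_ppca(x)[, ], x)

  # rank-1 noiseless matrix with deleted cells is completed exactly
  set.seed(42)
  u <- rnorm(20); v <- rnorm(8)
  r1 <- tcrossprod(u, v)
  holes <- r1
  drop_idx <- sample(length(r1), 16)
  holes[drop_idx] <- NA
  filled <- impute_ppca(holes, n_components = 1, max_iter = 500, tol = 1e-12)
  expect_equal(filled[drop_idx], r1[drop_idx], tolerance = 1e-6)
  # observed cells are untouched, bit for bit
  expect_identical(filled[-drop_idx], holes[-drop_idx])

  # correlated data: beats column-mean imputation
  set.seed(9)
  z <- matrix(rnorm(40 * 3), 40, 3)
  xc <- z %*% matrix(rnorm(3 * 12), 3, 12) + 0.3 * matrix(rnorm(40 * 12), 40, 12)
  miss <- matrix(runif(length(xc)) < 0.1, nrow(xc))
  xm <- xc; xm[miss] <- NA
  imp <- impute_ppca(xm, n_components = 3)
  rmse_ppca <- sqrt(mean((imp[miss] - xc[miss])^2))
  mean_fill <- xm
  cm <- colMeans(xm, na.rm = TRUE)
  mean_fill[miss] <- cm[col(xm)[miss]]
  rmse_mean <- sqrt(mean((mean_fill[miss] - xc[miss])^2))
  expect_lt(rmse_ppca, rmse_mean)

  expect_error(impute_ppca(xm, n_components = 12), class = "mc_config_error")
  xallna <- xm; xallna[, 1] <- NA
  expect_error(impute_ppca(xallna, 2), class = "mc_data_error")
})

test_that("ratio features: arithmetic, propagation, panel size", {
  tab <- generate_study(small_study_config(seed = 3))
  defs <- data.frame(name = "kyn/trp-like", numerator = "kynurenine",
                     denominator = "tyrosine")
  out <- compute_ratios(tab, defs)
  m <- out$measurements
  k <- m[m$subject == "occ01" & m$treatment == "placebo" & m$time == 0, ]
  expect_equal(k$concentration[k$metabolite == "kyn/trp-like"],
               k$concentration[k$metabolite == "kynurenine"] /
                 k$concentration[k$metabolite == "tyrosine"])
  expect_error(compute_ratios(tab, data.frame(name = "bad", numerator = "xx",
                                              denominator = "tyrosine")),
               class = "mc_config_error")

  # missing side propagates
  tab2 <- tab
  i <- which(tab2$measurements$metabolite == "tyrosine")[1]
  tab2$measurements$concentration[i] <- NA
  out2 <- compute_ratios(tab2, defs)
  m2 <- out2$measurements
  key <- tab2$measurements[i, ]
  r <- m2[m2$metabolite == "kyn/trp-like" & m2$subject == key$subject &
            m2$treatment == key$treatment & m2$time == key$time, ]
  expect_true(is.na(r$concentration))

  # the default panel yields 91 + 22 = 113 features
  full <- compute_ratios(generate_study(study_config(n_occasional = 2,
                                                     n_chronic = 2, seed = 1)))
  expect_equal(length(unique(full$measurements$metabolite)), 113)
})

test_that("QC PCA matches an explicit covariance eigen-decomposition", {
  set.seed(8)
  x <- matrix(rnorm(200), 20, 10)
  out <- qc_pca(x, 5)
  ev <- eigen(crossprod(sweep(x, 2, colMeans(x))), symmetric = TRUE)$values
  expect_equal(out$explained, (ev / sum(ev))[1:5], tolerance = 1e-8)
  expect_true(all(diff(out$explained) <= 1e-12))
  expect_lte(sum(out$explained), 1)

  # duplicated samples share score coordinates
  xd <- rbind(x, x[3, ])
  sc <- qc_pca(xd, 3)$scores
  expect_equal(sc[21, ], sc[3, ], tolerance = 1e-8)

  # rank-1 data concentrates the variance in one component
  r1 <- tcrossprod(rnorm(12), rnorm(5))
  expect_warning(p1 <- qc_pca(r1, 3), "rank")
  expect_equal(p1$explained[1], 1, tolerance = 1e-10)
})

test_that("the preprocessing pipeline is ordered, recorded, and invertible", {
  tab <- generate_study(small_study_config(seed = 13))
  set.seed(1)
  tab <- inject_missingness(tab, 0.05, "mcar")
  am <- preprocess_study(tab, samples = "all")
  expect_s3_class(am, "analysis_matrix")
  expect_false(anyNA(am$values))
  expect_equal(am$transform_record$steps, c("ratios", "log", "pareto", "impute"))
  expect_true(am$transform_record$impute$n_imputed > 0)

  # inverting the recorded transform recovers raw observed values
  raw <- invert_transforms(am)
  wide <- metabocross:::measurements_to_matrix(
    compute_ratios(tab)$measurements)
  keep <- colnames(raw)
  obs <- !is.na(wide$values[, keep])
  rel <- abs(raw[obs] - wide$values[, keep][obs]) / wide$values[, keep][obs]
  expect_lt(max(rel), 1e-10)

  # baseline mode gives one sample per subject
  amb <- preprocess_study(tab, samples = "baseline")
  expect_equal(nrow(amb$values), nrow(tab$subjects))
  expect_equal(amb$groups, tab$subjects$group)
})
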