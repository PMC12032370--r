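#' Configuration of the repeated double cross-validation engine
#'
#' @param n_outer,n_inner Outer / inner stratified fold counts (7 / 6 keep
#'   at least two subjects per class in every training set at n = 35).
#' @param n_repetitions Independent repetitions of the double CV (each with
#'   fresh fold draws); per-sample predictions are aggregated across them.
#' @param elimination_keep_fraction Fraction of features kept per recursive
#'   elimination step (by VIP rank).
#' @param min_panel Smallest panel size on the elimination ladder.
#' @param a_max Largest number of PLS components tuned over.
#' @param n_permutations Label permutations for [permutation_test()].
#' @param permutation_repetitions Repetitions used inside each permutation
#'   re-run (reduced relative to the main model for tractability).
#' @param seed Integer seed making the whole procedure deterministic.
#' @return Object of class `"rdcv_config"`.
#' @export
rdcv_config <- function(n_outer = 7, n_inner = 6, n_repetitions = 20,
                        elimination_keep_fraction = 0.8, min_panel = 2,
                        a_max = 3, n_permutations = 200,
                        permutation_repetitions = 5, seed = NULL) {
  if (n_outer < 2 || n_inner < 2) stop_config("fold counts must be at least 2")
  if (elimination_keep_fraction <= 0 || elimination_keep_fraction >= 1)
    stop_config("elimination_keep_fraction must lie in (0, 1)")
  if (min_panel < 1) stop_config("min_panel must be positive")
  if (n_repetitions < 1 || a_max < 1) stop_config("n_repetitions and a_max must be positive")
  if (n_permutations < 1) stop_config("n_permutations must be at least 1")
  structure(list(n_outer = n_outer, n_inner = n_inner,
                 n_repetitions = n_repetitions,
                 elimination_keep_fraction = elimination_keep_fraction,
                 min_panel = min_panel, a_max = a_max,
                 n_permutations = n_permutations,
                 permutation_repetitions = permutation_repetitions,
                 seed = seed),
            class = "rdcv_config")
}

# Panel sizes visited by recursive elimination: full panel down to min_panel.
ladder_sizes <- function(p, keep_fraction, min_panel) {
  if (p <= min_panel) return(p)
  sizes <- p
  s <- p
  repeat {
    s_next <- floor(s * keep_fraction)
    if (s_next >= s) s_next <- s - 1
    if (s_next <= min_panel) { sizes <- c(sizes, min_panel); break }
    sizes <- c(sizes, s_next)
    s <- s_next
  }
  sizes
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(yn, k) {
  fold <- integer(length(yn))
  for (cl in unique(yn)) {
    idx <- which(yn == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Per-sample aggregation across repetitions: majority vote; a 50/50 split
# falls to the sign of the mean continuous prediction, and an exactly zero
# mean to the majority training class.
aggregate_votes <- function(votes, cont, majority_code) {
  majority <- sign(rowSums(votes))
  tie <- majority == 0
  if (any(tie)) {
    majority[tie] <- sign(rowMeans(cont)[tie])
    majority[majority == 0] <- majority_code
  }
  majority
}

# Misclassification count of sign predictions against coded truth; exact
# zeros fall to the majority-class code.
count_miss <- function(resp, truth, majority_code) {
  pred <- sign(resp)
  pred[pred == 0] <- majority_code
  sum(pred != truth)
}

# One repetition of the double CV. X raw feature matrix, yn coded +/-1.
# Returns per-sample votes and continuous predictions, the chosen panel
# sizes, and the per-outer-model elimination ranks (1 = most important).
rdcv_one_rep <- function(X, yn, cfg, sizes, majority_code) {
  n <- nrow(X); p <- ncol(X)
  n_sizes <- length(sizes)
  votes <- integer(n); cont <- numeric(n)
  chosen <- integer(cfg$n_outer)
  ranks <- matrix(NA_integer_, cfg$n_outer, p)
  outer <- stratified_folds(yn, cfg$n_outer)

  fit_at <- function(rows, feats, A) {
    Xs <- X[rows, feats, drop = FALSE]
    xm <- colMeans(Xs); ym <- mean(yn[rows])
    fit <- pls1_fit(Xs - rep(xm, each = length(rows)), yn[rows] - ym, A)
    fit$xm <- xm; fit$ym <- ym
    fit
  }

  for (k in seq_len(cfg$n_outer)) {
    te <- which(outer == k); tr <- which(outer != k)
    if (length(unique(yn[tr])) < 2)
      stop_data("a class is absent from an outer training fold; reduce n_outer")
    err <- matrix(0, n_sizes, cfg$a_max)
    inner <- stratified_folds(yn[tr], cfg$n_inner)
    for (j in seq_len(cfg$n_inner)) {
      ival <- tr[inner == j]; itr <- tr[inner != j]
      if (!length(ival) || length(unique(yn[itr])) < 2) next
      feats <- seq_len(p)
      vips <- NULL
      for (si in seq_len(n_sizes)) {
        if (si > 1)
          feats <- feats[order(vips, decreasing = TRUE)[seq_len(sizes[si])]]
        A <- min(cfg$a_max, sizes[si], length(itr) - 1)
        fit <- fit_at(itr, feats, A)
        if (fit$A == 0) {
          # uninformative: predict the training majority for every component count
          mis <- count_miss(rep(sign(fit$ym) + (fit$ym == 0) * majority_code,
                                length(ival)), yn[ival], majority_code)
          err[si, ] <- err[si, ] + mis
          vips <- rep(0, length(feats))
          next
        }
        Xv <- X[ival, feats, drop = FALSE]
        Xvc <- Xv - rep(fit$xm, each = length(ival))
        for (a in seq_len(cfg$a_max)) {
          b <- pls1_coef(fit, min(a, fit$A))
          err[si, a] <- err[si, a] +
            count_miss(drop(Xvc %*% b) + fit$ym, yn[ival], majority_code)
        }
        vips <- pls1_vip(fit)
      }
    }
    # choose (size, A): minimal mean inner error; ties -> smaller panel,
    # then fewer components
    best <- which(err == min(err), arr.ind = TRUE)
    best <- best[order(-best[, 1], best[, 2]), , drop = FALSE][1, ]
    si_star <- best[1]; a_star <- best[2]
    chosen[k] <- sizes[si_star]

    # refit on the full outer-training set, eliminating down the ladder
    feats <- seq_len(p)
    blocks <- list()
    fit <- NULL
    for (si in seq_len(si_star)) {
      A <- min(cfg$a_max, sizes[si], length(tr) - 1)
      fit <- fit_at(tr, feats, A)
      vips <- if (fit$A > 0) pls1_vip(fit) else rep(0, length(feats))
      ord <- order(vips, decreasing = TRUE)
      if (si < si_star) {
        keep_n <- sizes[si + 1]
        blocks[[si]] <- feats[ord[(keep_n + 1):length(ord)]]
        feats <- feats[ord[seq_len(keep_n)]]
      } else {
        final_order <- feats[ord]
      }
    }
    # elimination ranks: retained panel first (by final VIP), then dropped
    # blocks from last-dropped to first-dropped
    ranked <- c(final_order, unlist(rev(blocks)))
    ranks[k, ranked] <- seq_len(p)

    if (fit$A == 0) {
      cont[te] <- fit$ym
      lab <- sign(fit$ym); if (lab == 0) lab <- majority_code
      votes[te] <- lab
    } else {
      b <- pls1_coef(fit, min(a_star, fit$A))
      resp <- drop((X[te, feats, drop = FALSE] -
                      rep(fit$xm, each = length(te))) %*% b) + fit$ym
      cont[te] <- resp
      lab <- sign(resp); lab[lab == 0] <- majority_code
      votes[te] <- lab
    }
  }
  list(votes = votes, cont = cont, chosen = chosen, ranks = ranks)
}

#' Repeated double cross-validated PLS-DA with recursive feature elimination
#'
#' The outer loop of each repetition splits subjects into stratified folds
#' and estimates unbiased class predictions; for every outer training set an
#' inner stratified cross-validation walks the recursive elimination ladder
#' (dropping the lowest-VIP features by `elimination_keep_fraction` per
#' step) and picks the panel size and component count minimising mean inner
#' misclassification (ties to the smaller panel, then the simpler model).
#' The chosen panel is refit on the outer training set and applied to the
#' held-out fold. Repetitions are aggregated by per-sample majority vote
#' into the classification rate; the 95% interval is the 2.5/97.5 percentile
#' range of per-repetition rates; the consensus feature ranking is the mean
#' elimination rank across all outer models, and the consensus panel size
#' the median of the chosen sizes.
#'
#' @param X Feature matrix (samples x features) or an
#'   [`analysis_matrix`][preprocess_study()].
#' @param y Two-level class labels (taken from `X$groups` for an analysis
#'   matrix).
#' @param config An [rdcv_config()].
#' @return Object of class `"rdcv_plsda"`: vote and continuous-prediction
#'   matrices (samples x repetitions), `classification_rate`, `rate_ci`,
#'   `per_repetition_rates`, `consensus_ranking` (mean rank and ordinal
#'   position per feature), `consensus_panel`, `chosen_sizes`, and
#'   `permutation_p` (`NA` until [permutation_test()] is run).
#' @examples
#' set.seed(7)
#' X <- cbind(matrix(rnorm(40 * 5), 40), sig = rep(c(-2, 2), each = 20) + rnorm(40))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- rdcv_plsda(X, y, rdcv_config(n_repetitions = 3, seed = 1))
#' fit$classification_rate
#' @export
rdcv_plsda <- function(X, y = NULL, config = rdcv_config()) {
  if (inherits(X, "analysis_matrix")) {
    y <- y %||% X$groups
    X <- X$values
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop_data("X must be complete; impute first")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop_data("exactly two classes required")
  lev <- levels(y)
  if (setequal(lev, c("occasional", "chronic"))) lev <- c("occasional", "chronic")
  coding <- stats::setNames(c(-1, 1), lev)
  yn <- unname(coding[as.character(y)])
  majority_code <- if (sum(yn == 1) > sum(yn == -1)) 1L else -1L
  sizes <- ladder_sizes(ncol(X), config$elimination_keep_fraction, config$min_panel)

  reps <- with_seed(config$seed,
    lapply(seq_len(config$n_repetitions), function(r)
      rdcv_one_rep(X, yn, config, sizes, majority_code)))

  R <- config$n_repetitions
  votes <- vapply(reps, `[[`, numeric(nrow(X)), "votes")
  cont <- vapply(reps, `[[`, numeric(nrow(X)), "cont")
  votes <- matrix(votes, nrow = nrow(X)); cont <- matrix(cont, nrow = nrow(X))
  per_rep <- colMeans(votes == yn)
  rank_mat <- do.call(rbind, lapply(reps, `[[`, "ranks"))
  mean_rank <- colMeans(rank_mat)
  feature_names <- colnames(X) %||% as.character(seq_len(ncol(X)))
  ranking <- data.frame(feature = feature_names, rank_lr = mean_rank,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$rank_lr), ]
  ranking$order_lr <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  chosen_sizes <- unlist(lapply(reps, `[[`, "chosen"))
  consensus_size <- round(stats::median(chosen_sizes))

  majority <- aggregate_votes(votes, cont, majority_code)
  rate <- mean(majority == yn)

  structure(list(
    vote_matrix = votes, prediction_matrix = cont,
    per_sample_mean_prediction = rowMeans(cont),
    majority_label = factor(names(coding)[(majority + 1) / 2 + 1], levels = names(coding)),
    classification_rate = rate,
    rate_ci = unname(stats::quantile(per_rep, c(0.025, 0.975))),
    per_repetition_rates = per_rep,
    consensus_ranking = ranking,
    consensus_panel_size = consensus_size,
    consensus_panel = ranking$feature[seq_len(consensus_size)],
    chosen_sizes = chosen_sizes,
    permutation_p = NA_real_,
    class_coding = coding, y = y, y_code = yn,
    feature_names = feature_names,
    config = config, call = match.call()),
    class = "rdcv_plsda")
}

#' @export
print.rdcv_plsda <- function(x, ...) {
  cat(sprintf("<rdcv_plsda> %d samples, %d features, %d repetitions\n",
              nrow(x$vote_matrix), length(x$feature_names),
              x$config$n_repetitions))
  cat(sprintf("  classification rate %.1f%% (95%% CI %.0f to %.0f%%)\n",
              100 * x$classification_rate, 100 * x$rate_ci[1], 100 * x$rate_ci[2]))
  cat(sprintf("  consensus panel: %d features (%s, ...)\n",
              x$consensus_panel_size,
              paste(utils::head(x$consensus_panel, 4), collapse = ", ")))
  if (!is.na(x$permutation_p))
    cat(sprintf("  permutation p = %.4g\n", x$permutation_p))
  invisible(x)
}

#' @export
summary.rdcv_plsda <- function(object, ...) {
  print(object)
  cat("\nTop of the consensus ranking:\n")
  print(utils::head(object$consensus_ranking, 15), digits = 3)
  invisible(object)
}

#' Permutation significance test of an rdCV-PLS-DA model
#'
#' Re-runs the double cross-validation under uniformly permuted class labels
#' (at `permutation_repetitions` repetitions per permutation) and compares
#' the permuted classification rates against the observed one:
#' p = (1 + #\{permuted >= observed\}) / (n_permutations + 1).
#'
#' @param X,y As in [rdcv_plsda()] (or pass the fitted `result` to reuse its
#'   labels and configuration).
#' @param config An [rdcv_config()]; `n_permutations` and
#'   `permutation_repetitions` control the test.
#' @param observed_rate Classification rate of the model on the true labels.
#' @return Object of class `"rdcv_permutation"`: `p`, the permuted rates,
#'   and the observed rate.
#' @export
permutation_test <- function(X, y = NULL, config = rdcv_config(),
                             observed_rate) {
  if (inherits(X, "analysis_matrix")) {
    y <- y %||% X$groups
    X <- X$values
  }
  y <- droplevels(as.factor(y))
  cfg <- config
  cfg$n_repetitions <- config$permutation_repetitions
  perm_seed <- if (!is.null(config$seed))
    substream_seed(config$seed, "permutation") else NULL
  rates <- with_seed(perm_seed, {
    vapply(seq_len(config$n_permutations), function(i) {
      yp <- sample(y)
      cfg$seed <- NULL   # draws flow from the ambient (substream) RNG
      r <- rdcv_plsda(X, yp, cfg)
      r$classification_rate
    }, numeric(1))
  })
  p <- (1 + sum(rates >= observed_rate)) / (config$n_permutations + 1)
  structure(list(p = p, permuted_rates = rates, observed_rate = observed_rate,
                 n_permutations = config$n_permutations),
            class = "rdcv_permutation")
}

#' @export
print.rdcv_permutation <- function(x, ...) {
  cat(sprintf("<rdcv_permutation> p = %.4g (%d permutations; observed rate %.3f, max permuted %.3f)\n",
              x$p, x$n_permutations, x$observed_rate, max(x$permuted_rates)))
  invisible(x)
}

#' Per-sample misclassification records
#'
#' One record per sample: actual class, aggregated majority prediction, mean
#' continuous prediction, and whether the sample is misclassified (majority
#' vote disagreeing with the actual label). Records are ordered as in the
#' misclassification plot: the first class block, then the second.
#'
#' @param result A fitted `"rdcv_plsda"`.
#' @param y Actual labels (defaults to those stored in the result).
#' @return Data frame; the per-repetition continuous predictions are
#'   attached as attribute `"predictions"` (samples x repetitions).
#' @export
misclassification_plot_data <- function(result, y = result$y) {
  lev <- names(result$class_coding)
  ord <- order(match(as.character(y), lev))
  df <- data.frame(
    sample = ord,
    actual = factor(as.character(y)[ord], levels = lev),
    majority = result$majority_label[ord],
    mean_prediction = result$per_sample_mean_prediction[ord],
    misclassified = (result$majority_label != factor(as.character(y), lev))[ord])
  rownames(df) <- NULL
  attr(df, "predictions") <- result$prediction_matrix[ord, , drop = FALSE]
  df
}

#' Misclassification plot of an rdCV-PLS-DA model
#'
#' Continuous per-repetition predictions per sample (light points), the
#' per-sample mean prediction (bold), and circles around misclassified
#' samples; the first class occupies the left block of the axis.
#'
#' @param x A fitted `"rdcv_plsda"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.rdcv_plsda <- function(x, ...) {
  d <- misclassification_plot_data(x)
  preds <- attr(d, "predictions")
  n <- nrow(d)
  graphics::plot(NA, xlim = c(1, n), ylim = range(preds, -1.3, 1.3),
                 xlab = "sample (grouped by actual class)",
                 ylab = "predicted class score", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  for (r in seq_len(ncol(preds)))
    graphics::points(seq_len(n) + stats::runif(n, -0.15, 0.15), preds[, r],
                     pch = 16, cex = 0.4, col = grDevices::adjustcolor("grey40", 0.35))
  graphics::points(seq_len(n), d$mean_prediction, pch = 16, cex = 1.1,
                   col = ifelse(d$actual == levels(d$actual)[1], "steelblue", "firebrick"))
  mis <- which(d$misclassified)
  if (length(mis)) graphics::points(mis, d$mean_prediction[mis], cex = 2)
  graphics::abline(v = sum(d$actual == levels(d$actual)[1]) + 0.5, lty = 3)
  invisible(d)
}
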