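#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment with enforced monotonicity (as in
#' [stats::p.adjust()], which does the computation). Input p-values must lie
#' in (0, 1]; violations are an error naming the offending hypothesis.
#'
#' @param p Numeric vector of raw p-values, optionally named.
#' @return Adjusted values (q-values) in the input order.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.finite(p) | p <= 0 | p > 1)
  if (length(bad)) {
    nm <- names(p) %||% as.character(seq_along(p))
    stop_data("p-value out of (0, 1] for hypothesis '%s' (value %s)",
              nm[bad[1]], format(p[bad[1]]))
  }
  stats::p.adjust(p, method = "BH")
}

# Simes combination of a family's p-values: min_i (m p_(i) / i).
simes_p <- function(p) {
  m <- length(p)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Two-level hierarchical family-wise FDR
#'
#' Hypotheses are grouped into pre-registered families (here: chemical
#' families of the metabolite panel). Each family is summarised by the Simes
#' combination of its p-values; Benjamini-Hochberg across the family
#' p-values at level `q` selects families; within each selected family BH is
#' applied at level `q * n_selected / n_families`. The procedure controls
#' the expected overall false discovery proportion at about `q` under
#' within-family positive dependence.
#'
#' Reported per-hypothesis adjusted values are the within-family BH values
#' inflated by `n_families / n_selected` (and floored at the family-level
#' adjusted p), so `p_adj <= q` reproduces the selection-path rejections;
#' with a single family they reduce exactly to plain BH.
#'
#' @param p Raw p-values in (0, 1].
#' @param family Family label per hypothesis (same length as `p`).
#' @param q Target FDR level (default 0.05).
#' @param ids Optional hypothesis identifiers.
#' @return Object of class `"fdr_tree"`: `hypotheses` (data frame: `id`,
#'   `p`, `family`, `p_adj`, `rejected`), `families` (family, `simes_p`,
#'   `p_adj`, `selected`), `q`, `n_selected`.
#' @export
hierarchical_fdr <- function(p, family, q = 0.05, ids = NULL) {
  if (length(p) != length(family)) stop_config("p and family lengths differ")
  if (!length(p)) stop_config("no hypotheses")
  if (anyNA(family) || any(!nzchar(family))) stop_config("empty family label")
  ids <- ids %||% names(p) %||% as.character(seq_along(p))
  names(p) <- ids
  p_checked <- bh_adjust(p)   # validates range; adjusted values recomputed below

  fams <- unique(family)
  fam_p <- vapply(fams, function(f) simes_p(p[family == f]), numeric(1))
  fam_adj <- stats::p.adjust(fam_p, method = "BH")
  selected <- fam_adj <= q
  n_sel <- sum(selected)

  p_adj <- numeric(length(p))
  rejected <- logical(length(p))
  for (i in seq_along(fams)) {
    idx <- which(family == fams[i])
    within <- stats::p.adjust(p[idx], method = "BH")
    infl <- within * length(fams) / max(n_sel, 1)
    p_adj[idx] <- pmin(1, pmax(infl, fam_adj[i]))
    if (selected[i]) rejected[idx] <- within <= q * n_sel / length(fams)
  }

  structure(list(
    hypotheses = data.frame(id = ids, p = unname(p), family = family,
                            p_adj = p_adj, rejected = rejected,
                            stringsAsFactors = FALSE),
    families = data.frame(family = fams, simes_p = unname(fam_p),
                          p_adj = unname(fam_adj), selected = unname(selected),
                          stringsAsFactors = FALSE),
    q = q, n_selected = n_sel),
    class = "fdr_tree")
}

#' @export
print.fdr_tree <- function(x, ...) {
  cat(sprintf("<fdr_tree> %d hypotheses in %d families; %d families selected, %d rejections at q = %g\n",
              nrow(x$hypotheses), nrow(x$families), x$n_selected,
              sum(x$hypotheses$rejected), x$q))
  invisible(x)
}
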