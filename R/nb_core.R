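# Negative-binomial count inference: median-of-ratios size factors,
# method-of-moments dispersion with optional log-scale shrinkage, a
# per-transcript NB GLM Wald test fitted by Fisher-scoring IRLS (vectorized
# across transcripts), Benjamini-Hochberg FDR, and a mean-count filter.
#
# NB parameterization throughout: Var(Y) = mu + alpha * mu^2.

.as_count_matrix <- function(counts) {
  if (inherits(counts, "ox_counts")) counts$counts else as.matrix(counts)
}

#' Median-of-ratios size factors
#'
#' Per-library scaling factors making counts comparable across sequencing
#' depths. For each library j, the factor is the median over reference
#' transcripts of `count[i, j] / geometric_mean_i(count[i, ])`, where the
#' reference transcripts are those with strictly positive counts in every
#' library. No post-hoc rescaling is applied.
#'
#' @param counts an `ox_counts` object or a counts matrix.
#' @param fallback if `TRUE` and no transcript is positive in every library,
#'   fall back to geometric means computed over the positive entries of each
#'   transcript (and ratios over positive entries only). Off by default:
#'   strict mode errors instead.
#' @return numeric vector of positive factors, one per library.
#' @export
estimate_size_factors <- function(counts, fallback = FALSE) {
  y <- .as_count_matrix(counts)
  if (nrow(y) == 0L) stop("empty count matrix")
  logy <- log(y)
  all_pos <- rowSums(y > 0) == ncol(y)
  if (any(all_pos)) {
    loggeo <- rowMeans(logy[all_pos, , drop = FALSE])
    sf <- apply(logy[all_pos, , drop = FALSE], 2L,
                function(col) exp(stats::median(col - loggeo)))
  } else if (fallback) {
    # pseudo-reference over positive entries only
    loggeo <- apply(logy, 1L, function(r) mean(r[is.finite(r)]))
    use <- is.finite(loggeo)
    if (!any(use)) stop("all-zero count matrix; size factors undefined")
    sf <- apply(logy[use, , drop = FALSE], 2L, function(col) {
      d <- col - loggeo[use]
      exp(stats::median(d[is.finite(d)]))
    })
  } else {
    stop("no transcript has positive counts in every library; ",
         "rerun with fallback = TRUE to use a positive-entry pseudo-reference",
         call. = FALSE)
  }
  names(sf) <- colnames(y)
  sf
}

#' Per-transcript NB dispersion by method of moments
#'
#' Gene-wise estimate on normalized counts, pooled within the two design
#' groups so that a real group effect does not inflate the variance:
#' with pooled within-group variance `s2` and overall mean `m`,
#' `alpha_gw = max(floor, (s2 - m) / m^2)`. Optionally each gene-wise
#' estimate is shrunk toward the across-transcript median on the log scale
#' with weight `shrink_weight`, which stabilizes the noisy per-transcript
#' moments at small replicate numbers.
#'
#' @param counts `ox_counts` or matrix.
#' @param size_factors per-library factors (see [estimate_size_factors()]).
#' @param groups two-level factor/character, one label per library; every
#'   group needs >= 2 libraries.
#' @param shrink logical; apply log-scale shrinkage toward the median.
#' @param shrink_weight weight on the median (0 = none, 1 = full), default 0.5.
#' @param floor smallest admissible dispersion, default `1e-8`.
#' @return numeric vector of dispersions, one per transcript, with the
#'   unshrunk gene-wise values in `attr(, "genewise")`.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 shrink = TRUE, shrink_weight = 0.5,
                                 floor = 1e-8) {
  y <- .as_count_matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) {
    stop("every group needs >= 2 libraries to estimate dispersion")
  }
  t_norm <- sweep(y, 2L, size_factors, "/")
  m <- rowMeans(t_norm)
  ss <- 0
  df <- 0
  for (g in levels(groups)) {
    cols <- which(groups == g)
    tg <- t_norm[, cols, drop = FALSE]
    mg <- rowMeans(tg)
    ss <- ss + rowSums((tg - mg)^2)
    df <- df + length(cols) - 1L
  }
  s2 <- ss / df
  a_gw <- ifelse(m > 0, (s2 - m) / m^2, floor)
  a_gw <- pmax(floor, a_gw)
  if (shrink) {
    med <- stats::median(a_gw[m > 0])
    if (!is.finite(med) || med <= 0) med <- floor
    a <- exp((1 - shrink_weight) * log(a_gw) + shrink_weight * log(med))
    a <- pmax(floor, a)
  } else {
    a <- a_gw
  }
  names(a) <- rownames(y)
  attr(a, "genewise") <- a_gw
  a
}

#' Per-transcript NB Wald test of a two-group contrast
#'
#' For each transcript, fits the log-link NB GLM
#' `log mu_ij = log s_j + beta0 + beta1 * x_j` (x = indicator of the test
#' group) by iteratively reweighted least squares with expected-information
#' weights `mu / (1 + alpha * mu)`, then reports the Wald statistic
#' `beta1 / SE(beta1)` against a standard normal. No fold-change shrinkage
#' is applied.
#'
#' Convergence tolerance is `1e-8` on the coefficients with at most 100
#' iterations; transcripts that fail to converge (including one group all
#' zero, where the MLE is infinite) are flagged and get a missing p-value,
#' as do all-zero transcripts.
#'
#' @param counts `ox_counts` or matrix.
#' @param size_factors per-library factors.
#' @param dispersions per-transcript NB dispersions (alpha).
#' @param groups two-level factor/character per library.
#' @param test the group whose effect is reported (numerator); default the
#'   non-reference (second) level.
#' @param ref the baseline group; default the first level.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `base_mean` (mean of normalized counts), `log2fc`, `se` (of log2fc),
#'   `stat`, `pvalue`, `converged`.
#' @export
nb_wald_test <- function(counts, size_factors, dispersions, groups,
                         test = NULL, ref = NULL) {
  y <- .as_count_matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (is.null(ref)) ref <- levels(groups)[1L]
  if (is.null(test)) test <- setdiff(levels(groups), ref)[1L]
  stopifnot(ref %in% levels(groups), test %in% levels(groups), ref != test)
  if (length(size_factors) != ncol(y)) stop("size_factors length mismatch")
  if (length(dispersions) != nrow(y)) stop("dispersions length mismatch")

  x <- as.numeric(groups == test)
  o <- log(size_factors)
  G <- nrow(y)
  n <- ncol(y)
  alpha <- pmax(as.numeric(dispersions), 0)

  t_norm <- sweep(y, 2L, size_factors, "/")
  base_mean <- rowMeans(t_norm)
  all_zero <- rowSums(y) == 0

  # init from group means of normalized counts (pseudo-floored)
  eps <- 1e-8
  mA <- pmax(rowMeans(t_norm[, x == 0, drop = FALSE]), eps)
  mB <- pmax(rowMeans(t_norm[, x == 1, drop = FALSE]), eps)
  b0 <- log(mA)
  b1 <- log(mB) - log(mA)

  active <- !all_zero
  converged <- rep(FALSE, G)
  ofs <- matrix(o, nrow = G, ncol = n, byrow = TRUE)
  xs <- matrix(x, nrow = G, ncol = n, byrow = TRUE)
  se_nat <- rep(NA_real_, G)

  for (iter in seq_len(100L)) {
    idx <- which(active & !converged)
    if (length(idx) == 0L) break
    eta <- b0[idx] + outer(b1[idx], x) + ofs[idx, , drop = FALSE]
    eta <- pmin(eta, 500)  # overflow guard; divergent fits flagged below
    mu <- exp(eta)
    w <- mu / (1 + alpha[idx] * mu)
    z <- (eta - ofs[idx, , drop = FALSE]) + (y[idx, , drop = FALSE] - mu) / mu
    Sw <- rowSums(w)
    Swx <- rowSums(w * xs[idx, , drop = FALSE])
    Swxx <- Swx  # x is 0/1 so x^2 = x
    Swz <- rowSums(w * z)
    Swxz <- rowSums(w * xs[idx, , drop = FALSE] * z)
    det <- Sw * Swxx - Swx^2
    ok <- is.finite(det) & det > 1e-12
    nb0 <- ifelse(ok, (Swxx * Swz - Swx * Swxz) / det, b0[idx])
    nb1 <- ifelse(ok, (Sw * Swxz - Swx * Swz) / det, b1[idx])
    delta <- pmax(abs(nb0 - b0[idx]), abs(nb1 - b1[idx]))
    b0[idx] <- nb0
    b1[idx] <- nb1
    just_conv <- ok & is.finite(delta) & delta < 1e-8 & abs(nb1) < 30
    converged[idx[just_conv]] <- TRUE
    se_nat[idx] <- ifelse(ok, sqrt(Sw / det), NA_real_)
    # fits walking to an infinite MLE or with singular information: give up
    dead <- !ok | !is.finite(delta) | abs(nb1) >= 30
    active[idx[dead]] <- FALSE
  }

  fitted_ok <- converged & !all_zero
  ln2 <- log(2)
  se <- ifelse(fitted_ok, se_nat / ln2, NA_real_)
  stat <- ifelse(fitted_ok, b1 / se_nat, NA_real_)
  pvalue <- ifelse(fitted_ok, 2 * stats::pnorm(-abs(stat)), NA_real_)
  data.frame(
    transcript_id = rownames(y),
    base_mean = base_mean,
    log2fc = ifelse(fitted_ok, b1 / ln2, NA_real_),
    se = se,
    stat = stat,
    pvalue = pvalue,
    converged = fitted_ok,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up over the `m` non-missing p-values: sorted ascending,
#' `q_(i) = min_{k >= i} p_(k) * m / k`, clipped at 1. Missing inputs give
#' missing outputs and do not count toward `m`.
#'
#' @param pvalues numeric vector in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  obs <- !is.na(p)
  if (any(p[obs] < 0 | p[obs] > 1)) stop("p-values must lie in [0, 1]")
  m <- sum(obs)
  q <- rep(NA_real_, length(p))
  if (m == 0L) return(q)
  po <- p[obs]
  ord <- order(po)
  ranked <- po[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  qo <- numeric(m)
  qo[ord] <- adj
  q[obs] <- qo
  q
}

#' Mean-normalized-count filter
#'
#' Transcripts whose mean normalized count falls below `min_mean` are
#' excluded from multiple testing (they get a missing adjusted p-value and
#' do not count toward the BH `m`).
#'
#' @param counts `ox_counts` or matrix.
#' @param size_factors per-library factors.
#' @param min_mean threshold on the mean normalized count, default 1.
#' @return logical keep-mask, one per transcript.
#' @export
low_count_filter <- function(counts, size_factors, min_mean = 1) {
  y <- .as_count_matrix(counts)
  rowMeans(sweep(y, 2L, size_factors, "/")) >= min_mean
}

#' One-call NB two-group test with normalization, filtering and FDR
#'
#' Convenience wrapper chaining [estimate_size_factors()],
#' [estimate_dispersions()], [nb_wald_test()], [low_count_filter()] and
#' [bh_adjust()]. `padj` is missing exactly for transcripts removed by the
#' filter or without a p-value.
#'
#' @inheritParams nb_wald_test
#' @param min_mean filter threshold passed to [low_count_filter()].
#' @param shrink,shrink_weight dispersion shrinkage controls.
#' @param dispersions optional known per-transcript dispersions; when
#'   supplied, estimation is skipped.
#' @param size_factors optional known factors.
#' @return `TestResult` data.frame: `transcript_id`, `base_mean`, `log2fc`,
#'   `se`, `stat`, `pvalue`, `padj`.
#' @export
nb_test <- function(counts, groups, test = NULL, ref = NULL,
                    min_mean = 1, shrink = TRUE, shrink_weight = 0.5,
                    size_factors = NULL, dispersions = NULL) {
  y <- .as_count_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(y)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(y, size_factors, groups,
                                        shrink = shrink,
                                        shrink_weight = shrink_weight)
  }
  res <- nb_wald_test(y, size_factors, dispersions, groups,
                      test = test, ref = ref)
  keep <- low_count_filter(y, size_factors, min_mean = min_mean)
  p_for_bh <- ifelse(keep, res$pvalue, NA_real_)
  res$padj <- bh_adjust(p_for_bh)
  res$converged <- NULL
  res
}
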