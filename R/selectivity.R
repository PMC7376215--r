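# Oxidation selectivity versus expression level, and concordance between
# oxidation and expression downregulation.

#' Assign detected transcripts to expression bins
#'
#' Ranks detected transcripts (base mean > 0) by expression and splits them
#' into `n_bins` contiguous groups. With `scheme = "equal_count"` the
#' groups have (near-)equal size: `floor(n / n_bins)` each, with the
#' remainder distributed one-per-bin starting from the top-expression bin.
#' With `scheme = "equal_width"` the detected expression range is split
#' into `n_bins` intervals of equal width. Ties in expression are broken by
#' transcript ID.
#'
#' @param base_means named numeric vector (names = transcript IDs) of mean
#'   normalized expression, `>= 0`.
#' @param n_bins number of bins (default 10).
#' @param scheme `"equal_count"` (default) or `"equal_width"`.
#' @return integer vector of bin labels 1 (lowest expression) to `n_bins`,
#'   `NA` for undetected transcripts; names preserved.
#' @export
assign_expression_bins <- function(base_means, n_bins = 10,
                                   scheme = c("equal_count", "equal_width")) {
  scheme <- match.arg(scheme)
  if (is.null(names(base_means))) stop("base_means must be named by transcript")
  stopifnot(all(base_means >= 0, na.rm = TRUE), n_bins >= 1)
  detected <- which(!is.na(base_means) & base_means > 0)
  if (length(detected) < n_bins) {
    stop(sprintf("only %d detected transcripts for %d bins; use fewer bins",
                 length(detected), n_bins))
  }
  bins <- rep(NA_integer_, length(base_means))
  names(bins) <- names(base_means)
  if (scheme == "equal_count") {
    ord <- detected[order(base_means[detected], names(base_means)[detected])]
    n <- length(ord)
    sizes <- rep(n %/% n_bins, n_bins)
    r <- n %% n_bins
    if (r > 0) sizes[seq(n_bins, by = -1L, length.out = r)] <- sizes[n_bins] + 1L
    bins[ord] <- rep(seq_len(n_bins), times = sizes)
  } else {
    x <- base_means[detected]
    breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
    bins[detected] <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                                1L), n_bins)
  }
  bins
}

#' Selectivity profile: oxidized fraction per expression bin
#'
#' For each expression bin, counts detected transcripts and oxidized
#' transcripts and reports the oxidized fraction, plus a chi-square
#' goodness-of-fit test of the oxidized counts against the
#' proportional-to-detected expectation (bins with expected count < 1 are
#' pooled into the nearest lower bin). A flat profile — oxidation
#' independent of abundance — gives a non-significant statistic.
#'
#' @param bins bin labels from [assign_expression_bins()] (named, `NA` =
#'   undetected).
#' @param oxidized character vector of oxidized transcript IDs (must be a
#'   subset of `names(bins)`).
#' @return `ox_selectivity`: list with `profile` (data.frame `bin`,
#'   `n_detected`, `n_oxidized`, `fraction`), `chisq`, `df`, `p_uniformity`
#'   (all `NA` when the oxidized set is empty).
#' @export
selectivity_profile <- function(bins, oxidized) {
  if (!all(oxidized %in% names(bins))) {
    stop("oxidized transcripts outside the binned universe: ",
         paste(utils::head(setdiff(oxidized, names(bins))), collapse = ", "))
  }
  n_bins <- max(bins, na.rm = TRUE)
  lev <- seq_len(n_bins)
  det <- tabulate(bins[!is.na(bins)], nbins = n_bins)
  ox_bins <- bins[intersect(oxidized, names(bins))]
  ox_bins <- ox_bins[!is.na(ox_bins)]
  ox <- tabulate(ox_bins, nbins = n_bins)
  frac <- ifelse(det > 0, ox / det, NA_real_)
  profile <- data.frame(bin = lev, n_detected = det, n_oxidized = ox,
                        fraction = frac)
  if (sum(ox) == 0L) {
    return(structure(list(profile = profile, chisq = NA_real_, df = NA_real_,
                          p_uniformity = NA_real_), class = "ox_selectivity"))
  }
  expected0 <- sum(ox) * det / sum(det)
  # pool bins with expected < 1 into their lower neighbour so the
  # chi-square reference distribution holds
  grp <- seq_len(n_bins)
  for (b in seq(n_bins, 2L)) {
    if (sum(expected0[grp == grp[b]]) < 1) grp[grp == grp[b]] <- grp[b - 1L]
  }
  low <- grp == grp[1L]
  if (sum(expected0[low]) < 1 && any(!low)) {
    grp[low] <- min(grp[!low])  # lowest pool still small: merge upward
  }
  o_pool <- vapply(split(ox, grp), sum, 0)
  e_pool <- vapply(split(expected0, grp), sum, 0)
  use <- e_pool > 0
  chisq <- sum((o_pool[use] - e_pool[use])^2 / e_pool[use])
  df <- max(sum(use) - 1L, 1L)
  p <- stats::pchisq(chisq, df = df, lower.tail = FALSE)
  structure(list(profile = profile, chisq = chisq, df = df, p_uniformity = p),
            class = "ox_selectivity")
}

#' Concordance between oxidation and expression downregulation
#'
#' Two summaries linking an induced oxidized set to a differential
#' expression analysis: the number of oxidized transcripts that are also
#' significantly downregulated, and the fraction of oxidized transcripts
#' whose expression log2 fold change is negative (the "negative fold-change
#' region" of the volcano plot). Induced members absent from the DE table
#' (or with missing fold change) are excluded from the denominator.
#'
#' @param induced `ox_induced_set`.
#' @param de `ox_diffexpr`.
#' @return list: `n_oxidized_down`, `frac_negative_lfc`, `n_with_lfc`
#'   (denominator), `n_induced`.
#' @export
downreg_concordance <- function(induced, de) {
  ids <- induced$members$transcript_id
  n_down <- length(intersect(ids, de$down))
  lfc <- de$table$log2fc[match(ids, de$table$transcript_id)]
  has <- !is.na(lfc)
  frac_neg <- if (any(has)) mean(lfc[has] < 0) else NA_real_
  list(n_oxidized_down = n_down,
       frac_negative_lfc = frac_neg,
       n_with_lfc = sum(has),
       n_induced = length(ids))
}
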