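# Discrimination of exposure-induced oxidized transcripts, cross-exposure
# overlap, and enrichment-profile clustering.

#' Discriminate exposure-induced oxidized transcripts
#'
#' A transcript enriched in the exposed condition is called
#' exposure-induced when it is either (A) unique — absent from the control
#' enriched set — or (B) shared but with a linear enrichment fold-change
#' ratio (exposed over control) strictly greater than `ratio_threshold`.
#' The ratio is computed on linear fold changes, i.e.
#' `2^(log2fc_exposed - log2fc_control)`.
#'
#' @param exposed,control `ox_enriched_set` objects from [rip_enrichment()]
#'   (or [enriched_set()]) over the same transcript universe.
#' @param ratio_threshold minimum exposed/control enrichment ratio for
#'   shared transcripts (default 1.5); must be positive.
#' @return `ox_induced_set`: list with `members` (data.frame
#'   `transcript_id`, `provenance` in `{unique, ratio}`, `log2fc_exposed`,
#'   `log2fc_control` and `fc_ratio`, the latter two `NA` for unique
#'   members), `min_log2fc` (minimum `log2fc_exposed` over members) and
#'   `ratio_threshold`.
#' @export
discriminate_induced <- function(exposed, control, ratio_threshold = 1.5) {
  if (!is.numeric(ratio_threshold) || ratio_threshold <= 0) {
    stop("ratio_threshold must be > 0")
  }
  em <- exposed$members
  cm <- control$members
  shared <- em$transcript_id %in% cm$transcript_id
  lfc_c <- cm$log2fc[match(em$transcript_id, cm$transcript_id)]
  fc_ratio <- ifelse(shared, 2^(em$log2fc - lfc_c), NA_real_)
  keep <- !shared | (shared & fc_ratio > ratio_threshold)
  members <- data.frame(
    transcript_id = as.character(em$transcript_id[keep]),
    provenance = as.character(ifelse(shared[keep], "ratio", "unique")),
    log2fc_exposed = as.numeric(em$log2fc[keep]),
    log2fc_control = as.numeric(ifelse(shared[keep], lfc_c[keep], NA_real_)),
    fc_ratio = as.numeric(fc_ratio[keep]),
    stringsAsFactors = FALSE
  )
  members <- members[order(members$transcript_id), , drop = FALSE]
  rownames(members) <- NULL
  res <- structure(
    list(members = members,
         min_log2fc = if (nrow(members)) min(members$log2fc_exposed) else NA_real_,
         ratio_threshold = ratio_threshold),
    class = "ox_induced_set")
  .check_induced(res, exposed, control)
  res
}

# post-construction assertions of the membership rule
.check_induced <- function(x, exposed, control) {
  m <- x$members
  stopifnot(all(m$transcript_id %in% exposed$members$transcript_id))
  is_ratio <- m$provenance == "ratio"
  stopifnot(all(m$fc_ratio[is_ratio] > x$ratio_threshold))
  stopifnot(!any(m$transcript_id[!is_ratio] %in% control$members$transcript_id))
  if (nrow(m)) stopifnot(identical(x$min_log2fc, min(m$log2fc_exposed)))
  invisible(TRUE)
}

#' @export
print.ox_induced_set <- function(x, ...) {
  cat(sprintf(
    "ox_induced_set: %d transcripts (%d unique, %d by FC ratio > %g); min log2FC %.3g\n",
    nrow(x$members), sum(x$members$provenance == "unique"),
    sum(x$members$provenance == "ratio"), x$ratio_threshold, x$min_log2fc))
  invisible(x)
}

#' Overlap two induced sets
#'
#' Partitions the union of two induced sets (e.g. from two exposure
#' intensities) into shared members, members unique to A and members unique
#' to B, with the paired enrichment effect sizes for shared members.
#'
#' @param induced_a,induced_b `ox_induced_set` objects.
#' @return list with `shared`, `unique_a`, `unique_b` (sorted character
#'   vectors) and `paired_log2fc` (data.frame `transcript_id`, `log2fc_a`,
#'   `log2fc_b` over the shared members).
#' @export
overlap_conditions <- function(induced_a, induced_b) {
  a <- induced_a$members$transcript_id
  b <- induced_b$members$transcript_id
  shared <- sort(intersect(a, b))
  paired <- data.frame(
    transcript_id = shared,
    log2fc_a = induced_a$members$log2fc_exposed[match(shared, a)],
    log2fc_b = induced_b$members$log2fc_exposed[match(shared, b)],
    stringsAsFactors = FALSE
  )
  list(shared = shared,
       unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       paired_log2fc = paired)
}

#' Cluster transcripts by enrichment profile
#'
#' Agglomerative average-linkage clustering on Euclidean distances between
#' per-transcript enrichment profiles (log2 fold changes across
#' conditions), as used to order heatmap rows. Missing entries are imputed
#' as 0 for the distance computation (and flagged). Rows are sorted by
#' transcript ID before clustering so the result is invariant to input
#' order; ties are thereby broken lexicographically.
#'
#' @param log2fc matrix, transcripts x conditions, rownames = transcript
#'   IDs; `NA` allowed.
#' @return `ox_cluster_order`: list with `order` (leaf-order transcript
#'   IDs), `merge`, `height` (as in [stats::hclust()]), and
#'   `imputed` (IDs with any missing entry). A single transcript returns a
#'   trivial order with a note attribute.
#' @export
cluster_enrichment_profiles <- function(log2fc) {
  log2fc <- as.matrix(log2fc)
  if (is.null(rownames(log2fc))) stop("log2fc needs transcript rownames")
  log2fc <- log2fc[order(rownames(log2fc)), , drop = FALSE]
  imputed <- rownames(log2fc)[rowSums(is.na(log2fc)) > 0]
  if (nrow(log2fc) < 2L) {
    res <- list(order = rownames(log2fc), merge = NULL, height = numeric(0),
                imputed = imputed)
    attr(res, "note") <- "fewer than 2 transcripts: trivial order"
    class(res) <- "ox_cluster_order"
    return(res)
  }
  filled <- log2fc
  filled[is.na(filled)] <- 0
  hc <- stats::hclust(stats::dist(filled, method = "euclidean"),
                      method = "average")
  structure(list(order = rownames(log2fc)[hc$order], merge = hc$merge,
                 height = hc$height, imputed = imputed),
            class = "ox_cluster_order")
}
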