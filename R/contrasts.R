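# The two applications of the NB machinery: 8-oxoG enrichment (RIP vs input
# within one exposure condition) and differential expression (exposed vs
# control on the input fraction), each with its thresholding into sets.

#' 8-oxoG enrichment test: RIP vs input within one condition
#'
#' Subsets the libraries of the named exposure condition and contrasts the
#' immunoprecipitated (rip) fraction against the unenriched (input)
#' fraction. A transcript is called 8-oxoG-enriched when its adjusted
#' p-value is below `padj_max` and its linear fold change (rip over input)
#' exceeds `min_fc`, i.e. `log2fc > log2(min_fc)`.
#'
#' Default `padj_max = 0.1` corresponds to the low-exposure analyses;
#' high-exposure runs conventionally use 0.05.
#'
#' @param counts an `ox_counts` object.
#' @param condition `"exposed"` or `"control"`: which libraries to use.
#' @param padj_max adjusted p-value ceiling (default 0.1).
#' @param min_fc minimum linear fold change rip/input (default 2).
#' @param ... further arguments to [nb_test()].
#' @return list with `table` (full TestResult) and `enriched`
#'   (an `ox_enriched_set`).
#' @export
rip_enrichment <- function(counts, condition, padj_max = 0.1, min_fc = 2,
                           ...) {
  samples <- counts$samples
  if (!condition %in% samples$condition) {
    stop("condition ", sQuote(condition), " absent from sample sheet")
  }
  sel <- samples$condition == condition
  sub <- rip_counts(counts$counts[, samples$sample_id[sel], drop = FALSE],
                    samples[sel, , drop = FALSE])
  for (fr in c("input", "rip")) {
    if (sum(sub$samples$fraction == fr) < 2L) {
      stop("condition ", sQuote(condition), " needs >= 2 ", fr, " libraries")
    }
  }
  tab <- nb_test(sub, groups = sub$samples$fraction,
                 test = "rip", ref = "input", ...)
  list(table = tab,
       enriched = enriched_set(tab, condition = condition,
                               padj_max = padj_max, min_fc = min_fc))
}

#' Build an enriched set from a test table
#'
#' @param table TestResult data.frame (from [nb_test()]).
#' @param condition label recorded on the set.
#' @param padj_max,min_fc the thresholds.
#' @return `ox_enriched_set`: list with `condition`, `thresholds` and
#'   `members` (data.frame `transcript_id`, `log2fc`, `padj`, all with
#'   `padj < padj_max` and `log2fc > log2(min_fc)`).
#' @export
enriched_set <- function(table, condition, padj_max = 0.1, min_fc = 2) {
  stopifnot(padj_max > 0, min_fc > 0)
  keep <- !is.na(table$padj) & table$padj < padj_max &
    !is.na(table$log2fc) & table$log2fc > log2(min_fc)
  members <- table[keep, c("transcript_id", "log2fc", "padj")]
  members <- members[order(members$transcript_id), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(condition = condition,
                 thresholds = list(padj_max = padj_max, min_fc = min_fc),
                 members = members),
            class = "ox_enriched_set")
}

#' @export
print.ox_enriched_set <- function(x, ...) {
  cat(sprintf("ox_enriched_set (%s): %d transcripts (padj < %g, FC > %g)\n",
              x$condition, nrow(x$members), x$thresholds$padj_max,
              x$thresholds$min_fc))
  invisible(x)
}

#' Differential expression: exposed vs control on the input fraction
#'
#' Contrasts exposure conditions using only the unenriched (input)
#' libraries, then classifies transcripts as upregulated
#' (`FC > up_fc`, `padj < padj_max`) or downregulated (`FC < down_fc`,
#' `padj < padj_max`); fold-change thresholds act on the linear scale.
#'
#' @param counts an `ox_counts` object.
#' @param padj_max adjusted p-value ceiling (default 0.05).
#' @param up_fc minimum linear fold change for "up" (default 2).
#' @param down_fc maximum linear fold change for "down" (default 0.5).
#' @param ... further arguments to [nb_test()].
#' @return `ox_diffexpr`: list with `table` (full TestResult), `up`, `down`
#'   (character vectors of transcript IDs) and `thresholds`.
#' @export
diff_expression <- function(counts, padj_max = 0.05, up_fc = 2,
                            down_fc = 0.5, ...) {
  stopifnot(up_fc > 0, down_fc > 0, down_fc < up_fc)
  samples <- counts$samples
  sel <- samples$fraction == "input"
  sub <- rip_counts(counts$counts[, samples$sample_id[sel], drop = FALSE],
                    samples[sel, , drop = FALSE])
  for (cc in c("exposed", "control")) {
    if (sum(sub$samples$condition == cc) < 2L) {
      stop("input fraction needs >= 2 ", cc, " libraries")
    }
  }
  tab <- nb_test(sub, groups = sub$samples$condition,
                 test = "exposed", ref = "control", ...)
  sig <- !is.na(tab$padj) & tab$padj < padj_max & !is.na(tab$log2fc)
  up <- tab$transcript_id[sig & tab$log2fc > log2(up_fc)]
  down <- tab$transcript_id[sig & tab$log2fc < log2(down_fc)]
  stopifnot(length(intersect(up, down)) == 0L)
  structure(list(table = tab, up = sort(up), down = sort(down),
                 thresholds = list(padj_max = padj_max, up_fc = up_fc,
                                   down_fc = down_fc)),
            class = "ox_diffexpr")
}

#' @export
print.ox_diffexpr <- function(x, ...) {
  cat(sprintf("ox_diffexpr: %d up, %d down (padj < %g, FC > %g / < %g)\n",
              length(x$up), length(x$down), x$thresholds$padj_max,
              x$thresholds$up_fc, x$thresholds$down_fc))
  invisible(x)
}
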