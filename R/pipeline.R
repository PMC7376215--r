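# End-to-end orchestration: enrichment in both conditions, discrimination
# of exposure-induced oxidized transcripts, differential expression,
# selectivity, and pathway over-representation, with a JSON manifest.

#' Default pipeline configuration
#'
#' @param counts path to a counts TSV or an `ox_counts` object.
#' @param samples path to a sample-sheet CSV (ignored when `counts` is an
#'   `ox_counts`).
#' @param gmt optional path to a GMT file or an `ox_genesets` collection;
#'   when absent the pathway stage is skipped.
#' @param out_dir output directory.
#' @param padj_enrich adjusted-p ceiling for the enrichment calls
#'   (0.1 for low-exposure runs, 0.05 for high-exposure runs).
#' @param min_fc minimum linear enrichment fold change.
#' @param ratio_threshold exposed/control enrichment ratio for shared
#'   transcripts.
#' @param padj_de,up_fc,down_fc differential-expression thresholds.
#' @param n_bins,bin_scheme selectivity binning controls.
#' @param seed recorded in the manifest (the inference itself is
#'   deterministic; the seed matters when `counts` comes from a simulator).
#' @return a `run_config` list.
#' @export
run_config <- function(counts, samples = NULL, gmt = NULL,
                       out_dir = "oxripseq_run",
                       padj_enrich = 0.1, min_fc = 2, ratio_threshold = 1.5,
                       padj_de = 0.05, up_fc = 2, down_fc = 0.5,
                       n_bins = 10, bin_scheme = "equal_count", seed = 1) {
  stopifnot(padj_enrich > 0, padj_enrich <= 1, min_fc > 0,
            ratio_threshold > 0, padj_de > 0, padj_de <= 1, n_bins >= 1)
  structure(list(counts = counts, samples = samples, gmt = gmt,
                 out_dir = out_dir, padj_enrich = padj_enrich,
                 min_fc = min_fc, ratio_threshold = ratio_threshold,
                 padj_de = padj_de, up_fc = up_fc, down_fc = down_fc,
                 n_bins = n_bins, bin_scheme = bin_scheme, seed = seed),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full oxidized-transcript inference pipeline
#'
#' Stages, in order: 8-oxoG enrichment testing (rip vs input) in the
#' exposed and in the control condition; discrimination of
#' exposure-induced oxidized transcripts (unique or fold-change-ratio
#' rule); differential expression on the input fraction; expression-bin
#' selectivity of the induced set; oxidation/downregulation concordance;
#' and, when gene sets are supplied, over-representation of the induced
#' set against all transcripts detected in the input fraction. Every
#' intermediate table is written as TSV and a JSON manifest records input
#' checksums, the configuration, package version and stage summaries.
#' Reruns on identical inputs reproduce identical outputs.
#'
#' @param config a [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return invisibly, the manifest list; a failure in stage S raises an
#'   error prefixed with the stage name, retaining outputs of earlier
#'   stages next to a `FAILED` marker file.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  input_files <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("failed at stage: ", name), file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  counts <- stage("load", {
    if (inherits(config$counts, "ox_counts")) config$counts
    else {
      input_files$samples <- config$samples
      input_files$counts <- config$counts
      read_counts(config$counts, read_sample_sheet(config$samples))
    }
  })
  gmt <- stage("load", {
    if (is.null(config$gmt)) NULL
    else if (inherits(config$gmt, "ox_genesets")) config$gmt
    else {
      input_files$gmt <- config$gmt
      read_gmt(config$gmt)
    }
  })

  enr_exp <- stage("enrich_exposed",
                   rip_enrichment(counts, "exposed",
                                  padj_max = config$padj_enrich,
                                  min_fc = config$min_fc))
  enr_ctl <- stage("enrich_control",
                   rip_enrichment(counts, "control",
                                  padj_max = config$padj_enrich,
                                  min_fc = config$min_fc))
  induced <- stage("discriminate",
                   discriminate_induced(enr_exp$enriched, enr_ctl$enriched,
                                        config$ratio_threshold))
  de <- stage("diffexpr",
              diff_expression(counts, padj_max = config$padj_de,
                              up_fc = config$up_fc, down_fc = config$down_fc))

  sel <- stage("selectivity", {
    bm <- stats::setNames(de$table$base_mean, de$table$transcript_id)
    bins <- assign_expression_bins(bm, n_bins = config$n_bins,
                                   scheme = config$bin_scheme)
    detected_induced <- intersect(induced$members$transcript_id,
                                  names(bins)[!is.na(bins)])
    selectivity_profile(bins, detected_induced)
  })
  concord <- stage("concordance", downreg_concordance(induced, de))

  pathways <- NULL
  if (!is.null(gmt)) {
    pathways <- stage("pathways", {
      universe <- de$table$transcript_id[de$table$base_mean > 0]
      qlist <- intersect(induced$members$transcript_id, universe)
      fisher_overrepresentation(qlist, gmt, universe)
    })
  }

  files <- stage("write", {
    f <- c(enrichment_exposed = "enrichment_exposed.tsv",
           enrichment_control = "enrichment_control.tsv",
           enriched_exposed = "enriched_exposed.tsv",
           enriched_control = "enriched_control.tsv",
           induced = "induced.tsv",
           diffexpr = "diffexpr.tsv",
           selectivity = "selectivity.tsv")
    write_results(enr_exp$table, file.path(out, f["enrichment_exposed"]))
    write_results(enr_ctl$table, file.path(out, f["enrichment_control"]))
    write_results(enr_exp$enriched$members, file.path(out, f["enriched_exposed"]))
    write_results(enr_ctl$enriched$members, file.path(out, f["enriched_control"]))
    write_results(induced$members, file.path(out, f["induced"]))
    write_results(de$table, file.path(out, f["diffexpr"]))
    write_results(sel$profile, file.path(out, f["selectivity"]))
    if (!is.null(pathways)) {
      f["pathways"] <- "pathways.tsv"
      write_results(pathways, file.path(out, f["pathways"]))
    }
    f
  })

  top_paths <- if (!is.null(pathways) && nrow(pathways)) {
    utils::head(pathways$set_name, 5L)
  } else character(0)
  manifest <- list(
    package = "oxripseq",
    version = as.character(utils::packageVersion("oxripseq")),
    seed = config$seed,
    config = config[setdiff(names(config), c("counts", "samples", "gmt"))],
    inputs = lapply(input_files, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(files),
    summary = list(
      n_enriched_exposed = nrow(enr_exp$enriched$members),
      n_enriched_control = nrow(enr_ctl$enriched$members),
      n_induced = nrow(induced$members),
      min_log2fc_induced = induced$min_log2fc,
      n_de_up = length(de$up),
      n_de_down = length(de$down),
      n_oxidized_down = concord$n_oxidized_down,
      frac_negative_lfc = concord$frac_negative_lfc,
      selectivity_p_uniformity = sel$p_uniformity,
      top_pathways = top_paths)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (file.exists(file.path(out, "FAILED"))) file.remove(file.path(out, "FAILED"))
  invisible(manifest)
}
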