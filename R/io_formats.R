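# On-disk artifacts: counts TSV, sample-sheet CSV, GMT gene sets, results TSV.
# Dialect is fixed: UTF-8, tab/comma separators, "." decimal point; transcript
# and set IDs are restricted to [A-Za-z0-9._-] so no quoting is ever needed and
# write/read round-trips are byte-stable.

.id_regex <- "^[A-Za-z0-9._-]+$"

#' Construct a validated sample sheet
#'
#' A sample sheet describes the RIP-seq design: one row per sequencing
#' library, with its exposure condition (`exposed` or `control`), its
#' fraction (`input` = unenriched pool, `rip` = antibody-captured pool)
#' and a biological replicate number.
#'
#' Designs with fewer than two replicates in any used (condition, fraction)
#' cell are accepted but flagged: a warning is raised and the returned sheet
#' carries `attr(x, "under_replicated")` listing the offending cells.
#'
#' @param sample_id character, unique library identifiers.
#' @param condition character, each `"exposed"` or `"control"` (case-folded).
#' @param fraction character, each `"input"` or `"rip"` (case-folded).
#' @param replicate positive integers.
#' @return A `data.frame` of class `ox_sample_sheet`.
#' @export
sample_sheet <- function(sample_id, condition, fraction, replicate) {
  df <- data.frame(
    sample_id = as.character(sample_id),
    condition = tolower(as.character(condition)),
    fraction  = tolower(as.character(fraction)),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  bad_cond <- setdiff(unique(df$condition), c("exposed", "control"))
  if (length(bad_cond) > 0L) {
    stop("unknown condition value(s): ", paste(sQuote(bad_cond), collapse = ", "),
         " (expected 'exposed' or 'control')", call. = FALSE)
  }
  bad_frac <- setdiff(unique(df$fraction), c("input", "rip"))
  if (length(bad_frac) > 0L) {
    stop("unknown fraction value(s): ", paste(sQuote(bad_frac), collapse = ", "),
         " (expected 'input' or 'rip')", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  cell <- paste(df$condition, df$fraction, sep = ":")
  n_cell <- table(cell)
  under <- names(n_cell)[n_cell < 2L]
  attr(df, "under_replicated") <- under
  if (length(under) > 0L) {
    warning("under-replicated design cell(s) (< 2 replicates): ",
            paste(under, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("ox_sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from CSV
#'
#' Columns `sample_id`, `condition`, `fraction`, `replicate` are required
#' (header case-insensitive); `condition`/`fraction` values are normalized
#' to lowercase.
#'
#' @param path CSV file path.
#' @return An `ox_sample_sheet` (see [sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample_id", "condition", "fraction", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_sheet(df$sample_id, df$condition, df$fraction, df$replicate)
}

#' Write a sample sheet to CSV
#' @param samples an `ox_sample_sheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.csv(as.data.frame(samples)[, c("sample_id", "condition",
                                              "fraction", "replicate")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundle a count matrix with its sample sheet
#'
#' The pipeline entry point: transcript-level counts (rows = transcripts,
#' columns = libraries) together with the design. Counts must be
#' non-negative integers; upstream quantifier output (e.g. RSEM expected
#' counts) is assumed rounded to integers before entry, since the
#' negative-binomial likelihood is defined on integers.
#'
#' @param counts integer matrix with unique rownames (transcript IDs) and
#'   colnames matching `samples$sample_id`.
#' @param samples an `ox_sample_sheet`.
#' @return A list of class `ox_counts` with elements `counts` and `samples`.
#' @export
rip_counts <- function(counts, samples) {
  if (!inherits(samples, "ox_sample_sheet")) {
    samples <- validate_sample_sheet(as.data.frame(samples))
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  if (anyDuplicated(rownames(counts))) {
    stop("duplicated transcript ID: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(colnames(counts))) stop("counts must have sample colnames")
  sym_diff <- union(setdiff(colnames(counts), samples$sample_id),
                    setdiff(samples$sample_id, colnames(counts)))
  if (length(sym_diff) > 0L) {
    stop("count columns and sample sheet disagree; symmetric difference: ",
         paste(sym_diff, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "counts must be non-negative integers; first offending cell: row '%s', column '%s' (value %s)",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  counts <- counts[, samples$sample_id, drop = FALSE]  # canonical column order
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples), class = "ox_counts")
}

#' @export
print.ox_counts <- function(x, ...) {
  cat(sprintf("ox_counts: %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("design: ")
  print(table(x$samples$condition, x$samples$fraction))
  invisible(x)
}

#' @export
dim.ox_counts <- function(x) dim(x$counts)

#' Read a transcript count matrix from TSV
#'
#' First column = transcript ID, remaining columns = one per library with
#' headers matching the sample sheet (any order; columns are reordered to
#' the sheet). Cells must be non-negative integers.
#'
#' @param path TSV file path.
#' @param samples an `ox_sample_sheet` naming the expected columns.
#' @return An `ox_counts` object.
#' @export
read_counts <- function(path, samples) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts TSV needs an ID column plus >= 1 sample")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    nonnum <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))) &
                      !is.na(mat), arr.ind = TRUE)
    if (nrow(nonnum) > 0L) {
      stop(sprintf("non-numeric count at row '%s', column '%s'",
                   ids[nonnum[1L, 1L]], colnames(mat)[nonnum[1L, 2L]]),
           call. = FALSE)
    }
    storage.mode(mat) <- "numeric"
  }
  rownames(mat) <- ids
  rip_counts(mat, samples)
}

#' Write a count matrix to TSV
#' @param x an `ox_counts` object.
#' @param path output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(transcript_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated per set.
#'
#' @param path GMT file path.
#' @return A named list of class `ox_genesets`; each element has `description`
#'   and `members` (character vector). An empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need name, description, >= 1 member",
                   i, length(f)), call. = FALSE)
    }
    nm <- f[[1L]]
    if (!is.null(sets[[nm]])) stop("duplicated set name: ", nm, call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("set ", nm, " has no members", call. = FALSE)
    sets[[nm]] <- list(description = f[[2L]], members = members)
  }
  structure(sets, class = "ox_genesets")
}

#' Write a gene-set collection to GMT
#' @param sets an `ox_genesets` collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$members), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Fixed documented dialect: tab separator, column order as in the input
#' data.frame, doubles rendered with 6 significant digits, missing values
#' as the literal `NA`.
#'
#' @param table a data.frame (test results, induced set, selectivity
#'   profile, pathway results, ...).
#' @param path output path.
#' @export
write_results <- function(table, path) {
  out <- as.data.frame(table, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), NA_character_,
                         formatC(out[[j]], digits = 6L, format = "g"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a result table written by [write_results()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
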