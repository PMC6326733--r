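#' Write a groundtruth matrix and partition to TSV files
#'
#' The matrix file is a dense TSV with node ids as header row and first
#' column; values are written with 10 decimal places, which the reader
#' reproduces exactly. The partition file has two columns,
#' `node_id<TAB>module_label`.
#'
#' @param gt A `ground_truth` object.
#' @param matrix_path,partition_path Output file paths.
#' @return `gt`, invisibly.
#' @export
write_groundtruth <- function(gt, matrix_path, partition_path) {
  w <- gt$values
  n <- nrow(w)
  header <- paste(c("node", seq_len(n)), collapse = "\t")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(i, sprintf("%.10f", w[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), matrix_path)
  readr::write_tsv(
    tibble(node_id = gt$partition$node, module_label = as.character(gt$partition$module)),
    partition_path
  )
  invisible(gt)
}

#' Load a groundtruth matrix and partition from TSV files
#'
#' Reads a dense numeric TSV (optionally carrying node ids as a header row
#' and/or first column) plus a two-column `node_id<TAB>module_label` partition
#' file, and validates every groundtruth invariant (square, finite, |r| <= 1,
#' symmetric within `tol_asymmetry`, unit diagonal, positive mean FC,
#' within-module FC above between-module FC) before returning.
#'
#' @param matrix_path Path to the matrix TSV.
#' @param partition_path Path to the partition TSV.
#' @param tol_asymmetry Symmetrization tolerance; larger asymmetries error.
#' @return A `ground_truth` object.
#' @export
load_groundtruth <- function(matrix_path, partition_path, tol_asymmetry = 1e-8) {
  raw <- utils::read.delim(matrix_path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  # detect a header row (first row not fully numeric past the corner cell)
  first_row_num <- suppressWarnings(as.numeric(raw[1, -1]))
  has_header <- any(is.na(first_row_num)) ||
    identical(tolower(as.character(raw[1, 1])), "node")
  if (has_header) raw <- raw[-1, , drop = FALSE]
  first_col_num <- suppressWarnings(as.numeric(raw[[1]]))
  has_rownames <- has_header || any(is.na(first_col_num)) ||
    (ncol(raw) == nrow(raw) + 1)
  if (has_rownames) raw <- raw[, -1, drop = FALSE]
  values <- suppressWarnings(apply(as.matrix(raw), c(1, 2), as.numeric))
  dimnames(values) <- NULL
  if (nrow(values) != ncol(values)) {
    stop_validation(sprintf(
      "matrix must be square, got %d rows x %d columns", nrow(values), ncol(values)
    ))
  }
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf("non-numeric or missing entry at [%d, %d]", bad[1, 1], bad[1, 2]))
  }
  bad <- which(abs(values) > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf(
      "|correlation| > 1 at [%d, %d]: %.4f", bad[1, 1], bad[1, 2], values[bad[1, , drop = FALSE]]
    ))
  }
  part <- readr::read_tsv(partition_path, show_col_types = FALSE)
  names(part) <- c("node", "module")[seq_len(min(2, ncol(part)))]
  as_groundtruth(values, as_partition(part), tol_asymmetry = tol_asymmetry)
}

#' Export a simulated cohort as per-subject TSV matrices plus a manifest
#'
#' @param cohort A `cohort` object (see [simulate_cohort()]).
#' @param dir Output directory, created if needed.
#' @return The manifest tibble (subject_id, group, file, b_s), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(cohort$subjects, function(s) {
    file <- sprintf("subject_%s.tsv", s$subject_id)
    utils::write.table(
      round(s$values, 6), file.path(dir, file),
      sep = "\t", row.names = FALSE, col.names = FALSE
    )
    tibble(subject_id = s$subject_id, group = s$group, file = file, b_s = s$b_s)
  })
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}
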