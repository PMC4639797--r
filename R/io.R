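#' Read a labelled numeric matrix or table from TSV
#'
#' Expects a header row of column labels and a first column of row labels;
#' `#`-prefixed lines are metadata and skipped. Duplicate row/column labels,
#' non-numeric cells in numeric blocks, and out-of-range beta-values are
#' rejected with the offending coordinate in the message.
#'
#' @param path TSV file path.
#' @param kind one of `"expression"`, `"methylation"`, `"covariates"`,
#'   `"phenotypes"`. Matrix kinds return a numeric matrix; table kinds a
#'   data.frame.
#' @return matrix or data.frame with row names from the first column.
#' @export
read_matrix <- function(path,
                        kind = c("expression", "methylation", "covariates",
                                 "phenotypes")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  rl <- as.character(df[[1]])
  if (anyDuplicated(rl))
    stop("duplicate row label(s): ",
         paste(unique(rl[duplicated(rl)]), collapse = ", "))
  cl <- colnames(df)[-1]
  if (anyDuplicated(cl))
    stop("duplicate column label(s): ",
         paste(unique(cl[duplicated(cl)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  rownames(body) <- rl
  if (kind %in% c("covariates", "phenotypes")) return(body)
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop("non-numeric cell at row '", rl[bad[1]], "', column '", cl[j], "'")
    body[[j]] <- v
  }
  m <- as.matrix(body)
  if (kind == "methylation") {
    out <- which(m < 0 | m > 1, arr.ind = TRUE)
    if (nrow(out))
      stop("beta-value out of [0,1] at row '", rl[out[1, 1]],
           "', column '", cl[out[1, 2]], "'")
  }
  m
}

#' Write a labelled matrix or table as TSV
#'
#' Counterpart of [read_matrix()]; round trips exactly at the printed
#' precision (17 significant digits for numeric matrices).
#'
#' @param x matrix or data.frame with row names.
#' @param path output path.
#' @param id_col name for the row-label column.
#' @export
write_matrix <- function(x, path, id_col = "id") {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.matrix(x))
    df[] <- lapply(df, function(v) sprintf("%.17g", v))
  df <- cbind(stats::setNames(data.frame(rownames(x),
                                         stringsAsFactors = FALSE), id_col),
              df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED-like annotation file (0-based half-open intervals)
#'
#' Columns: chrom, start, end, name and optionally class. Intervals with
#' `end <= start` are rejected; an unsorted file is sorted with a warning.
#'
#' @param path TSV path, `#` lines skipped.
#' @return data.frame chrom, start, end, name(, class), sorted by
#'   chrom/start.
#' @export
read_bed_like <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "name")
  if (!all(need %in% colnames(df)))
    stop("BED-like file must have columns: ", paste(need, collapse = ", "))
  if (any(df$end <= df$start))
    stop("interval with end <= start at row ",
         which(df$end <= df$start)[1])
  o <- order(df$chrom, df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("unsorted intervals; sorting")
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write one cohort's tables to a directory
#'
#' Expression, detection p-values, covariates, phenotypes and methylation
#' (when present) as TSV files named `<cohort_id>_<what>.tsv`.
#'
#' @param cohort a `cohort_dataset`.
#' @param dir output directory (created if needed).
#' @return invisible vector of written paths.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, what, id_col) {
    p <- file.path(dir, paste0(cohort$cohort_id, "_", what, ".tsv"))
    write_matrix(x, p, id_col = id_col)
    paths <<- c(paths, p)
  }
  wr(cohort$expression, "expression", "sample_id")
  wr(cohort$detection_p, "detection_p", "sample_id")
  wr(cohort$covariates[, setdiff(colnames(cohort$covariates), "sample_id")],
     "covariates", "sample_id")
  if (!is.null(cohort$phenotypes)) wr(cohort$phenotypes, "phenotypes",
                                      "sample_id")
  if (!is.null(cohort$methylation)) wr(cohort$methylation, "methylation",
                                       "sample_id")
  invisible(paths)
}
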