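#' Construct an OTU count table
#'
#' The central container of the 16S side of the pipeline: an integer count
#' matrix (OTUs in rows, samples in columns) together with per-sample
#' metadata and an optional rank-prefixed lineage string per OTU (the
#' `p_`/`o_`/`f_`/`g_` convention of classic QIIME-style tables).
#'
#' @param counts non-negative integer matrix, OTUs x samples, with unique
#'   rownames (OTU ids) and colnames (sample ids).
#' @param metadata data.frame with at least columns `sample_id` and `group`;
#'   every sample in `counts` must appear exactly once. Extra columns are
#'   preserved.
#' @param lineage optional named character vector mapping OTU id to a
#'   semicolon-delimited, rank-prefixed lineage string.
#' @return an object of class `daqu_otu_table` with elements `counts`,
#'   `metadata`, `lineage`.
#' @export
otu_table <- function(counts, metadata, lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  bad <- which(counts < 0 | abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at OTU '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 counts[bad[1, , drop = FALSE]]))
  storage.mode(counts) <- "double"
  counts <- round(counts)

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must contain columns 'sample_id' and 'group'")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  missing_md <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing_md) > 0)
    stop("samples missing from metadata: ", paste(missing_md, collapse = ", "))
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL

  if (!is.null(lineage)) {
    lineage <- lineage[intersect(names(lineage), rownames(counts))]
    if (length(lineage) == 0) lineage <- NULL
  }
  structure(list(counts = counts, metadata = metadata, lineage = lineage),
            class = "daqu_otu_table")
}

#' @export
print.daqu_otu_table <- function(x, ...) {
  cat(sprintf("daqu_otu_table: %d OTUs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- table(x$metadata$group)
  cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "), "\n")
  if (!is.null(x$lineage))
    cat(sprintf("lineage available for %d OTUs\n", length(x$lineage)))
  invisible(x)
}

#' @export
dim.daqu_otu_table <- function(x) dim(x$counts)

#' Subset an OTU table by OTUs and/or samples
#'
#' @param table a `daqu_otu_table`.
#' @param otus,samples character vectors of ids (or logical/integer indices).
#' @return a `daqu_otu_table` restricted to the requested rows/columns.
#' @export
subset_otu_table <- function(table, otus = NULL, samples = NULL) {
  stopifnot(inherits(table, "daqu_otu_table"))
  counts <- table$counts
  if (!is.null(otus)) {
    if (is.character(otus) && !all(otus %in% rownames(counts)))
      stop("unknown OTU id(s): ",
           paste(setdiff(otus, rownames(counts)), collapse = ", "))
    counts <- counts[otus, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples) && !all(samples %in% colnames(counts)))
      stop("unknown sample id(s): ",
           paste(setdiff(samples, colnames(counts)), collapse = ", "))
    counts <- counts[, samples, drop = FALSE]
  }
  md <- table$metadata[table$metadata$sample_id %in% colnames(counts), , drop = FALSE]
  otu_table(counts, md, table$lineage)
}

#' Read a tab-separated OTU table and its sample metadata
#'
#' Expects the classic QIIME-style layout: a header row starting with
#' `#OTU ID` followed by sample ids, one row per OTU, and optionally a
#' trailing `taxonomy` column holding the semicolon-delimited lineage.
#'
#' @param path path to the OTU table (TSV).
#' @param metadata_path path to the sample metadata (TSV with columns
#'   `sample_id`, `group`, and optionally more, e.g. `batch`).
#' @return a validated `daqu_otu_table`.
#' @export
read_otu_table <- function(path, metadata_path) {
  if (!file.exists(path)) stop("OTU table not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata not found: ", metadata_path)
  raw <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("OTU table needs an id column plus >=1 sample column")
  otu_ids <- as.character(raw[[1]])
  raw <- raw[, -1, drop = FALSE]
  lineage <- NULL
  tax_col <- which(tolower(names(raw)) == "taxonomy")
  if (length(tax_col) == 1) {
    lineage <- stats::setNames(as.character(raw[[tax_col]]), otu_ids)
    raw <- raw[, -tax_col, drop = FALSE]
  }
  counts <- matrix(NA_real_, nrow = length(otu_ids), ncol = ncol(raw),
                   dimnames = list(otu_ids, names(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("unparseable count at row %d (OTU '%s'), column '%s': '%s'",
                   i, otu_ids[i], names(raw)[j], raw[[j]][i]))
    }
    counts[, j] <- v
  }
  metadata <- utils::read.delim(metadata_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
  otu_table(counts, metadata, lineage)
}

#' Write an OTU table (and optionally its metadata) to TSV
#'
#' @param table a `daqu_otu_table`.
#' @param path output path for the count table.
#' @param metadata_path optional output path for the sample metadata.
#' @export
write_otu_table <- function(table, path, metadata_path = NULL) {
  stopifnot(inherits(table, "daqu_otu_table"))
  df <- data.frame(`#OTU ID` = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$lineage))
    df$taxonomy <- unname(table$lineage[rownames(table$counts)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(table$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
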