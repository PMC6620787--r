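#' Remove sparse, low-count OTUs
#'
#' Retains OTUs that are present (nonzero) in at least `min_samples` samples
#' AND have at least `min_total` reads summed over all samples. The defaults
#' reproduce the common screen that drops OTUs seen in a single sample or
#' carrying fewer than 20 tags.
#'
#' @param table a `daqu_otu_table`.
#' @param min_samples minimum number of samples with a nonzero count.
#' @param min_total minimum total count across samples.
#' @return the filtered `daqu_otu_table`; the sample set is unchanged.
#' @export
filter_low_occupancy <- function(table, min_samples = 2, min_total = 20) {
  stopifnot(inherits(table, "daqu_otu_table"))
  keep <- rowSums(table$counts > 0) >= min_samples &
    rowSums(table$counts) >= min_total
  out <- table
  out$counts <- table$counts[keep, , drop = FALSE]
  if (!is.null(out$lineage))
    out$lineage <- out$lineage[intersect(names(out$lineage), rownames(out$counts))]
  out
}

#' Per-sample relative abundances
#'
#' @param table a `daqu_otu_table`.
#' @return matrix of fractions (OTUs x samples); each column sums to 1.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "daqu_otu_table"))
  tot <- colSums(table$counts)
  zero <- names(tot)[tot == 0]
  if (length(zero) > 0)
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  sweep(table$counts, 2, tot, "/")
}

#' Call the core microbiome by prevalence
#'
#' An OTU belongs to the core of a sample group when it is present (nonzero)
#' in strictly more than `threshold` of the group's samples — "more than
#' 95%" with the default.
#'
#' @param table a `daqu_otu_table`.
#' @param sample_subset sample ids defining the group (default: all samples).
#' @param threshold prevalence fraction; strict `>` comparison.
#' @return a `core_set`: list with `core_otu_ids`, `prevalence` (named
#'   fractions for every OTU) and `threshold`.
#' @export
prevalence_core <- function(table, sample_subset = NULL, threshold = 0.95) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (is.null(sample_subset)) sample_subset <- colnames(table$counts)
  if (length(sample_subset) == 0) stop("sample subset is empty")
  unknown <- setdiff(sample_subset, colnames(table$counts))
  if (length(unknown) > 0)
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  prev <- rowMeans(table$counts[, sample_subset, drop = FALSE] > 0)
  structure(list(core_otu_ids = names(prev)[prev > threshold],
                 prevalence = prev, threshold = threshold),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set: %d core OTUs at prevalence > %g\n",
              length(x$core_otu_ids), x$threshold))
  invisible(x)
}

#' Partition OTUs by group presence (Venn regions)
#'
#' An OTU is "present in" a group when it has a nonzero count in at least
#' one sample of that group. Region names are `&`-joined group labels
#' (e.g. `"W&Y"`); all non-empty subsets of the groups are reported.
#'
#' @param table a `daqu_otu_table`.
#' @param grouping named character vector mapping sample id to group label;
#'   defaults to the `group` column of the metadata.
#' @param groups 2 or 3 group labels to partition over.
#' @return a `venn_partition`: list with `region_counts` and `group_totals`.
#' @export
venn_partition <- function(table, grouping = NULL, groups = NULL) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (is.null(grouping))
    grouping <- stats::setNames(as.character(table$metadata$group),
                                table$metadata$sample_id)
  if (is.null(groups)) groups <- unique(unname(grouping))
  if (!length(groups) %in% 2:3) stop("venn_partition supports 2 or 3 groups")
  presence <- sapply(groups, function(g) {
    ss <- names(grouping)[grouping == g]
    ss <- intersect(ss, colnames(table$counts))
    if (length(ss) == 0) stop("group with zero samples: ", g)
    rowSums(table$counts[, ss, drop = FALSE] > 0) > 0
  })
  k <- length(groups)
  subsets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(groups, m, simplify = FALSE)), recursive = FALSE)
  region_counts <- vapply(subsets, function(s) {
    inside <- rowSums(presence[, s, drop = FALSE]) == length(s)
    outside <- rowSums(presence[, setdiff(groups, s), drop = FALSE]) == 0
    sum(inside & outside)
  }, numeric(1))
  names(region_counts) <- vapply(subsets, paste, "", collapse = "&")
  group_totals <- colSums(presence)
  structure(list(region_counts = region_counts, group_totals = group_totals),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition regions:\n")
  print(x$region_counts)
  invisible(x)
}
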