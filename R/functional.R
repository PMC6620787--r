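#' Construct a gene relative-abundance profile
#'
#' @param abundance numeric matrix, genes x samples, with gene rownames and
#'   sample colnames; per-sample totals must not exceed 1 (+1e-9).
#' @param ko optional named KO ids (NA allowed).
#' @param ec optional named EC strings, `"a.b.c.d"`; genes mapping to
#'   several ECs use a `;`-separated string.
#' @param taxon optional named taxon node ids (or `"UNKNOWN"`).
#' @param taxon_label optional named display labels of the assigned taxa.
#' @return a `gene_profile` list.
#' @export
gene_profile <- function(abundance, ko = NULL, ec = NULL, taxon = NULL,
                         taxon_label = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    stop("abundance needs gene rownames and sample colnames")
  if (any(abundance < 0)) stop("abundances must be non-negative")
  if (any(colSums(abundance) > 1 + 1e-9))
    stop("per-sample abundance totals exceed 1")
  align <- function(v) if (is.null(v)) NULL else v[rownames(abundance)]
  structure(list(abundance = abundance, ko = align(ko), ec = align(ec),
                 taxon = align(taxon), taxon_label = align(taxon_label)),
            class = "gene_profile")
}

#' @export
print.gene_profile <- function(x, ...) {
  cat(sprintf("gene_profile: %d genes x %d samples (%d with EC)\n",
              nrow(x$abundance), ncol(x$abundance),
              if (is.null(x$ec)) 0L else sum(!is.na(x$ec))))
  invisible(x)
}

#' Read a gene profile from TSV
#'
#' Columns: `gene_id`, one column per sample, then `ko`, `ec`, `taxon_id`
#' and optionally `taxon_label`. Empty strings and `NA` mean unannotated.
#'
#' @param path path to the table.
#' @return a `gene_profile`.
#' @export
read_gene_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ann_cols <- intersect(c("ko", "ec", "taxon_id", "taxon_label"), names(df))
  sample_cols <- setdiff(names(df), c("gene_id", ann_cols))
  ab <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(ab) <- df$gene_id
  grab <- function(col) {
    if (!col %in% ann_cols) return(NULL)
    v <- as.character(df[[col]])
    v[v == ""] <- NA_character_
    stats::setNames(v, df$gene_id)
  }
  gene_profile(ab, ko = grab("ko"), ec = grab("ec"), taxon = grab("taxon_id"),
               taxon_label = grab("taxon_label"))
}

#' Write a gene profile to TSV
#'
#' @param profile a `gene_profile`.
#' @param path output path.
#' @export
write_gene_profiles <- function(profile, path) {
  stopifnot(inherits(profile, "gene_profile"))
  df <- data.frame(gene_id = rownames(profile$abundance), profile$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("ko", "ec", "taxon_id", "taxon_label")) {
    v <- profile[[sub("taxon_id", "taxon", col)]]
    if (!is.null(v)) df[[col]] <- unname(v)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Best-hit KO assignment
#'
#' Keeps the maximum-bitscore hit if its bitscore is strictly greater than
#' `min_bitscore`; ties broken by smallest e-value, then lexicographic
#' subject id.
#'
#' @param hits data.frame with columns `ko` (or `sseqid`), `bitscore`,
#'   `evalue`, `sseqid`, for a single gene; zero rows allowed.
#' @param min_bitscore strict lower bound on the best bitscore.
#' @return the winning KO id, or `NA_character_`.
#' @export
assign_best_ko <- function(hits, min_bitscore = 60) {
  if (is.null(hits) || nrow(hits) == 0) return(NA_character_)
  ord <- order(-hits$bitscore, hits$evalue, hits$sseqid)
  best <- hits[ord[1], , drop = FALSE]
  if (best$bitscore <= min_bitscore) return(NA_character_)
  as.character(if ("ko" %in% names(hits)) best$ko else best$sseqid)
}

#' EC-level abundance matrix
#'
#' Sums gene abundances by EC number within each sample. Genes without an EC
#' contribute nothing; genes with several ECs (`;`-separated) contribute
#' their full abundance to each — per-enzyme summaries, not a partition.
#'
#' @param profile a `gene_profile` with `ec` annotations.
#' @return numeric matrix, ECs x samples.
#' @export
ec_abundance <- function(profile) {
  stopifnot(inherits(profile, "gene_profile"))
  if (is.null(profile$ec)) stop("profile has no EC annotations")
  has <- !is.na(profile$ec)
  ecs_per_gene <- strsplit(profile$ec[has], ";", fixed = TRUE)
  gene_idx <- rep(which(has), lengths(ecs_per_gene))
  ec <- trimws(unlist(ecs_per_gene))
  all_ecs <- sort(unique(ec))
  out <- matrix(0, nrow = length(all_ecs), ncol = ncol(profile$abundance),
                dimnames = list(all_ecs, colnames(profile$abundance)))
  for (j in seq_len(ncol(out)))
    out[, j] <- as.numeric(tapply(profile$abundance[gene_idx, j],
                                  factor(ec, levels = all_ecs),
                                  sum, default = 0))
  out
}

#' Load a pathway map (set of EC numbers)
#'
#' Plain-text format: a header line naming the map (prefixed `#`), then one
#' EC number per line. Two maps ship with the package:
#' `"starch_glucose"` and `"cellulose"`.
#'
#' @param map path to a map file, or the name of a shipped map.
#' @return a `pathway_map`: list with `name` and `ec_numbers`.
#' @export
load_pathway_map <- function(map) {
  if (!file.exists(map)) {
    shipped <- system.file("extdata", paste0(map, ".txt"),
                           package = "daquscope")
    if (shipped == "") stop("pathway map not found: ", map)
    map <- shipped
  }
  lines <- trimws(readLines(map))
  lines <- lines[lines != ""]
  name <- if (startsWith(lines[1], "#")) sub("^#\\s*", "", lines[1]) else map
  ecs <- setdiff(lines, lines[startsWith(lines, "#")])
  bad <- ecs[!grepl("^\\d+\\.\\d+\\.\\d+\\.\\d+$", ecs)]
  if (length(bad) > 0)
    stop("invalid EC number(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, ec_numbers = unique(ecs)),
            class = "pathway_map")
}

#' Restrict an EC matrix to a pathway map and rank its enzymes
#'
#' @param ec_matrix matrix from [ec_abundance()].
#' @param map a `pathway_map` (or the name/path of one).
#' @return list with `matrix` (map ECs x samples; ECs absent from the data
#'   appear as zero rows) and `ranking` (data.frame `ec`, `mean_abundance`,
#'   sorted descending).
#' @export
pathway_profile <- function(ec_matrix, map) {
  if (!inherits(map, "pathway_map")) map <- load_pathway_map(map)
  sub <- matrix(0, nrow = length(map$ec_numbers), ncol = ncol(ec_matrix),
                dimnames = list(map$ec_numbers, colnames(ec_matrix)))
  found <- intersect(map$ec_numbers, rownames(ec_matrix))
  sub[found, ] <- ec_matrix[found, , drop = FALSE]
  means <- rowMeans(sub)
  ranking <- data.frame(ec = names(sort(means, decreasing = TRUE)),
                        mean_abundance = as.numeric(sort(means, decreasing = TRUE)),
                        stringsAsFactors = FALSE)
  list(matrix = sub, ranking = ranking)
}

#' Display transform for abundance heatmaps
#'
#' `log10(x + 1e-8)`: zero abundance maps to exactly -8.
#'
#' @param x non-negative relative abundance(s).
#' @return transformed value(s).
#' @export
display_log <- function(x) {
  if (any(x < 0)) stop("abundance must be non-negative")
  log10(x + 1e-8)
}

#' Taxon breakdown of one enzyme's genes
#'
#' Groups the genes carrying a given EC by their (lowest-level) taxon label,
#' expresses each taxon as a fraction of the enzyme's total abundance mass,
#' and pools taxa below `min_frac` into `"Others (<1%)"`.
#'
#' @param profile a `gene_profile` with `ec` and taxon labels (falls back to
#'   taxon ids when labels are absent).
#' @param ec the EC number of interest.
#' @param min_frac pooling threshold (fraction of the EC total).
#' @return named fractions summing to 1, sorted decreasing, minor taxa
#'   pooled last.
#' @export
taxon_breakdown <- function(profile, ec, min_frac = 0.01) {
  stopifnot(inherits(profile, "gene_profile"))
  labels <- if (!is.null(profile$taxon_label)) profile$taxon_label
            else profile$taxon
  if (is.null(labels)) stop("profile has no taxon annotations")
  in_ec <- !is.na(profile$ec) &
    vapply(strsplit(profile$ec, ";", fixed = TRUE),
           function(e) ec %in% trimws(e), logical(1))
  if (!any(in_ec)) stop("no genes annotated to EC ", ec)
  mass <- rowSums(profile$abundance[in_ec, , drop = FALSE])
  if (sum(mass) <= 0) stop("zero abundance mass for EC ", ec)
  lab <- labels[in_ec]
  lab[is.na(lab)] <- "UNKNOWN"
  frac <- tapply(mass, lab, sum) / sum(mass)
  frac <- sort(unclass(frac), decreasing = TRUE)
  minor <- frac < min_frac
  out <- frac[!minor]
  if (any(minor))
    out <- c(out, stats::setNames(sum(frac[minor]),
                                  sprintf("Others (<%g%%)", 100 * min_frac)))
  out
}
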