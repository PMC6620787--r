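CANONICAL_RANKS <- c("root", "kingdom", "phylum", "class", "order",
                     "family", "genus", "species")
MICROBIAL_KINGDOMS <- c("Bacteria", "Archaea", "Fungi", "Viruses")

#' Construct a rooted, ranked taxonomy tree
#'
#' @param nodes data.frame with columns `node_id`, `parent_id`, `rank`,
#'   `name`. Exactly one root (its own parent, or empty/NA parent) with rank
#'   `"root"`; all other ranks must be canonical
#'   (kingdom/phylum/class/order/family/genus/species). Nodes at
#'   non-canonical ranks (e.g. "no rank") are collapsed onto their nearest
#'   canonical ancestor: their children are re-parented and they are dropped.
#' @return a `taxonomy_tree`: list with `nodes` (data.frame), `parent`,
#'   `rank`, `name` (named vectors) and `root`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("node_id", "parent_id", "rank", "name")
  if (!all(need %in% names(nodes)))
    stop("nodes needs columns: ", paste(need, collapse = ", "))
  nodes$node_id <- as.character(nodes$node_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  if (anyDuplicated(nodes$node_id)) stop("duplicate node ids")

  is_root <- is.na(nodes$parent_id) | nodes$parent_id == "" |
    nodes$parent_id == nodes$node_id
  if (sum(is_root) != 1) stop("tree must have exactly one root")
  root <- nodes$node_id[is_root]
  nodes$parent_id[is_root] <- nodes$node_id[is_root]
  nodes$rank[is_root] <- "root"

  # collapse non-canonical ranks onto the nearest canonical ancestor
  bad <- !(nodes$rank %in% CANONICAL_RANKS)
  if (any(bad)) {
    parent <- stats::setNames(nodes$parent_id, nodes$node_id)
    keep_canon <- function(id) {
      while (bad[match(id, nodes$node_id)]) id <- parent[[id]]
      id
    }
    nodes$parent_id <- vapply(nodes$parent_id, keep_canon, "")
    nodes <- nodes[!bad, , drop = FALSE]
  }

  parent <- stats::setNames(nodes$parent_id, nodes$node_id)
  if (!all(parent %in% nodes$node_id)) stop("parent id not in tree")
  # reachability / acyclicity from every node to the root
  for (id in nodes$node_id) {
    seen <- character(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen) stop("cycle detected at node ", id)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (length(seen) > length(parent)) stop("unreachable node ", id)
    }
  }
  structure(list(nodes = nodes,
                 parent = parent,
                 rank = stats::setNames(nodes$rank, nodes$node_id),
                 name = stats::setNames(nodes$name, nodes$node_id),
                 root = root),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("taxonomy_tree: %d nodes, root '%s'\n",
              nrow(x$nodes), x$root))
  print(table(factor(x$rank, levels = CANONICAL_RANKS)))
  invisible(x)
}

#' Read a taxonomy from a 4-column TSV or NCBI-style dump files
#'
#' @param path 4-column TSV (`node_id`, `parent_id`, `rank`, `name`) — or
#'   a `nodes.dmp` when `names_path` is given.
#' @param names_path optional `names.dmp` companion (fields separated by
#'   `\t|\t`); scientific names are used.
#' @return a `taxonomy_tree`.
#' @export
read_taxonomy <- function(path, names_path = NULL) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  if (is.null(names_path)) {
    nodes <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(taxonomy_tree(nodes))
  }
  split_dmp <- function(p) {
    lines <- readLines(p)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  nd <- split_dmp(path)
  nodes <- data.frame(node_id = vapply(nd, `[`, "", 1),
                      parent_id = vapply(nd, `[`, "", 2),
                      rank = vapply(nd, `[`, "", 3),
                      stringsAsFactors = FALSE)
  nm <- split_dmp(names_path)
  sci <- vapply(nm, function(f) length(f) >= 4 && f[4] == "scientific name",
                logical(1))
  name_map <- stats::setNames(vapply(nm[sci], `[`, "", 2),
                              vapply(nm[sci], `[`, "", 1))
  nodes$name <- unname(name_map[nodes$node_id])
  nodes$name[is.na(nodes$name)] <- nodes$node_id[is.na(nodes$name)]
  # NCBI convention: "superkingdom" is the kingdom-like top split
  nodes$rank[nodes$rank == "superkingdom"] <- "kingdom"
  taxonomy_tree(nodes)
}

# Path from the root down to `id` (inclusive).
root_path <- function(id, tree) {
  path <- character(0)
  cur <- id
  while (cur != tree$root) {
    path <- c(cur, path)
    cur <- tree$parent[[cur]]
  }
  c(tree$root, path)
}

#' Lowest common ancestor of a set of taxa
#'
#' @param taxa non-empty vector of node ids, all present in `tree`.
#' @param tree a `taxonomy_tree`.
#' @return the id of the deepest node that is an ancestor-or-self of every
#'   input node.
#' @export
lca <- function(taxa, tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) stop("taxa is empty")
  unknown <- setdiff(taxa, names(tree$parent))
  if (length(unknown) > 0)
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  path <- root_path(taxa[1], tree)
  for (t in taxa[-1]) {
    p <- root_path(t, tree)
    k <- min(length(path), length(p))
    common <- which(path[seq_len(k)] == p[seq_len(k)])
    path <- path[seq_len(max(common))]
  }
  path[length(path)]
}

# Ancestor of `id` at the given rank, or NA if none on the path.
ancestor_at_rank <- function(id, tree, rank) {
  cur <- id
  repeat {
    if (tree$rank[[cur]] == rank) return(cur)
    if (cur == tree$root) return(NA_character_)
    cur <- tree$parent[[cur]]
  }
}

#' Read a tabular alignment hit file
#'
#' 14 tab-separated columns: the standard 12-column tabular alignment format
#' (qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) plus qlen and staxid.
#'
#' @param path path to the hit table (no header).
#' @return data.frame of hits.
#' @export
read_hits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "staxid")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(cols))
    stop("expected ", length(cols), " columns, got ", ncol(df))
  names(df) <- cols
  df$staxid <- as.character(df$staxid)
  df
}

#' Alignment coverage of the query ("match percentage")
#'
#' Alignment length divided by the query length, as a percentage, capped at
#' 100 (gapped alignments can exceed the query length). The divisor is the
#' query length by default — the usual convention for gene-catalog
#' annotation; pass subject lengths via `denom` to use subject coverage.
#'
#' @param aln_length alignment length(s) in residues.
#' @param query_length query length(s); must be positive.
#' @param denom optional alternative denominator (e.g. subject lengths).
#' @return percentage(s) in `[0, 100]`.
#' @export
match_pct <- function(aln_length, query_length, denom = NULL) {
  d <- if (is.null(denom)) query_length else denom
  if (any(d <= 0)) stop("length denominator must be positive")
  pmin(100, 100 * aln_length / d)
}

#' Filter-cascade for the alignment hits of one query
#'
#' Stage 1 keeps hits with query coverage >= `min_match` percent AND percent
#' identity >= `min_identity`. Stage 2 computes the minimum e-value among
#' stage-1 survivors and keeps hits with e-value <= `evalue_factor` times
#' that minimum (with `evalue_window = "pre"` the minimum is taken over all
#' input hits instead).
#'
#' @param hits data.frame of hits for a single query (columns as in
#'   [read_hits()]).
#' @param min_match query-coverage threshold (percent).
#' @param min_identity percent-identity threshold.
#' @param evalue_factor width of the e-value window.
#' @param evalue_window `"post"` (minimum over stage-1 survivors, default)
#'   or `"pre"` (minimum over all hits).
#' @return the surviving rows (possibly zero rows).
#' @export
filter_hits <- function(hits, min_match = 80, min_identity = 65,
                        evalue_factor = 10,
                        evalue_window = c("post", "pre")) {
  evalue_window <- match.arg(evalue_window)
  if (nrow(hits) == 0) return(hits)
  if (length(unique(hits$qseqid)) > 1)
    stop("filter_hits expects hits of a single query")
  cov <- match_pct(hits$length, hits$qlen)
  stage1 <- hits[cov >= min_match & hits$pident >= min_identity, , drop = FALSE]
  if (nrow(stage1) == 0) return(stage1)
  e_min <- if (evalue_window == "post") min(stage1$evalue) else min(hits$evalue)
  stage1[stage1$evalue <= evalue_factor * e_min, , drop = FALSE]
}

#' Annotate one gene by filtered-hit LCA
#'
#' Applies [filter_hits()] and assigns the lowest common ancestor of the
#' surviving subject taxa. Genes with no hits, or none surviving the
#' cascade, are `UNKNOWN`.
#'
#' @param hits data.frame of hits for one gene (may have zero rows).
#' @param tree a `taxonomy_tree`.
#' @param min_match,min_identity,evalue_factor,evalue_window passed to
#'   [filter_hits()].
#' @return list with `taxon` (node id or `"UNKNOWN"`), `rank`, and `kingdom`
#'   (kingdom-rank ancestor name, `"UNCLASSIFIED"` when the assignment sits
#'   at the root, `"UNKNOWN"` when there is no assignment).
#' @export
annotate_gene <- function(hits, tree, min_match = 80, min_identity = 65,
                          evalue_factor = 10,
                          evalue_window = c("post", "pre")) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  surv <- if (is.null(hits) || nrow(hits) == 0) hits
          else filter_hits(hits, min_match, min_identity, evalue_factor,
                           match.arg(evalue_window))
  if (is.null(surv) || nrow(surv) == 0)
    return(list(taxon = "UNKNOWN", rank = NA_character_, kingdom = "UNKNOWN"))
  node <- lca(surv$staxid, tree)
  kg <- ancestor_at_rank(node, tree, "kingdom")
  list(taxon = node,
       rank = tree$rank[[node]],
       kingdom = if (is.na(kg)) "UNCLASSIFIED" else unname(tree$name[[kg]]))
}

#' Annotate every gene in a hit table
#'
#' @param hits data.frame of hits for many genes ([read_hits()] layout).
#' @param tree a `taxonomy_tree`.
#' @param gene_ids genes to annotate; genes without hits become `UNKNOWN`.
#'   Defaults to the queries present in `hits`.
#' @param ... thresholds passed to [annotate_gene()].
#' @return data.frame with columns `gene_id`, `taxon`, `rank`, `kingdom`.
#' @export
annotate_genes <- function(hits, tree, gene_ids = NULL, ...) {
  if (is.null(gene_ids)) gene_ids <- unique(hits$qseqid)
  by_gene <- split(seq_len(nrow(hits)), hits$qseqid)
  rows <- lapply(gene_ids, function(g) {
    h <- if (g %in% names(by_gene)) hits[by_gene[[g]], , drop = FALSE]
         else hits[0, , drop = FALSE]
    a <- annotate_gene(h, tree, ...)
    data.frame(gene_id = g, taxon = a$taxon, rank = a$rank,
               kingdom = a$kingdom, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kingdom-level abundance profile
#'
#' Pools gene relative abundance by kingdom: `Unknown` (no surviving hits),
#' the four microbial kingdoms, and `Others` (plants, animals, protists and
#' anything whose assignment has no kingdom-rank ancestor).
#'
#' @param annotations data.frame from [annotate_genes()].
#' @param abundances named numeric vector of per-gene relative abundance
#'   covering every annotated gene.
#' @return named fractions over {Unknown, Bacteria, Archaea, Fungi, Viruses,
#'   Others}, summing to 1.
#' @export
kingdom_profile <- function(annotations, abundances) {
  missing_ab <- setdiff(annotations$gene_id, names(abundances))
  if (length(missing_ab) > 0)
    stop("missing abundance for gene(s): ", paste(missing_ab, collapse = ", "))
  ab <- abundances[annotations$gene_id]
  cat_of <- ifelse(annotations$kingdom == "UNKNOWN", "Unknown",
                   ifelse(annotations$kingdom %in% MICROBIAL_KINGDOMS,
                          annotations$kingdom, "Others"))
  lv <- c("Unknown", MICROBIAL_KINGDOMS, "Others")
  tot <- tapply(ab, factor(cat_of, levels = lv), sum, default = 0)
  out <- as.numeric(tot) / sum(ab)
  stats::setNames(out, lv)
}

#' Retain microbial genes and renormalize their abundances
#'
#' Keeps genes annotated to Bacteria, Archaea, Fungi or Viruses; by default
#' the retained abundances are renormalized to sum to 1 (within-microbe
#' proportions).
#'
#' @param annotations data.frame from [annotate_genes()].
#' @param abundances named per-gene relative abundances.
#' @param renormalize logical; rescale retained abundances to sum to 1.
#' @return list with `annotations` (retained rows) and `abundances`.
#' @export
retain_microbial <- function(annotations, abundances, renormalize = TRUE) {
  keep <- annotations$kingdom %in% MICROBIAL_KINGDOMS
  if (!any(keep)) stop("no microbial genes to retain")
  ann <- annotations[keep, , drop = FALSE]
  ab <- abundances[ann$gene_id]
  if (sum(ab) <= 0) stop("zero microbial abundance mass")
  if (renormalize) ab <- ab / sum(ab)
  list(annotations = ann, abundances = ab)
}
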