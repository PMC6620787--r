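#' Specification of a simulated grouped community
#'
#' Defaults emulate the two immature starter groups of the study design
#' (white and yellow, 27 samples each): lognormal baseline composition,
#' Dirichlet-multinomial sampling noise, and sequencing depths spanning the
#' study's observed range so the rarefaction path is always exercised.
#'
#' @param groups named integer vector: samples per group.
#' @param n_otus number of OTUs.
#' @param base_log_mean,base_log_sd lognormal parameters of the baseline
#'   composition.
#' @param markers data.frame with columns `otu`, `group` (label) and
#'   `log2fc`: spiked differential OTUs, multiplied by `2^log2fc` in that
#'   group.
#' @param markers_at how to read `markers$otu`: `"index"` (row index into
#'   the table) or `"rank"` (baseline-abundance rank, 1 = most abundant).
#'   Rank placement keeps planted effects at observable abundances instead
#'   of the lognormal tails, where a spiked OTU may never be sampled.
#' @param exclusive optional named list (group -> OTU indices) of
#'   group-exclusive OTUs (zero baseline elsewhere).
#' @param concentration Dirichlet concentration scale (overdispersion;
#'   larger = less dispersed).
#' @param depth_range integer range reads are drawn from, uniformly.
#' @param seed integer RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(groups = c(W = 27, Y = 27), n_otus = 300,
                           base_log_mean = 0, base_log_sd = 1.5,
                           markers = NULL, markers_at = c("index", "rank"),
                           exclusive = NULL,
                           concentration = 50,
                           depth_range = c(988, 20000), seed = 1) {
  if (any(groups < 1)) stop("each group needs >= 1 sample")
  if (concentration <= 0) stop("concentration must be positive")
  if (depth_range[1] < 1) stop("depth_range minimum must be >= 1")
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    if (any(markers$otu > n_otus | markers$otu < 1))
      stop("marker index out of range")
    if (!all(markers$group %in% names(groups)))
      stop("marker group not among the groups")
  }
  structure(list(groups = groups, n_otus = n_otus,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 markers = markers, markers_at = match.arg(markers_at),
                 exclusive = exclusive,
                 concentration = concentration,
                 depth_range = as.integer(depth_range),
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Community spec mirroring the full study layout
#'
#' Two immature groups of 27 samples (W, Y) and 131 mature samples across
#' six batches (B0..B5 of 26/24/4/32/30/15).
#'
#' @param n_otus number of OTUs.
#' @param seed integer seed.
#' @param ... further arguments to [community_spec()].
#' @return a `community_spec`.
#' @export
study_design_spec <- function(n_otus = 300, seed = 1, ...) {
  community_spec(groups = c(W = 27, Y = 27, B0 = 26, B1 = 24, B2 = 4,
                            B3 = 32, B4 = 30, B5 = 15),
                 n_otus = n_otus, seed = seed, ...)
}

#' Simulate a grouped OTU count table
#'
#' Per sample: proportions ~ Dirichlet(concentration x group-adjusted
#' baseline), counts ~ multinomial at a uniformly drawn depth. Spiked marker
#' OTUs get their baseline multiplied by `2^log2fc` in the marked group;
#' group-exclusive OTUs have zero baseline elsewhere.
#'
#' @param spec a [community_spec()].
#' @return list with `table` (a `daqu_otu_table`) and `truth` (list:
#'   `marker_otus`, `spec`, `seed`).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    n_otus <- spec$n_otus
    otu_ids <- sprintf("OTU%05d", seq_len(n_otus))
    baseline <- stats::rlnorm(n_otus, spec$base_log_mean, spec$base_log_sd)
    baseline <- baseline / sum(baseline)
    markers <- spec$markers
    if (!is.null(markers) && identical(spec$markers_at, "rank")) {
      by_rank <- order(baseline, decreasing = TRUE)
      markers$otu <- by_rank[markers$otu]
    }
    cols <- list(); sids <- character(0); grp <- character(0)
    for (g in names(spec$groups)) {
      base_g <- baseline
      if (!is.null(spec$exclusive)) {
        foreign <- unlist(spec$exclusive[setdiff(names(spec$exclusive), g)])
        base_g[foreign] <- 0
      }
      if (!is.null(markers)) {
        mk <- markers[markers$group == g, , drop = FALSE]
        base_g[mk$otu] <- base_g[mk$otu] * 2^mk$log2fc
      }
      base_g <- base_g / sum(base_g)
      alpha <- spec$concentration * base_g
      for (s in seq_len(spec$groups[[g]])) {
        gam <- stats::rgamma(n_otus, shape = alpha, rate = 1)
        p <- if (sum(gam) > 0) gam / sum(gam) else base_g
        depth <- sample(spec$depth_range[1]:spec$depth_range[2], 1)
        cols[[length(cols) + 1]] <- stats::rmultinom(1, depth, p)[, 1]
        sids <- c(sids, sprintf("%s.%02d", g, s))
        grp <- c(grp, g)
      }
    }
    counts <- do.call(cbind, cols)
    dimnames(counts) <- list(otu_ids, sids)
    md <- data.frame(sample_id = sids, group = grp, batch = grp,
                     stringsAsFactors = FALSE)
    truth <- list(
      marker_otus = if (is.null(markers)) character(0)
                    else unique(otu_ids[markers$otu]),
      spec = spec, seed = spec$seed)
    list(table = otu_table(counts, md), truth = truth)
  })
}

#' Simulate a balanced ranked taxonomy tree
#'
#' Rooted at `"root"`, with the named kingdoms at the first level and a
#' fixed branching factor per rank below. The default kingdoms comprise the
#' four microbial ones plus two non-microbial clades for retention tests;
#' passing a `kingdom` entry in `branching` replaces them with generic
#' kingdoms `K1..Kb`.
#'
#' @param branching named integer vector of branching factors for ranks
#'   below kingdom (phylum/class/order/family/genus/species, default 2
#'   each); an optional `kingdom` entry overrides the kingdom set size.
#' @param seed unused for the balanced topology; kept so every generator is
#'   a pure function of (spec, seed).
#' @param kingdoms kingdom names used when `branching` has no `kingdom` entry.
#' @return a `taxonomy_tree` whose node names carry their clade path.
#' @export
simulate_taxonomy <- function(branching = c(phylum = 2, class = 2, order = 2,
                                            family = 2, genus = 2, species = 2),
                              seed = 1,
                              kingdoms = c("Bacteria", "Archaea", "Fungi",
                                           "Viruses", "Metazoa",
                                           "Viridiplantae")) {
  if (any(branching < 1)) stop("branching factors must be >= 1")
  lower <- c("phylum", "class", "order", "family", "genus", "species")
  if ("kingdom" %in% names(branching)) {
    kingdoms <- paste0("K", seq_len(branching[["kingdom"]]))
  }
  b <- stats::setNames(rep(2L, length(lower)), lower)
  b[intersect(names(branching), lower)] <-
    branching[intersect(names(branching), lower)]
  nodes <- data.frame(node_id = "root", parent_id = NA_character_,
                      rank = "root", name = "root", stringsAsFactors = FALSE)
  frontier <- data.frame(node_id = paste0("k", seq_along(kingdoms)),
                         parent_id = "root", rank = "kingdom",
                         name = kingdoms, stringsAsFactors = FALSE)
  nodes <- rbind(nodes, frontier)
  for (r in lower) {
    children <- do.call(rbind, lapply(seq_len(nrow(frontier)), function(i) {
      data.frame(
        node_id = paste0(frontier$node_id[i], "_", substr(r, 1, 1),
                         seq_len(b[[r]])),
        parent_id = frontier$node_id[i],
        rank = r,
        name = paste0(frontier$name[i], "|", substr(r, 1, 1), seq_len(b[[r]])),
        stringsAsFactors = FALSE)
    }))
    nodes <- rbind(nodes, children)
    frontier <- children
  }
  taxonomy_tree(nodes)
}

# All leaf (deepest-rank) descendants of `node`.
leaf_descendants <- function(node, tree) {
  kids <- names(tree$parent)[tree$parent == node & names(tree$parent) != node]
  if (length(kids) == 0) return(node)
  unlist(lapply(kids, leaf_descendants, tree = tree))
}

direct_children <- function(node, tree)
  names(tree$parent)[tree$parent == node & names(tree$parent) != node]

hit_template <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = numeric(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0), evalue = numeric(0),
             bitscore = numeric(0), qlen = numeric(0), staxid = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate alignment hit tables with planted LCAs
#'
#' Each gene gets a planted truth node at `clade_rank`; its genuine hits go
#' to leaves under that node (covering at least two distinct children, so
#' the LCA of the hit set is exactly the planted node), with identities,
#' coverages and e-values that pass the default filter cascade. Decoy hits
#' point outside the clade and are engineered to fail at least one filter —
#' unless `stress = TRUE`, in which case they pass and degrade recovery
#' toward ancestors of the truth.
#'
#' @param n_genes number of genes.
#' @param tree a `taxonomy_tree`.
#' @param clade_rank rank of the planted truth nodes.
#' @param decoy_rate probability in [0, 1) that a gene receives decoy hits.
#' @param seed integer RNG seed.
#' @param stress logical; make decoys pass the filters.
#' @return list with `hits` (data.frame in [read_hits()] layout) and `truth`
#'   (list with `planted_lcas`, `seed`).
#' @export
simulate_hits <- function(n_genes, tree, clade_rank = "genus",
                          decoy_rate = 0.2, seed = 1, stress = FALSE) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  if (decoy_rate < 0 || decoy_rate >= 1) stop("decoy_rate must be in [0, 1)")
  if (n_genes == 0) {
    empty <- hit_template()[0, ]
    return(list(hits = empty,
                truth = list(planted_lcas = character(0), seed = seed)))
  }
  candidates <- names(tree$rank)[tree$rank == clade_rank]
  if (length(candidates) == 0) stop("no node at rank ", clade_rank)
  with_seed(seed, {
    rows <- vector("list", n_genes)
    planted <- character(n_genes)
    all_leaves <- names(tree$rank)[tree$rank == "species"]
    for (i in seq_len(n_genes)) {
      gid <- sprintf("gene%05d", i)
      truth <- sample(candidates, 1)
      planted[i] <- truth
      kids <- direct_children(truth, tree)
      k <- sample(3:10, 1)
      leaves <- if (length(kids) >= 2) {
        two <- sample(kids, 2)
        c(vapply(two, function(kid) sample(leaf_descendants(kid, tree), 1), ""),
          sample(leaf_descendants(truth, tree), k - 2, replace = TRUE))
      } else sample(leaf_descendants(truth, tree), k, replace = TRUE)
      qlen <- sample(150:600, 1)
      e_min <- 10^stats::runif(1, -50, -10)
      good <- data.frame(
        qseqid = gid, sseqid = paste0("prot_", leaves, "_", seq_along(leaves)),
        pident = stats::runif(k, 70, 99),
        length = round(qlen * stats::runif(k, 0.85, 1)),
        mismatch = 0L, gapopen = 0L, qstart = 1L, qend = qlen,
        sstart = 1L, send = qlen,
        evalue = e_min * stats::runif(k, 1, 9),
        bitscore = stats::runif(k, 80, 250),
        qlen = qlen, staxid = leaves, stringsAsFactors = FALSE)
      good$evalue[1] <- e_min
      if (stats::runif(1) < decoy_rate) {
        n_dec <- sample(1:3, 1)
        in_clade <- leaf_descendants(truth, tree)
        off <- setdiff(all_leaves, in_clade)
        dec_leaves <- sample(off, n_dec, replace = TRUE)
        decoys <- good[rep(1, n_dec), , drop = FALSE]
        decoys$sseqid <- paste0("decoy_", dec_leaves, "_", seq_len(n_dec))
        decoys$staxid <- dec_leaves
        if (stress) {
          decoys$pident <- stats::runif(n_dec, 70, 99)
          decoys$length <- round(qlen * stats::runif(n_dec, 0.85, 1))
          decoys$evalue <- e_min * stats::runif(n_dec, 1, 9)
        } else {
          # each decoy fails at least one cascade filter
          mode <- sample(1:3, n_dec, replace = TRUE)
          decoys$pident <- ifelse(mode == 1, stats::runif(n_dec, 30, 64.5),
                                  stats::runif(n_dec, 70, 99))
          decoys$length <- ifelse(mode == 2,
                                  round(qlen * stats::runif(n_dec, 0.2, 0.75)),
                                  round(qlen * stats::runif(n_dec, 0.85, 1)))
          decoys$evalue <- ifelse(mode == 3,
                                  e_min * stats::runif(n_dec, 20, 1e4),
                                  e_min * stats::runif(n_dec, 1, 9))
        }
        good <- rbind(good, decoys)
      }
      rows[[i]] <- good
    }
    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    list(hits = hits,
         truth = list(planted_lcas = stats::setNames(planted,
                                                     sprintf("gene%05d",
                                                             seq_len(n_genes))),
                      seed = seed))
  })
}

#' Simulate EC-annotated gene profiles with planted mass ratios
#'
#' Genes draw their EC from `ec_pool` with probability proportional to the
#' pool weights, so the expected EC abundance-mass ratios equal the weight
#' ratios (e.g. a 3:1 alpha-glucosidase : glucoamylase plant). Per-sample
#' gene abundances are symmetric-Dirichlet; a fraction of genes stays
#' unannotated; taxon labels are drawn from the tree's genus-level clades.
#'
#' @param n_genes number of genes.
#' @param samples sample ids.
#' @param ec_pool named numeric vector: EC number -> target mass weight.
#' @param tree a `taxonomy_tree` supplying taxon labels.
#' @param no_ec_frac fraction of genes left without EC annotation.
#' @param seed integer RNG seed.
#' @return list with `profile` (a `gene_profile`) and `truth` (list with
#'   `ec_weights`, `seed`).
#' @export
simulate_gene_profiles <- function(n_genes, samples, ec_pool, tree = NULL,
                                   no_ec_frac = 0.2, seed = 1) {
  if (length(ec_pool) == 0) stop("ec_pool is empty")
  with_seed(seed, {
    gids <- sprintf("gene%05d", seq_len(n_genes))
    ab <- matrix(stats::rgamma(n_genes * length(samples), shape = 1), n_genes,
                 dimnames = list(gids, samples))
    ab <- sweep(ab, 2, colSums(ab), "/")
    ec <- rep(NA_character_, n_genes)
    annotated <- stats::runif(n_genes) >= no_ec_frac
    ec[annotated] <- sample(names(ec_pool), sum(annotated), replace = TRUE,
                            prob = ec_pool / sum(ec_pool))
    names(ec) <- gids
    taxon <- taxon_label <- NULL
    if (!is.null(tree)) {
      genera <- names(tree$rank)[tree$rank == "genus"]
      taxon <- stats::setNames(sample(genera, n_genes, replace = TRUE), gids)
      taxon_label <- stats::setNames(unname(tree$name[taxon]), gids)
    }
    list(profile = gene_profile(ab, ec = ec, taxon = taxon,
                                taxon_label = taxon_label),
         truth = list(ec_weights = ec_pool, seed = seed))
  })
}

#' Simulate physicochemical property tables with planted correlations
#'
#' Each linked property is generated by a Gaussian copula on the OTU's
#' relative-abundance ranks with the requested target Spearman rho
#' (Pearson correlation on normal scores of 2 sin(pi rho / 6)); unlinked
#' properties are independent standard normals.
#'
#' @param table a `daqu_otu_table`.
#' @param links data.frame with columns `otu`, `property`, `rho`
#'   (|rho| < 1); may be NULL for a fully independent table.
#' @param properties property column names.
#' @param seed integer RNG seed.
#' @return list with `properties` (data.frame: `sample_id` + one column per
#'   property) and `truth` (the links, seed).
#' @export
simulate_properties <- function(table, links = NULL,
                                properties = c("AC", "SU", "MO", "ST",
                                               "SA", "LI", "PA", "CA"),
                                seed = 1) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (!is.null(links)) {
    links <- as.data.frame(links)
    if (any(abs(links$rho) >= 1)) stop("|rho| must be < 1")
    unknown <- setdiff(links$otu, rownames(table$counts))
    if (length(unknown) > 0)
      stop("unknown OTU in links: ", paste(unknown, collapse = ", "))
    if (!all(links$property %in% properties))
      stop("unknown property in links")
  }
  ra <- relative_abundance(table)
  n <- ncol(ra)
  with_seed(seed, {
    out <- data.frame(sample_id = colnames(ra), stringsAsFactors = FALSE)
    for (pn in properties) {
      link <- if (is.null(links)) NULL
              else links[links$property == pn, , drop = FALSE]
      if (!is.null(link) && nrow(link) >= 1) {
        z <- stats::qnorm((rank(ra[link$otu[1], ], ties.method = "average") -
                             0.5) / n)
        r <- 2 * sin(pi * link$rho[1] / 6)
        out[[pn]] <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
      } else out[[pn]] <- stats::rnorm(n)
    }
    list(properties = out,
         truth = list(links = links, seed = seed))
  })
}
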