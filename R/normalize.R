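# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cumulative sum scaling (CSS) normalization
#'
#' For each sample j, the scaling factor s_j is the sum of counts no larger
#' than the chosen quantile q_j of that sample's positive counts; normalized
#' values are `counts / s_j * 1000`. Quantiles use the lower empirical
#' (type-1) definition, so ties resolve downward.
#'
#' With `quantile = "adaptive"` the quantile is chosen data-driven: the
#' relative cumulative-sum curves of all samples are compared to their
#' median curve, and the smallest quantile at which the median deviation
#' from the reference starts growing unstably (relative increment above
#' `instability`) is used; if the curves never destabilize the fixed 0.5
#' fallback applies.
#'
#' @param table a `daqu_otu_table` in which every sample has a positive total.
#' @param quantile a fraction in (0, 1] or `"adaptive"`.
#' @param instability relative-increment threshold of the adaptive rule.
#' @return list with `normalized` (matrix, OTUs x samples), `scaling_factors`
#'   (named positive numbers) and `quantile` (the fraction actually used).
#' @export
css_normalize <- function(table, quantile = "adaptive", instability = 0.1) {
  stopifnot(inherits(table, "daqu_otu_table"))
  counts <- table$counts
  tot <- colSums(counts)
  if (any(tot <= 0))
    stop("sample(s) with no positive count: ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  if (identical(quantile, "adaptive")) {
    quantile <- css_adaptive_quantile(counts, instability)
  } else {
    if (!is.numeric(quantile) || length(quantile) != 1 ||
        quantile <= 0 || quantile > 1)
      stop("quantile must be in (0, 1] or \"adaptive\"")
  }
  s <- vapply(seq_len(ncol(counts)), function(j) {
    pos <- counts[counts[, j] > 0, j]
    q <- stats::quantile(pos, probs = quantile, type = 1, names = FALSE)
    sum(counts[counts[, j] <= q, j])
  }, numeric(1))
  names(s) <- colnames(counts)
  if (any(s <= 0)) stop("zero CSS scaling factor for sample(s): ",
                        paste(names(s)[s <= 0], collapse = ", "))
  normalized <- sweep(counts, 2, s, "/") * 1000
  list(normalized = normalized, scaling_factors = s, quantile = quantile)
}

# Smallest quantile at which the per-sample relative cumulative-sum curves
# start diverging from their median reference; 0.5 when they never do.
css_adaptive_quantile <- function(counts, instability = 0.1) {
  probs <- seq(0.05, 0.95, by = 0.05)
  curves <- sapply(seq_len(ncol(counts)), function(j) {
    pos <- counts[counts[, j] > 0, j]
    qs <- stats::quantile(pos, probs = probs, type = 1, names = FALSE)
    vapply(qs, function(q) sum(pos[pos <= q]), numeric(1)) / sum(pos)
  })
  ref <- apply(curves, 1, stats::median)
  dev <- apply(abs(curves - ref), 1, stats::median)
  inc <- diff(dev)
  rel <- ifelse(dev[-length(dev)] > 0, inc / dev[-length(dev)], 0)
  hit <- which(rel > instability)
  if (length(hit) == 0) return(0.5)
  probs[hit[1]]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`.
#' Samples with fewer than `depth` total reads are dropped with a warning.
#' The draw is deterministic given `seed`.
#'
#' @param table a `daqu_otu_table`.
#' @param depth target reads per sample (the study rarefied at the observed
#'   minimum, 988).
#' @param seed integer RNG seed.
#' @return the rarefied `daqu_otu_table`.
#' @export
rarefy <- function(table, depth, seed = 1) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (!is.numeric(depth) || depth < 1) stop("depth must be a positive integer")
  depth <- as.integer(depth)
  tot <- colSums(table$counts)
  drop <- names(tot)[tot < depth]
  if (length(drop) > 0)
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    length(drop), depth, paste(drop, collapse = ", ")))
  keep <- setdiff(colnames(table$counts), drop)
  if (length(keep) == 0) stop("no sample reaches depth ", depth)
  counts <- table$counts[, keep, drop = FALSE]
  out <- with_seed(seed, {
    apply(counts, 2, function(col) {
      if (sum(col) == depth) return(col)
      pool <- rep.int(seq_along(col), col)
      drawn <- pool[sample.int(length(pool), depth)]
      tabulate(drawn, nbins = length(col))
    })
  })
  if (!is.matrix(out))  # single-OTU tables: apply() drops the dimension
    out <- matrix(out, nrow = nrow(counts), dimnames = dimnames(counts))
  rownames(out) <- rownames(table$counts)
  md <- table$metadata[table$metadata$sample_id %in% keep, , drop = FALSE]
  otu_table(out, md, table$lineage)
}

#' Alpha diversity at a fixed rarefaction depth
#'
#' Shannon entropy (base-2 by default) and observed OTU richness, computed
#' on a rarefied table. With `iterations > 1` the indices are averaged over
#' repeated independent rarefactions (seeds derived from `seed`).
#'
#' @param table a `daqu_otu_table`.
#' @param depth rarefaction depth; defaults to the observed minimum total.
#' @param seed integer RNG seed.
#' @param base logarithm base of the Shannon index.
#' @param iterations number of rarefaction draws to average over.
#' @return data.frame with columns `sample_id`, `shannon`, `observed_otus`.
#' @export
alpha_diversity <- function(table, depth = NULL, seed = 1, base = 2,
                            iterations = 1) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (is.null(depth)) depth <- min(colSums(table$counts))
  one <- function(s) {
    r <- rarefy(table, depth, seed = s)
    p <- sweep(r$counts, 2, colSums(r$counts), "/")
    shannon <- apply(p, 2, function(q) {
      q <- q[q > 0]
      -sum(q * log(q, base = base))
    })
    data.frame(sample_id = colnames(r$counts), shannon = shannon,
               observed_otus = colSums(r$counts > 0), row.names = NULL)
  }
  if (iterations <= 1) return(one(seed))
  draws <- lapply(seq_len(iterations), function(i) one(seed + i - 1L))
  out <- draws[[1]]
  for (d in draws[-1]) {
    out$shannon <- out$shannon + d$shannon
    out$observed_otus <- out$observed_otus + d$observed_otus
  }
  out$shannon <- out$shannon / iterations
  out$observed_otus <- out$observed_otus / iterations
  out
}
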