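# All permutations of 1..n as an n!-row matrix (n <= 9).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, k] <- n
    out[rows, -k] <- sub
  }
  out
}

#' Spearman rank correlation with p-value
#'
#' rho is the product-moment correlation of mid-ranks (ties averaged). The
#' p-value comes from the t-approximation with n-2 degrees of freedom; for
#' n <= 9 an exact permutation test over all n! orderings is used instead.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, and `degenerate` (TRUE when either vector
#'   is constant, in which case rho is NA).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("need equal lengths >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, degenerate = TRUE))
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= 9) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- all_perms(n)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    rho_perm <- as.numeric(stats::cor(rx, t(ry_perm)))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p = min(1, p), degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (step-up, capped at 1, order-preserving).
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact when both groups have at most 10 observations: every assignment of
#' the pooled mid-ranks to the two groups is enumerated and the two-sided
#' p-value is the fraction of assignments whose U statistic deviates from
#' its null mean at least as much as the observed one. Larger samples use
#' the normal approximation with tie and continuity corrections.
#'
#' @param a,b numeric vectors (non-empty).
#' @return list with `statistic` (Mann-Whitney U of `a`), `p` (two-sided),
#'   and `exact`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na <= 10 && nb <= 10) {
    mu <- na * nb / 2
    dev_obs <- abs(u_obs - mu)
    picks <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[picks], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= dev_obs - 1e-12)
    return(list(statistic = u_obs, p = p, exact = TRUE))
  }
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  list(statistic = u_obs, p = p, exact = FALSE)
}

#' Bray-Curtis distances between samples
#'
#' d(s, t) = sum|x - y| / sum(x + y) over OTUs, in `[0, 1]`.
#'
#' @param table a `daqu_otu_table` or a non-negative abundance matrix
#'   (OTUs x samples).
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "daqu_otu_table")) table$counts else as.matrix(table)
  if (any(m < 0)) stop("abundances must be non-negative")
  empty <- colSums(m) == 0
  if (sum(empty) >= 2)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(m)[empty], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  diag(d) <- 0
  d
}

perm_result <- function(statistic, p_value, n_permutations, seed, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = n_permutations, seed = seed,
                 method = method),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%s permutations, seed %s)\n",
              x$method, x$statistic, x$p_value,
              if (is.na(x$n_permutations)) "all" else x$n_permutations,
              x$seed))
  invisible(x)
}

# pseudo-F from squared distances and a grouping
permanova_f <- function(D2, labels) {
  n <- nrow(D2)
  g <- length(unique(labels))
  ss_t <- sum(D2[upper.tri(D2)]) / n
  ss_w <- 0
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    ss_w <- ss_w + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  ((ss_t - ss_w) / (g - 1)) / (ss_w / (n - g))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' pseudo-F = `[(SS_T - SS_W)/(g-1)] / [SS_W/(n-g)]` with SS_T the mean
#' squared inter-sample distance and SS_W its within-group analogue. The
#' p-value permutes the group labels: p = (1 + b)/(1 + B) where b counts
#' permutations with F at least the observed. `n_perm = "exact"` enumerates
#' all n! label orderings and reports the exact proportion instead.
#'
#' @param D distance matrix (square, symmetric, zero diagonal).
#' @param labels group label per sample; >= 2 groups of >= 2 samples.
#' @param n_perm number of random permutations, or `"exact"`.
#' @param seed RNG seed for the permutations.
#' @return a `perm_test` result.
#' @export
permanova <- function(D, labels, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  if (all(D == 0)) stop("degenerate all-zero distance matrix")
  labels <- as.character(labels)
  if (length(labels) != nrow(D)) stop("labels must match the matrix dimension")
  if (length(unique(labels)) < 2 || any(table(labels) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  D2 <- D^2
  f_obs <- permanova_f(D2, labels)
  if (identical(n_perm, "exact")) {
    perms <- all_perms(length(labels))
    f_perm <- apply(perms, 1, function(p) permanova_f(D2, labels[p]))
    return(perm_result(f_obs, mean(f_perm >= f_obs - 1e-12), NA_integer_,
                       NA_integer_, "PERMANOVA (exact)"))
  }
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      permanova_f(D2, sample(labels)) >= f_obs - 1e-12, logical(1)))
  })
  perm_result(f_obs, (1 + b) / (1 + n_perm), n_perm, seed, "PERMANOVA")
}

#' Mantel test between two distance matrices
#'
#' Statistic: correlation (Spearman by default) between the upper-triangle
#' entries. Significance by simultaneous row/column permutation of the
#' second matrix, p = (1 + b)/(1 + B); `n_perm = "exact"` enumerates all n!
#' permutations.
#'
#' @param D1,D2 distance matrices of equal dimension, symmetric with zero
#'   diagonals.
#' @param n_perm number of permutations or `"exact"`.
#' @param seed RNG seed.
#' @param method `"spearman"` (rank-based, default) or `"pearson"`.
#' @return a `perm_test`; `statistic` is NA (degenerate) when either
#'   triangle is constant.
#' @export
mantel <- function(D1, D2, n_perm = 999, seed = 1,
                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in dimension")
  ut <- upper.tri(D1)
  v1 <- D1[ut]
  if (length(unique(v1)) == 1 || length(unique(D2[ut])) == 1)
    return(perm_result(NA_real_, NA_real_, NA_integer_, seed,
                       "Mantel (degenerate)"))
  if (method == "spearman") {
    v1 <- rank(v1)
    R2 <- matrix(0, nrow(D2), ncol(D2))
    R2[ut] <- rank(D2[ut])          # rank set is permutation-invariant
    R2 <- R2 + t(R2)
  } else R2 <- D2
  stat_for <- function(p) stats::cor(v1, R2[p, p][ut])
  r_obs <- stat_for(seq_len(nrow(D1)))
  if (identical(n_perm, "exact")) {
    perms <- all_perms(nrow(D1))
    r_perm <- apply(perms, 1, stat_for)
    return(perm_result(r_obs, mean(r_perm >= r_obs - 1e-12), NA_integer_,
                       NA_integer_, "Mantel (exact)"))
  }
  b <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      stat_for(sample.int(nrow(D1))) >= r_obs - 1e-12, logical(1)))
  })
  perm_result(r_obs, (1 + b) / (1 + n_perm), n_perm, seed,
              paste0("Mantel (", method, ")"))
}

#' Spearman correlation network of core OTUs
#'
#' All pairwise Spearman correlations between the relative abundances of a
#' set of (core) OTUs, with Benjamini-Hochberg adjustment across the
#' C(k, 2) pairs and a significance mask at `alpha`. Display labels follow
#' the "taxon_lastdigits" convention: the last lineage field joined with the
#' trailing digits of the OTU id.
#'
#' @param table a `daqu_otu_table` already restricted to the core OTUs (and
#'   the sample group of interest).
#' @param alpha significance level applied to the adjusted p-values.
#' @return a `correlation_network`: list with `rho`, `p_adjusted`,
#'   `significant`, `labels`.
#' @export
core_correlation_network <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "daqu_otu_table"))
  k <- nrow(table$counts)
  if (k < 2) stop("need >= 2 core OTUs")
  ra <- relative_abundance(table)
  ids <- rownames(ra)
  rho <- diag(1, k); dimnames(rho) <- list(ids, ids)
  praw <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  pairs <- utils::combn(k, 2)
  pv <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    s <- spearman_cor(ra[i, ], ra[j, ])
    rho[i, j] <- rho[j, i] <- s$rho
    pv[c] <- s$p
  }
  padj <- bh_fdr(pv)
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1, c]; j <- pairs[2, c]
    praw[i, j] <- praw[j, i] <- padj[c]
  }
  labels <- vapply(ids, function(id) {
    digits <- sub("^.*?(\\d+)$", "\\1", id)
    suffix <- substr(digits, max(1, nchar(digits) - 2), nchar(digits))
    if (!is.null(table$lineage) && id %in% names(table$lineage)) {
      fields <- strsplit(table$lineage[[id]], ";", fixed = TRUE)[[1]]
      paste0(trimws(fields[length(fields)]), "_", suffix)
    } else id
  }, "")
  sig <- !is.na(praw) & praw <= alpha
  diag(sig) <- FALSE
  structure(list(rho = rho, p_adjusted = praw, significant = sig,
                 labels = labels, alpha = alpha),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d OTUs, %d significant pair(s) at alpha %g\n",
              nrow(x$rho), sum(x$significant[upper.tri(x$significant)]),
              x$alpha))
  invisible(x)
}

#' Screen OTUs against physicochemical properties
#'
#' Spearman correlation of every OTU's relative abundance against each
#' property, with BH adjustment within each property (properties are
#' separate test families). Samples missing from the property table are
#' dropped with a warning.
#'
#' @param table a `daqu_otu_table`.
#' @param properties data.frame with a `sample_id` column plus one numeric
#'   column per property.
#' @return named list (one element per property) of data.frames with columns
#'   `otu_id`, `rho`, `p`, `p_adjusted`, ordered as the table's OTUs.
#' @export
property_screen <- function(table, properties) {
  stopifnot(inherits(table, "daqu_otu_table"))
  if (!"sample_id" %in% names(properties))
    stop("properties needs a sample_id column")
  common <- intersect(colnames(table$counts), properties$sample_id)
  if (length(common) == 0) stop("no overlapping samples")
  missing_s <- setdiff(colnames(table$counts), common)
  if (length(missing_s) > 0)
    warning(sprintf("dropping %d sample(s) without property data: %s",
                    length(missing_s), paste(missing_s, collapse = ", ")))
  ra <- relative_abundance(subset_otu_table(table, samples = common))
  props <- properties[match(common, properties$sample_id),
                      setdiff(names(properties), "sample_id"), drop = FALSE]
  out <- lapply(names(props), function(pn) {
    res <- t(vapply(rownames(ra), function(o) {
      s <- spearman_cor(ra[o, ], props[[pn]])
      c(rho = s$rho, p = s$p)
    }, c(rho = 0, p = 0)))
    ok <- !is.na(res[, "p"])
    padj <- rep(NA_real_, nrow(res))
    padj[ok] <- bh_fdr(res[ok, "p"])
    data.frame(otu_id = rownames(ra), rho = res[, "rho"], p = res[, "p"],
               p_adjusted = padj, row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- names(props)
  out
}
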