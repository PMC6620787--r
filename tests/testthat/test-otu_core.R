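test_that("OTU tables round-trip through TSV with lineage and metadata", {
  counts <- matrix(c(5, 0, 12, 3, 7, 0), nrow = 3,
                   dimnames = list(c("OTU1", "OTU2", "OTU3"), c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), group = c("W", "Y"),
                   batch = c("b1", "b1"), stringsAsFactors = FALSE)
  lin <- c(OTU1 = "p_Firmicutes;g_Bacillus", OTU2 = "p_Actinobacteria",
           OTU3 = "p_Firmicutes;f_Bacillaceae")
  tab <- otu_table(counts, md, lin)

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_otu_table(tab, f1, f2)
  back <- read_otu_table(f1, f2)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$metadata$group, tab$metadata$group)
  expect_identical(back$lineage[names(lin)], lin)
})

test_that("malformed tables are rejected with the offending cell named", {
  md <- data.frame(sample_id = c("s1", "s2"), group = c("W", "Y"))
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t4\t-3", "OTU2\t1\t2"), f1)
  write.table(md, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_otu_table(f1, f2), "OTU1.*s2|s2.*OTU1")

  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t4\tx", "OTU2\t1\t2"), f1)
  expect_error(read_otu_table(f1, f2), "unparseable.*OTU1.*s2")

  writeLines(c("#OTU ID\ts1\ts2", "OTU1\t4\t1", "OTU1\t1\t2"), f1)
  expect_error(read_otu_table(f1, f2), "duplicate")

  writeLines(c("#OTU ID\ts1\ts3", "OTU1\t4\t1"), f1)
  expect_error(read_otu_table(f1, f2), "missing from metadata.*s3")
})

test_that("low-occupancy screen drops single-sample and <20-tag OTUs", {
  counts <- rbind(one_sample_100 = c(100, 0, 0),
                  three_samples_19 = c(7, 6, 6),
                  three_samples_20 = c(7, 7, 6),
                  two_samples_30 = c(15, 15, 0))
  colnames(counts) <- paste0("s", 1:3)
  tab <- tiny_table(counts)
  kept <- rownames(filter_low_occupancy(tab)$counts)
  expect_false("one_sample_100" %in% kept)   # present in only one sample
  expect_false("three_samples_19" %in% kept) # fewer than 20 tags
  expect_true(all(c("three_samples_20", "two_samples_30") %in% kept))
  expect_identical(colnames(filter_low_occupancy(tab)$counts),
                   colnames(tab$counts))
  # empty table stays empty
  empty <- filter_low_occupancy(tab, min_total = 1e6)
  expect_identical(nrow(empty$counts), 0L)
  expect_identical(nrow(filter_low_occupancy(empty)$counts), 0L)
})

test_that("the screen is idempotent and monotone in both thresholds", {
  set.seed(11)
  counts <- matrix(rpois(200, 2) * rbinom(200, 1, 0.5), nrow = 20)
  tab <- tiny_table(counts)
  once <- filter_low_occupancy(tab)
  expect_identical(filter_low_occupancy(once)$counts, once$counts)
  n_kept <- function(ms, mt)
    nrow(filter_low_occupancy(tab, min_samples = ms, min_total = mt)$counts)
  for (ms in 1:4) expect_gte(n_kept(ms, 10), n_kept(ms + 1, 10))
  for (mt in c(1, 5, 10, 20)) expect_gte(n_kept(2, mt), n_kept(2, mt + 5))
})

test_that("relative abundances are column-normalized fractions", {
  tab <- tiny_table(matrix(c(1, 3), nrow = 2, dimnames = list(NULL, "s1")))
  expect_equal(unname(relative_abundance(tab)[, 1]), c(0.25, 0.75))
  one <- tiny_table(matrix(5, 1, 1))
  expect_equal(unname(relative_abundance(one)[1, 1]), 1.0)
  sim <- simulate_community(community_spec(groups = c(A = 4, B = 4),
                                           n_otus = 50, seed = 2))
  expect_equal(unname(colSums(relative_abundance(sim$table))),
               rep(1, 8), tolerance = 1e-12)
  bad <- tiny_table(matrix(c(1, 0, 0, 0), 2, dimnames = list(NULL, c("s1", "s2"))))
  expect_error(relative_abundance(bad), "s2")
})

test_that("CSS normalization matches a direct implementation of the formula", {
  # published formula, implemented independently: s_j sums counts <= the
  # type-1 quantile of the sample's positive counts; values scaled by 1000
  css_oracle <- function(counts, q) {
    sapply(seq_len(ncol(counts)), function(j) {
      pos <- sort(counts[counts[, j] > 0, j])
      qv <- pos[ceiling(q * length(pos))]
      s <- sum(counts[counts[, j] <= qv, j])
      counts[, j] / s * 1000
    })
  }
  tab <- tiny_table(matrix(c(10, 5, 1, 1, 1), ncol = 1))
  r <- css_normalize(tab, quantile = 0.5)
  expect_equal(unname(r$scaling_factors), 3)
  expect_equal(unname(r$normalized[, 1]),
               c(10, 5, 1, 1, 1) / 3 * 1000, tolerance = 1e-9)

  set.seed(7)
  for (i in 1:5) {
    counts <- matrix(rpois(60, 5) + rbinom(60, 1, 0.2) * rpois(60, 100),
                     nrow = 12)
    counts[1, ] <- counts[1, ] + 1  # keep samples non-empty
    tab <- tiny_table(counts)
    for (q in c(0.25, 0.5, 0.75)) {
      got <- css_normalize(tab, quantile = q)$normalized
      expect_equal(unname(got), unname(css_oracle(counts, q)),
                   tolerance = 1e-9)
    }
  }
})

test_that("CSS is invariant to uniform scaling and rejects bad quantiles", {
  counts <- matrix(c(10, 5, 1, 1, 1, 3, 9, 2, 0, 4), ncol = 2)
  tab <- tiny_table(counts)
  base <- css_normalize(tab, quantile = 0.5)
  doubled <- tiny_table(counts * 2)
  r2 <- css_normalize(doubled, quantile = 0.5)
  expect_equal(unname(r2$normalized), unname(base$normalized))
  expect_equal(unname(r2$scaling_factors), unname(base$scaling_factors) * 2)
  expect_true(all(base$scaling_factors > 0))
  # all-equal counts in a sample normalize to all-equal values
  eq <- css_normalize(tiny_table(matrix(4, 5, 1)), quantile = 0.5)
  expect_equal(length(unique(eq$normalized[, 1])), 1L)
  expect_error(css_normalize(tab, quantile = 0), "quantile")
  expect_error(css_normalize(tab, quantile = 1.2), "quantile")
  # adaptive mode returns a usable fraction
  ad <- css_normalize(tab, quantile = "adaptive")
  expect_true(ad$quantile > 0 && ad$quantile <= 1)
})

test_that("rarefaction is an exact seeded subsample that drops shallow samples", {
  counts <- matrix(c(500, 300, 188, 20, 30, 50), ncol = 2,
                   dimnames = list(paste0("o", 1:3), c("deep", "shallow")))
  tab <- tiny_table(counts)
  expect_warning(r <- rarefy(tab, 988, seed = 4), "shallow")
  expect_identical(colnames(r$counts), "deep")
  expect_equal(unname(colSums(r$counts)), 988)
  # depth equal to the total leaves the sample untouched
  same <- suppressWarnings(rarefy(tab, 100, seed = 1))
  expect_equal(unname(colSums(same$counts)), c(100, 100))
  exact <- tiny_table(matrix(c(60, 40), ncol = 1))
  expect_identical(rarefy(exact, 100, seed = 3)$counts, exact$counts)
  # determinism
  expect_identical(suppressWarnings(rarefy(tab, 500, seed = 9))$counts,
                   suppressWarnings(rarefy(tab, 500, seed = 9))$counts)
  expect_error(rarefy(tab, 0), "depth")
})

test_that("alpha diversity reproduces hand-computed Shannon values", {
  even4 <- tiny_table(matrix(rep(25, 4), ncol = 1))
  a <- alpha_diversity(even4, depth = 100, seed = 1)
  expect_equal(a$shannon, 2.0)
  expect_equal(a$observed_otus, 4L)

  single <- tiny_table(matrix(50, 1, 1))
  a1 <- alpha_diversity(single, depth = 50, seed = 1)
  expect_equal(a1$shannon, 0.0)
  expect_equal(a1$observed_otus, 1L)

  mix <- tiny_table(matrix(c(1, 1, 2), ncol = 1))
  expect_equal(alpha_diversity(mix, depth = 4, seed = 1)$shannon, 1.5)

  # shannon <= log2(observed), equality iff uniform
  sim <- simulate_community(community_spec(groups = c(A = 6), n_otus = 40,
                                           seed = 5))
  div <- alpha_diversity(sim$table, depth = 988, seed = 2)
  expect_true(all(div$shannon <= log2(div$observed_otus) + 1e-9))
})

test_that("core calling uses a strict prevalence inequality", {
  # 125/131 (0.954) qualifies at 0.95; 124/131 (0.947) does not
  counts <- rbind(core125 = c(rep(1, 125), rep(0, 6)),
                  edge124 = c(rep(1, 124), rep(0, 7)),
                  absent = rep(0, 131))
  colnames(counts) <- paste0("m", 1:131)
  tab <- tiny_table(counts)
  cs <- prevalence_core(tab, threshold = 0.95)
  expect_true("core125" %in% cs$core_otu_ids)
  expect_false("edge124" %in% cs$core_otu_ids)
  expect_equal(unname(cs$prevalence["absent"]), 0)
  expect_true(all(cs$prevalence[cs$core_otu_ids] > cs$threshold))

  # with 20 samples, > 0.95 forces presence in all 20
  c20 <- cbind(matrix(1, 2, 19), c(1, 0))
  colnames(c20) <- paste0("x", 1:20)
  rownames(c20) <- c("all20", "only19")
  cs20 <- prevalence_core(tiny_table(c20), threshold = 0.95)
  expect_identical(cs20$core_otu_ids, "all20")

  # threshold edge cases: 0 keeps everything present, 1 keeps nothing
  expect_setequal(prevalence_core(tab, threshold = 0)$core_otu_ids,
                  c("core125", "edge124"))
  expect_length(prevalence_core(tab, threshold = 1)$core_otu_ids, 0)
  expect_error(prevalence_core(tab, sample_subset = "nope"), "unknown sample")
})

test_that("venn partition agrees with brute-force set algebra", {
  set.seed(21)
  for (rep in 1:5) {
    n_otu <- sample(10:50, 1)
    groups <- c("W", "Y", "M")
    n_s <- c(3, 4, 5)
    counts <- matrix(rbinom(n_otu * 12, 1, 0.4) * rpois(n_otu * 12, 5),
                     nrow = n_otu)
    grp <- rep(groups, n_s)
    tab <- tiny_table(counts, groups = grp)
    vp <- venn_partition(tab, groups = groups)

    # oracle: per-OTU membership sets, counted per region
    member <- apply(counts, 1, function(row)
      paste(sort(unique(grp[row > 0])), collapse = ","))
    oracle <- table(member[member != ""])
    for (region in names(vp$region_counts)) {
      key <- paste(sort(strsplit(region, "&")[[1]]), collapse = ",")
      expected <- if (key %in% names(oracle)) unname(oracle[[key]]) else 0
      expect_equal(unname(vp$region_counts[[region]]), expected)
    }
    expect_equal(sum(vp$region_counts), sum(member != ""))
    for (g in groups)
      expect_equal(unname(vp$group_totals[[g]]),
                   sum(grepl(g, member, fixed = TRUE)))
  }
})

test_that("venn partition handles exclusive OTUs and bad groupings", {
  counts <- diag(3) * 5
  tab <- tiny_table(counts, groups = c("W", "Y", "M"))
  vp <- venn_partition(tab, groups = c("W", "Y", "M"))
  expect_equal(unname(vp$region_counts[c("W", "Y", "M")]), c(1, 1, 1))
  expect_equal(unname(vp$region_counts[["W&Y&M"]]), 0)
  grouping <- stats::setNames(c("W", "Y", "M"), colnames(tab$counts))
  expect_error(venn_partition(tab, grouping, groups = c("W", "Y", "Z")),
               "zero samples")
})
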