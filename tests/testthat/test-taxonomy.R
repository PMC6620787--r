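test_that("taxonomy trees validate structure and collapse odd ranks", {
  expect_s3_class(mini_tree(), "taxonomy_tree")
  # two roots
  expect_error(taxonomy_tree(data.frame(
    node_id = c("a", "b"), parent_id = c(NA, NA),
    rank = c("root", "root"), name = c("a", "b"))), "exactly one root")
  # cycle
  expect_error(taxonomy_tree(data.frame(
    node_id = c("r", "a", "b"), parent_id = c(NA, "b", "a"),
    rank = c("root", "genus", "genus"), name = c("r", "a", "b"))),
    "cycle|unreachable")
  # a "no rank" node between kingdom and genus collapses away
  tr <- taxonomy_tree(data.frame(
    node_id = c("r", "k", "x", "g"),
    parent_id = c(NA, "r", "k", "x"),
    rank = c("root", "kingdom", "no rank", "genus"),
    name = c("r", "Bacteria", "clade X", "Bacillus")))
  expect_false("x" %in% names(tr$parent))
  expect_identical(unname(tr$parent[["g"]]), "k")
})

test_that("taxonomies load from 4-column TSV and NCBI-style dumps", {
  tsv <- tempfile()
  write.table(mini_tree()$nodes, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tr <- read_taxonomy(tsv)
  expect_identical(sort(names(tr$parent)), sort(names(mini_tree()$parent)))

  nodes_dmp <- tempfile(); names_dmp <- tempfile()
  writeLines(c("1\t|\t1\t|\troot\t|",
               "2\t|\t1\t|\tsuperkingdom\t|",
               "3\t|\t2\t|\tgenus\t|"), nodes_dmp)
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tsynonym\t|",
               "3\t|\tBacillus\t|\t\t|\tscientific name\t|"), names_dmp)
  trd <- read_taxonomy(nodes_dmp, names_dmp)
  expect_identical(unname(trd$name[["2"]]), "Bacteria")
  expect_identical(unname(trd$rank[["2"]]), "kingdom")
})

test_that("match percentage is query coverage capped at 100", {
  expect_equal(match_pct(80, 100), 80)
  expect_equal(match_pct(120, 100), 100)  # gapped alignment
  expect_equal(match_pct(79, 100), 79)    # just under an 80% threshold
  expect_error(match_pct(50, 0), "positive")
})

test_that("the hit filter cascade applies coverage/identity then the e-value window", {
  tr <- mini_tree()
  hits <- rbind(hit_row(evalue = 1e-50, staxid = "bsub"),
                hit_row(evalue = 5e-50, staxid = "lpla"),
                hit_row(evalue = 2e-49, staxid = "anig"))
  surv <- filter_hits(hits)
  expect_setequal(surv$staxid, c("bsub", "lpla"))  # 2e-49 > 10 x 1e-50

  # identity 64.9 fails the 65% stage outright
  expect_identical(nrow(filter_hits(hit_row(pident = 64.9))), 0L)
  expect_identical(nrow(filter_hits(hit_row(pident = 65))), 1L)  # inclusive
  # coverage boundary: 80% inclusive, 79% out
  expect_identical(nrow(filter_hits(hit_row(length = 80))), 1L)
  expect_identical(nrow(filter_hits(hit_row(length = 79))), 0L)
  # a lone survivor is its own e-value minimum
  expect_identical(nrow(filter_hits(hit_row())), 1L)
  expect_error(filter_hits(rbind(hit_row(qseqid = "g1"),
                                 hit_row(qseqid = "g2"))), "single query")
  # the pre-filter window uses the minimum over all hits
  mixed <- rbind(hit_row(evalue = 1e-60, pident = 50),  # fails stage 1
                 hit_row(evalue = 1e-50))
  expect_identical(nrow(filter_hits(mixed, evalue_window = "post")), 1L)
  expect_identical(nrow(filter_hits(mixed, evalue_window = "pre")), 0L)
})

test_that("the filter cascade shrinks predictably", {
  # With the e-value window anchored on the pre-filter minimum, raising any
  # threshold can only shrink the survivor set. (Under the post-stage
  # anchor, removing the best-e-value hit can shift the window upward, so
  # only survivors-subset-of-input holds there.)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    hits <- do.call(rbind, lapply(seq_len(n), function(k)
      hit_row(pident = runif(1, 40, 100), length = sample(50:120, 1),
              evalue = 10^runif(1, -60, -5), staxid = "bsub",
              sseqid = paste0("p", k))))
    base_pre <- filter_hits(hits, evalue_window = "pre")$sseqid
    for (alt in list(filter_hits(hits, min_match = 90, evalue_window = "pre"),
                     filter_hits(hits, min_identity = 80,
                                 evalue_window = "pre"),
                     filter_hits(hits, evalue_factor = 2,
                                 evalue_window = "pre")))
      expect_true(all(alt$sseqid %in% base_pre))
    # post mode: survivors are always a subset of the input, and narrowing
    # the window alone still shrinks the set
    base_post <- filter_hits(hits)$sseqid
    expect_true(all(base_post %in% hits$sseqid))
    expect_true(all(filter_hits(hits, evalue_factor = 2)$sseqid %in%
                      base_post))
  }
})

test_that("LCA matches a brute-force ancestor-set intersection oracle", {
  tr <- mini_tree()
  expect_identical(lca("bac", tr), "bac")               # singleton
  expect_identical(lca(c("bac", "lac"), tr), "firm")    # sibling genera
  expect_identical(lca(c("bsub", "anig"), tr), "r")     # across kingdoms
  expect_error(lca(c("bac", "nope"), tr), "unknown")
  expect_error(lca(character(0), tr), "empty")

  ancestor_set <- function(id, tree) {
    out <- id
    while (id != tree$root) { id <- tree$parent[[id]]; out <- c(out, id) }
    out
  }
  brute_lca <- function(taxa, tree) {
    common <- Reduce(intersect, lapply(taxa, ancestor_set, tree = tree))
    depth <- vapply(common, function(x) length(ancestor_set(x, tree)),
                    numeric(1))
    common[which.max(depth)]
  }
  set.seed(99)
  big <- simulate_taxonomy(c(phylum = 2, class = 2, order = 2, family = 2,
                             genus = 2, species = 2))  # < 200 node clades
  nodes <- names(big$parent)
  for (i in 1:25) {
    taxa <- sample(nodes, sample(1:5, 1))
    expect_identical(lca(taxa, big), brute_lca(taxa, big))
  }
  # order-invariance and idempotence; lca of a superset is an ancestor
  taxa <- sample(nodes, 4)
  a <- lca(taxa, big)
  expect_identical(lca(rev(taxa), big), a)
  expect_identical(lca(a, big), a)
  expect_true(a %in% ancestor_set(lca(c(taxa, sample(nodes, 2)), big), big) ||
                lca(c(taxa, sample(nodes, 2)), big) %in% ancestor_set(a, big))
})

test_that("gene annotation falls back to UNKNOWN and reports kingdoms", {
  tr <- mini_tree()
  none <- annotate_gene(hit_row()[0, ], tr)
  expect_identical(none$taxon, "UNKNOWN")
  expect_identical(none$kingdom, "UNKNOWN")

  one <- annotate_gene(rbind(hit_row(staxid = "bsub"),
                             hit_row(staxid = "bsub", sseqid = "p2")), tr)
  expect_identical(one$taxon, "bsub")
  expect_identical(one$rank, "species")
  expect_identical(one$kingdom, "Bacteria")

  # hits straddling kingdoms resolve to the root -> kingdom UNCLASSIFIED
  cross <- annotate_gene(rbind(hit_row(staxid = "bsub"),
                               hit_row(staxid = "anig", sseqid = "p2")), tr)
  expect_identical(cross$taxon, "r")
  expect_identical(cross$kingdom, "UNCLASSIFIED")

  # all hits filtered out -> UNKNOWN
  filt <- annotate_gene(hit_row(pident = 30), tr)
  expect_identical(filt$taxon, "UNKNOWN")
})

test_that("kingdom profiles pool correctly and conserve mass", {
  tr <- mini_tree()
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    taxon = c("bsub", "anig", "UNKNOWN"),
                    rank = c("species", "species", NA),
                    kingdom = c("Bacteria", "Fungi", "UNKNOWN"),
                    stringsAsFactors = FALSE)
  ab <- c(g1 = 0.25, g2 = 0.25, g3 = 0.5)
  kp <- kingdom_profile(ann, ab)
  expect_equal(sum(kp), 1, tolerance = 1e-12)
  expect_equal(unname(kp["Unknown"]), 0.5)
  expect_equal(unname(kp["Bacteria"]), 0.25)
  expect_equal(unname(kp["Fungi"]), 0.25)

  # equal-abundance split between bacteria and fungi
  kp2 <- kingdom_profile(ann[1:2, ], c(g1 = 0.1, g2 = 0.1))
  expect_equal(unname(kp2[c("Bacteria", "Fungi")]), c(0.5, 0.5))

  # all genes unknown
  kp3 <- kingdom_profile(ann[3, ], ab)
  expect_equal(unname(kp3["Unknown"]), 1)

  # UNCLASSIFIED and non-microbial kingdoms pool into Others
  ann4 <- data.frame(gene_id = "g4", taxon = "r", rank = "root",
                     kingdom = "UNCLASSIFIED")
  expect_equal(unname(kingdom_profile(ann4, c(g4 = 1))["Others"]), 1)
  expect_error(kingdom_profile(ann, ab[1:2]), "missing abundance")
})

test_that("microbial retention matches manual subsetting arithmetic", {
  ann <- data.frame(gene_id = paste0("g", 1:4),
                    taxon = c("bsub", "anig", "r", "UNKNOWN"),
                    rank = c("species", "species", "root", NA),
                    kingdom = c("Bacteria", "Fungi", "UNCLASSIFIED", "UNKNOWN"),
                    stringsAsFactors = FALSE)
  ab <- c(g1 = 0.2, g2 = 0.3, g3 = 0.1, g4 = 0.4)
  ret <- retain_microbial(ann, ab)
  expect_setequal(ret$annotations$gene_id, c("g1", "g2"))
  expect_equal(sum(ret$abundances), 1, tolerance = 1e-12)
  expect_equal(unname(ret$abundances["g1"]), 0.2 / 0.5)  # manual oracle
  # pure microbial input with renormalize = FALSE is the identity
  pure <- retain_microbial(ann[1:2, ], ab[1:2], renormalize = FALSE)
  expect_identical(pure$abundances, ab[1:2])
  expect_error(retain_microbial(ann[3:4, ], ab), "no microbial")
})

test_that("hit tables round-trip through the 14-column reader", {
  tr <- simulate_taxonomy()
  sh <- simulate_hits(5, tr, decoy_rate = 0, seed = 8)
  f <- tempfile()
  write.table(sh$hits, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- read_hits(f)
  expect_equal(back$evalue, sh$hits$evalue)
  expect_identical(back$staxid, sh$hits$staxid)
  expect_identical(back$qseqid, sh$hits$qseqid)
})
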