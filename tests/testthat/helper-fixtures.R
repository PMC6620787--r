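# Tiny in-code fixtures shared across test files.

tiny_table <- function(counts, groups = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("otu", seq_len(nrow(counts)))
  if (is.null(groups)) groups <- rep("A", ncol(counts))
  otu_table(counts,
            data.frame(sample_id = colnames(counts), group = groups,
                       stringsAsFactors = FALSE))
}

# Independent permutation generator (recursive insertion), deliberately a
# different construction from the package's internal enumerator.
perm_list <- function(n) {
  if (n == 1) return(list(1L))
  shorter <- perm_list(n - 1L)
  out <- list()
  for (p in shorter)
    for (pos in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
  out
}

# Small hand-rolled taxonomy: root -> 2 kingdoms -> ... used where a full
# simulated tree is overkill.
mini_tree <- function() {
  taxonomy_tree(data.frame(
    node_id  = c("r", "bact", "fungi", "firm", "asco", "bac", "lac", "asp",
                 "bsub", "lpla", "anig"),
    parent_id = c(NA, "r", "r", "bact", "fungi", "firm", "firm", "asco",
                  "bac", "lac", "asp"),
    rank = c("root", "kingdom", "kingdom", "phylum", "phylum", "genus",
             "genus", "genus", "species", "species", "species"),
    name = c("root", "Bacteria", "Fungi", "Firmicutes", "Ascomycota",
             "Bacillus", "Lactobacillus", "Aspergillus", "B. subtilis",
             "L. plantarum", "A. niger"),
    stringsAsFactors = FALSE))
}

# Minimal hit row(s) in the 14-column tabular layout.
hit_row <- function(qseqid = "g1", staxid = "bsub", pident = 90,
                    length = 90, qlen = 100, evalue = 1e-30,
                    bitscore = 150, sseqid = "prot1") {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = qlen, sstart = 1L, send = qlen, evalue = evalue,
             bitscore = bitscore, qlen = qlen, staxid = staxid,
             stringsAsFactors = FALSE)
}
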