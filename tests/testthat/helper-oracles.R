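# Independent brute-force oracles and random fixture generators used across
# the suite. These deliberately re-derive everything from first principles
# (genetic code, per-column scans, leaf-set LCAs) so they share no code path
# with the package implementation.

ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1L, paste,
                    collapse = "")

# fourfold-degenerate codons derived from the genetic code itself: a codon
# is fourfold iff all four third-position variants encode one amino acid
oracle_is_fourfold_codon <- function(codon) {
  pre <- substr(codon, 1L, 2L)
  fam <- paste0(pre, c("A", "C", "G", "T"))
  aas <- Biostrings::GENETIC_CODE[fam]
  !anyNA(aas) && length(unique(aas)) == 1L
}

oracle_4dtv_counts <- function(row_a, row_b) {
  n <- nchar(row_a) / 3L
  sites <- 0L; tv <- 0L
  for (i in seq_len(n)) {
    ca <- substr(row_a, 3L * i - 2L, 3L * i)
    cb <- substr(row_b, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (substr(ca, 1L, 2L) != substr(cb, 1L, 2L)) next
    if (!oracle_is_fourfold_codon(ca) || !oracle_is_fourfold_codon(cb)) next
    sites <- sites + 1L
    ta <- substr(ca, 3L, 3L); tb <- substr(cb, 3L, 3L)
    pur <- c("A", "G")
    if ((ta %in% pur) != (tb %in% pur)) tv <- tv + 1L
  }
  c(sites = sites, tv = tv)
}

random_codon_row <- function(n_codons) {
  pool <- c(ALL_CODONS, rep("---", 8L), "A-C", "ANT", "NNN")
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# naive reconciliation: map every gene-tree node through the LCA of the
# species of ALL its descendant leaves, computed by ancestor-path
# intersection rather than pairwise recursion
oracle_ancestor_path <- function(tree, node) {
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    path <- c(path, node)
  }
  path
}

oracle_lca_of_tips <- function(species_tree, sp_labels) {
  tips <- match(unique(sp_labels), species_tree$tip.label)
  paths <- lapply(tips, function(t) oracle_ancestor_path(species_tree, t))
  common <- Reduce(intersect, paths)
  # the deepest common ancestor is the one with the longest own path
  depths <- vapply(common, function(n)
    length(oracle_ancestor_path(species_tree, n)), 0L)
  common[which.max(depths)]
}

oracle_reconcile <- function(gene_tree, species_tree, g2s) {
  ntip <- ape::Ntip(gene_tree)
  n_nodes <- ntip + gene_tree$Nnode
  mapping <- integer(n_nodes)
  label <- rep(NA_character_, n_nodes)
  tips_under <- vector("list", n_nodes)
  for (i in seq_len(ntip)) tips_under[[i]] <- i
  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    tips_under[[po[i, 1L]]] <- c(tips_under[[po[i, 1L]]],
                                 tips_under[[po[i, 2L]]])
  for (v in seq_len(n_nodes)) {
    sp <- g2s[gene_tree$tip.label[tips_under[[v]]]]
    mapping[v] <- oracle_lca_of_tips(species_tree, sp)
    label[v] <- if (v <= ntip) "leaf" else NA_character_
  }
  ch <- split(gene_tree$edge[, 2L], gene_tree$edge[, 1L])
  for (v in (ntip + 1L):n_nodes) {
    kids <- ch[[as.character(v)]]
    label[v] <- if (any(mapping[kids] == mapping[v])) "duplication"
                else "speciation"
  }
  list(mapping = mapping, label = label)
}

random_reconciliation_case <- function(n_species, n_genes) {
  st <- ape::rtree(n_species, tip.label = paste0("S", seq_len(n_species)))
  gt <- ape::rtree(n_genes, tip.label = paste0("g", seq_len(n_genes)))
  g2s <- stats::setNames(sample(st$tip.label, n_genes, replace = TRUE),
                         gt$tip.label)
  list(gene_tree = gt, species_tree = st, g2s = g2s)
}

# hypergeometric upper-tail by explicit binomial-coefficient summation
oracle_fisher_tail <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  js <- k:jmax
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# simple genome fixture: two mirrored scaffolds of shared families plus a
# tandem pair, for direct classifier checks
toy_genome <- function(genome_id = "G1") {
  famA <- paste0("F", 1:7)
  pos <- data.frame(
    gene_id = c(paste0("a", 1:7), paste0("b", 1:7)),
    genome_id = genome_id,
    scaffold_id = rep(c("s1", "s2"), each = 7L),
    gene_index = rep(0:6, 2L),
    stringsAsFactors = FALSE)
  fam <- data.frame(gene_id = pos$gene_id,
                    family_id = rep(famA, 2L),
                    species_id = "sp1", stringsAsFactors = FALSE)
  gene_order(pos, fam)
}
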