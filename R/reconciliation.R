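# parent vector indexed by node number; 0 for the root
phylo_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

node_depths <- function(tree) {
  parent <- phylo_parents(tree)
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  root <- ape::Ntip(tree) + 1L
  depth[root] <- 0L
  # edges in preorder guarantee parents are visited first
  for (i in seq_len(nrow(tree$edge))) {
    e <- tree$edge[i, ]
    depth[e[2L]] <- depth[e[1L]] + 1L
  }
  depth
}

#' Stable branch names for a species tree
#'
#' Branches are identified by their child node: leaves keep their species
#' label, internal nodes use the tree's node labels when present and are
#' otherwise numbered `N1`, `N2`, ... in ape's internal node order (`N1`
#' is the root). The root "branch" collects duplications older than the
#' first speciation.
#'
#' @param species_tree rooted `phylo`.
#' @return character vector indexed by node number.
#' @export
species_branch_names <- function(species_tree) {
  ntip <- ape::Ntip(species_tree)
  nn <- species_tree$Nnode
  lab <- species_tree$node.label
  if (is.null(lab) || any(!nzchar(lab)) || anyDuplicated(lab))
    lab <- paste0("N", seq_len(nn))
  c(species_tree$tip.label, lab)
}

#' LCA reconciliation of a gene tree against a species tree
#'
#' Maps every gene-tree node v to the most recent species-tree node M(v)
#' that could have hosted it: leaves map to their gene's species and an
#' internal node maps to the species-tree LCA of its children's images.
#' A node is a duplication when it maps to the same species-tree node as
#' at least one of its children (the two child lineages coexist in one
#' species), otherwise a speciation. This is the parsimony reconciliation
#' used by gene-tree-aware duplication tagging; on correct input trees it
#' recovers the branch on which each duplication occurred, including the
#' signature of delayed rediploidization, where paralogues that only began
#' diverging after a later speciation are assigned to a daughter branch.
#'
#' @param gene_tree rooted binary `phylo`; tips are gene ids.
#' @param species_tree rooted binary `phylo`; tips are species ids.
#' @param gene_to_species named character vector (gene id -> species id)
#'   or a data.frame with columns gene_id, species_id.
#' @return object of class `reconciled_tree`: the input trees plus, for
#'   every gene-tree node, the mapped species node (`mapping`), its branch
#'   name (`branch`), and the node label (`leaf`, `speciation` or
#'   `duplication`).
#' @export
lca_map <- function(gene_tree, species_tree, gene_to_species) {
  if (is.data.frame(gene_to_species)) {
    stopifnot(all(c("gene_id", "species_id") %in% names(gene_to_species)))
    gene_to_species <- stats::setNames(gene_to_species$species_id,
                                       gene_to_species$gene_id)
  }
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree))
    stop("both trees must be rooted", call. = FALSE)
  if (!ape::is.binary(gene_tree))
    stop("gene tree contains a polytomy; resolve it before reconciliation",
         call. = FALSE)
  if (!ape::is.binary(species_tree))
    stop("species tree contains a polytomy", call. = FALSE)
  genes <- gene_tree$tip.label
  unmapped <- setdiff(genes, names(gene_to_species))
  if (length(unmapped))
    stop("gene(s) without species assignment: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  sp <- gene_to_species[genes]
  missing_sp <- setdiff(unique(sp), species_tree$tip.label)
  if (length(missing_sp))
    stop("species absent from species tree: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)

  sp_parent <- phylo_parents(species_tree)
  sp_depth <- node_depths(species_tree)
  lca2 <- function(u, v) {
    while (sp_depth[u] > sp_depth[v]) u <- sp_parent[u]
    while (sp_depth[v] > sp_depth[u]) v <- sp_parent[v]
    while (u != v) { u <- sp_parent[u]; v <- sp_parent[v] }
    u
  }

  ntip_g <- ape::Ntip(gene_tree)
  n_nodes <- ntip_g + gene_tree$Nnode
  mapping <- integer(n_nodes)
  mapping[seq_len(ntip_g)] <- match(sp, species_tree$tip.label)
  label <- rep(NA_character_, n_nodes)
  label[seq_len(ntip_g)] <- "leaf"

  po <- ape::reorder.phylo(gene_tree, "postorder")$edge
  children <- split(po[, 2L], po[, 1L])
  # postorder edge list visits every internal node after its children
  for (v in unique(po[, 1L])) {
    ch <- children[[as.character(v)]]
    m <- mapping[ch[1L]]
    for (c2 in ch[-1L]) m <- lca2(m, mapping[c2])
    mapping[v] <- m
    label[v] <- if (any(mapping[ch] == m)) "duplication" else "speciation"
  }

  branch_names <- species_branch_names(species_tree)
  out <- list(gene_tree = gene_tree, species_tree = species_tree,
              gene_to_species = sp, mapping = mapping, label = label,
              branch = branch_names[mapping])
  class(out) <- "reconciled_tree"
  out
}

#' @export
print.reconciled_tree <- function(x, ...) {
  nd <- sum(x$label == "duplication", na.rm = TRUE)
  ns <- sum(x$label == "speciation", na.rm = TRUE)
  cat("Reconciled gene tree: ", ape::Ntip(x$gene_tree), " genes, ",
      nd, " duplication node(s), ", ns, " speciation node(s)\n", sep = "")
  invisible(x)
}

node_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  tips <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    tips[[po[i, 1L]]] <- c(tips[[po[i, 1L]]], tips[[po[i, 2L]]])
  tips
}

#' Emit duplication events and their paralogue pairs
#'
#' For every duplication node of one or more reconciled trees, reports the
#' species-tree branch the duplication is assigned to and the paralogue
#' pairs it created: all cross pairs between the two child clades by
#' default, or a single representative pair (the cross pair with the most
#' qualifying fourfold sites, ties broken lexicographically) when a codon
#' alignment is supplied and `representative = TRUE`.
#'
#' @param recon a `reconciled_tree` or list of them.
#' @param family_ids character vector naming each tree's family (recycled
#'   from list names if NULL).
#' @param representative emit only one pair per duplication node.
#' @param alignments named list of codon alignments by family id; required
#'   when `representative = TRUE`.
#' @return list with `events` (family_id, node_id, branch, n_pairs) and
#'   `pairs` (family_id, node_id, branch, gene_a, gene_b).
#' @export
tag_duplications <- function(recon, family_ids = NULL,
                             representative = FALSE, alignments = NULL) {
  if (inherits(recon, "reconciled_tree")) recon <- list(recon)
  if (is.null(family_ids)) {
    family_ids <- names(recon)
    if (is.null(family_ids))
      family_ids <- paste0("fam", seq_along(recon))
  }
  stopifnot(length(family_ids) == length(recon))
  if (representative && is.null(alignments))
    stop("representative pair selection needs codon alignments",
         call. = FALSE)
  ev_list <- list(); pair_list <- list()
  for (i in seq_along(recon)) {
    r <- recon[[i]]
    fam <- family_ids[i]
    dup_nodes <- which(r$label == "duplication")
    if (!length(dup_nodes)) next
    tips <- node_tips(r$gene_tree)
    kids <- split(r$gene_tree$edge[, 2L], r$gene_tree$edge[, 1L])
    for (v in dup_nodes) {
      ch <- kids[[as.character(v)]]
      left <- r$gene_tree$tip.label[tips[[ch[1L]]]]
      right <- r$gene_tree$tip.label[tips[[ch[2L]]]]
      pr <- expand.grid(gene_a = left, gene_b = right,
                        stringsAsFactors = FALSE)
      swap <- pr$gene_a > pr$gene_b
      tmp <- pr$gene_a[swap]; pr$gene_a[swap] <- pr$gene_b[swap]
      pr$gene_b[swap] <- tmp
      pr <- pr[order(pr$gene_a, pr$gene_b), , drop = FALSE]
      if (representative) {
        aln <- alignments[[fam]]
        if (is.null(aln))
          stop("no alignment for family ", fam, call. = FALSE)
        nsites <- vapply(seq_len(nrow(pr)), function(j) {
          sum(is_fourfold_site(codon_matrix(aln[[pr$gene_a[j]]]),
                               codon_matrix(aln[[pr$gene_b[j]]])))
        }, 0L)
        pr <- pr[order(-nsites, pr$gene_a, pr$gene_b)[1L], , drop = FALSE]
      }
      ev_list[[length(ev_list) + 1L]] <-
        data.frame(family_id = fam, node_id = v, branch = r$branch[v],
                   n_pairs = nrow(pr), stringsAsFactors = FALSE)
      pair_list[[length(pair_list) + 1L]] <-
        data.frame(family_id = fam, node_id = v, branch = r$branch[v],
                   gene_a = pr$gene_a, gene_b = pr$gene_b,
                   stringsAsFactors = FALSE)
    }
  }
  empty_ev <- data.frame(family_id = character(0), node_id = integer(0),
                         branch = character(0), n_pairs = integer(0),
                         stringsAsFactors = FALSE)
  empty_pr <- data.frame(family_id = character(0), node_id = integer(0),
                         branch = character(0), gene_a = character(0),
                         gene_b = character(0), stringsAsFactors = FALSE)
  list(events = if (length(ev_list)) do.call(rbind, ev_list) else empty_ev,
       pairs = if (length(pair_list)) do.call(rbind, pair_list)
               else empty_pr)
}

#' Per-branch duplication counts
#'
#' Counts duplication events per species-tree branch, reporting every
#' branch (zeros included) in the tree's node order so summaries line up
#' across runs.
#'
#' @param events the `events` data.frame from [tag_duplications()].
#' @param species_tree the species tree the events were assigned against.
#' @return data.frame: branch, n_duplications.
#' @export
count_duplications_per_branch <- function(events, species_tree) {
  branches <- species_branch_names(species_tree)
  n <- vapply(branches, function(b) sum(events$branch == b), 0L)
  data.frame(branch = branches, n_duplications = as.integer(n),
             stringsAsFactors = FALSE, row.names = NULL)
}
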