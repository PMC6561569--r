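#' Simulation configuration
#'
#' Describes a ground-truthed scenario: gene families descending through a
#' known time-calibrated species tree, with zero or more whole-genome
#' duplications (WGD) planted on named branches and tandem segmental
#' duplications (SD) arising at a per-branch rate. Each WGD can carry a
#' divergence-onset offset modelling delayed rediploidization: the locus
#' duplicates at the WGD but its copies only begin to diverge `offset`
#' time units later, because they keep recombining while inheritance is
#' tetrasomic. An offset that postdates a later speciation makes the
#' divergence replay independently in each descendant lineage, which is
#' the signature that pushes reconciliation-based branch assignment onto
#' daughter branches.
#'
#' @param species_tree rooted binary `phylo` with branch lengths in time
#'   units.
#' @param n_families number of gene families to simulate.
#' @param wgd_branch character vector of species-tree branch names (see
#'   [species_branch_names()]) carrying a WGD each; NULL for none. Each
#'   WGD sits at the midpoint of its branch.
#' @param retention per-WGD probability that a family retains both copies.
#' @param divergence_onset per-WGD offset (time units) between
#'   duplication and divergence onset; 0 means instant rediploidization.
#' @param tandem_rate probability of a tandem SD per lineage per branch.
#' @param mu substitution rate at third codon positions (per site per
#'   time unit), Jukes-Cantor.
#' @param n_sites fourfold codon sites per gene.
#' @param loss_frac fraction of genes removed from the simulated genomes
#'   (degrades synteny neighbourhoods).
#' @param shuffle_frac fraction of genome genes subjected to a local
#'   position swap (within 3 positions).
#' @param genes_per_scaffold ancestral loci per scaffold.
#' @param seed integer seed; all outputs are deterministic given the
#'   config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(species_tree,
                              n_families = 100L,
                              wgd_branch = NULL,
                              retention = 1,
                              divergence_onset = 0,
                              tandem_rate = 0,
                              mu = 1,
                              n_sites = 300L,
                              loss_frac = 0,
                              shuffle_frac = 0,
                              genes_per_scaffold = 10000L,
                              seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"))
  if (!ape::is.rooted(species_tree) || !ape::is.binary(species_tree))
    stop("species tree must be rooted and binary", call. = FALSE)
  if (is.null(species_tree$edge.length))
    stop("species tree needs branch lengths (time units)", call. = FALSE)
  n_wgd <- length(wgd_branch)
  retention <- rep_len(retention, n_wgd)
  divergence_onset <- rep_len(divergence_onset, n_wgd)
  if (n_wgd && any(retention < 0 | retention > 1))
    stop("retention must lie in [0, 1]", call. = FALSE)
  if ((n_wgd && any(divergence_onset < 0)) || tandem_rate < 0 || mu < 0)
    stop("rates and offsets must be non-negative", call. = FALSE)
  if (loss_frac < 0 || loss_frac >= 1 || shuffle_frac < 0 ||
      shuffle_frac > 1)
    stop("loss_frac must lie in [0, 1) and shuffle_frac in [0, 1]",
         call. = FALSE)
  branch_names <- species_branch_names(species_tree)
  depth <- ape::node.depth.edgelength(species_tree)
  parent <- phylo_parents(species_tree)
  ntip <- ape::Ntip(species_tree)
  if (n_wgd) {
    idx <- match(wgd_branch, branch_names)
    if (anyNA(idx))
      stop("unknown wgd_branch: ",
           paste(wgd_branch[is.na(idx)], collapse = ", "), call. = FALSE)
    if (any(idx == ntip + 1L))
      stop("the root has no branch above it to host a WGD", call. = FALSE)
    tips_of <- node_tips(species_tree)
    for (j in seq_len(n_wgd)) {
      v <- idx[j]
      t_w <- (depth[parent[v]] + depth[v]) / 2
      min_leaf <- min(depth[tips_of[[v]]])
      if (t_w + divergence_onset[j] >= min_leaf)
        stop("divergence onset of the WGD on branch '", wgd_branch[j],
             "' falls beyond the tips of its clade", call. = FALSE)
    }
  }
  cfg <- list(species_tree = species_tree,
              n_families = as.integer(n_families),
              wgd_branch = wgd_branch, retention = retention,
              divergence_onset = divergence_onset,
              tandem_rate = tandem_rate, mu = mu,
              n_sites = as.integer(n_sites),
              loss_frac = loss_frac, shuffle_frac = shuffle_frac,
              genes_per_scaffold = as.integer(genes_per_scaffold),
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate gene families descending through the species tree
#'
#' Every family starts as a single locus at the root and traverses the
#' species tree. On a WGD branch the locus duplicates with the event's
#' retention probability; the copies' gene-tree bifurcation is placed at
#' the divergence-onset time (WGD time + offset), replaying independently
#' in each descendant lineage when the onset postdates a speciation.
#' Tandem SDs strike each lineage on each branch with probability
#' `tandem_rate`, at a uniform time on the branch, and diverge instantly.
#' Gene ids encode family, species, locus copy and tandem index, e.g.
#' `fam0007_spA_c2` or `fam0007_spA_c1t1`.
#'
#' @param config a [simulation_config()].
#' @return list with `gene_trees` (named list of `phylo` with time branch
#'   lengths), `gene_to_species` (data.frame gene_id, species_id),
#'   `families` (data.frame gene_id, family_id, species_id), `gene_meta`
#'   (per-gene copy and tandem annotations), `truth_events` (data.frame
#'   family_id, event_type, event_branch, realized_branch, t_event,
#'   t_divergence; delayed-onset WGDs realize once per descendant lineage)
#'   and `truth_pairs` (one row per paralogue pair created by an event
#'   realization).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_families_impl(config))
}

simulate_families_impl <- function(config) {
  st <- config$species_tree
  depth <- ape::node.depth.edgelength(st)
  parent <- phylo_parents(st)
  branch_names <- species_branch_names(st)
  ntip <- ape::Ntip(st)
  kids <- split(st$edge[, 2L], st$edge[, 1L])
  root <- ntip + 1L
  n_wgd <- length(config$wgd_branch)
  wgd_node <- if (n_wgd) match(config$wgd_branch, branch_names) else integer(0)
  wgd_time <- if (n_wgd) (depth[parent[wgd_node]] + depth[wgd_node]) / 2
              else numeric(0)
  no_events <- data.frame(time = numeric(0), type = character(0),
                          event_branch = character(0), t_event = numeric(0),
                          wgd_idx = integer(0), stringsAsFactors = FALSE)

  gene_trees <- vector("list", config$n_families)
  fam_ids <- sprintf("fam%04d", seq_len(config$n_families))
  names(gene_trees) <- fam_ids
  leaf_acc <- vector("list", config$n_families)
  event_acc <- list()
  pair_acc <- list()

  for (f in seq_len(config$n_families)) {
    fam <- fam_ids[f]
    retained <- if (n_wgd) stats::runif(n_wgd) < config$retention
                else logical(0)
    tandem_counter <- 0L
    leaves <- list()
    events <- list()
    pairs <- list()

    new_leaf <- function(species_node, copy, tidx) {
      sp <- st$tip.label[species_node]
      id <- sprintf("%s_%s_c%d%s", fam, sp, copy,
                    if (tidx > 0L) sprintf("t%d", tidx) else "")
      leaves[[length(leaves) + 1L]] <<-
        data.frame(gene_id = id, family_id = fam, species_id = sp,
                   copy = copy, tandem_idx = tidx, stringsAsFactors = FALSE)
      id
    }

    # One lineage on the branch above node v, entering at time t_enter with
    # outstanding events `pending`. `check` is TRUE when the lineage is new
    # on this branch (fresh descent or newborn paralogue), in which case it
    # is exposed to this branch's WGD and draws its tandem-SD Bernoulli;
    # the continuation of a lineage after an in-branch split must not be
    # re-exposed, its events already sit in `pending`.
    descend <- function(v, t_enter, pending, copy, tidx, check = TRUE) {
      t_bot <- depth[v]
      if (check) {
        for (j in seq_len(n_wgd)) {
          if (wgd_node[j] == v && retained[j] && t_enter < wgd_time[j]) {
            pending <- rbind(pending, data.frame(
              time = wgd_time[j] + config$divergence_onset[j],
              type = "WGD", event_branch = config$wgd_branch[j],
              t_event = wgd_time[j], wgd_idx = j,
              stringsAsFactors = FALSE))
          }
        }
        if (config$tandem_rate > 0 &&
            stats::runif(1) < config$tandem_rate) {
          t_t <- stats::runif(1, t_enter, t_bot)
          pending <- rbind(pending, data.frame(
            time = t_t, type = "SD", event_branch = branch_names[v],
            t_event = t_t, wgd_idx = NA_integer_,
            stringsAsFactors = FALSE))
        }
      }
      due <- pending[pending$time <= t_bot & pending$time > t_enter, ,
                     drop = FALSE]
      future <- pending[pending$time > t_bot, , drop = FALSE]
      if (nrow(due)) {
        due <- due[order(due$time), , drop = FALSE]
        e <- due[1L, ]
        rest <- rbind(due[-1L, , drop = FALSE], future)
        if (e$type == "SD") {
          tandem_counter <<- tandem_counter + 1L
          new_copy <- copy; new_tidx <- tandem_counter
        } else {
          # event-deterministic copy label: each WGD contributes one bit,
          # so copy k means the same event combination in every family and
          # WGD copies of all families co-locate on the same scaffold
          new_copy <- copy + 2L^(e$wgd_idx - 1L); new_tidx <- tidx
        }
        left <- descend(v, e$time, rest, copy, tidx, check = FALSE)
        right <- descend(v, e$time, no_events, new_copy, new_tidx,
                         check = TRUE)
        events[[length(events) + 1L]] <<- data.frame(
          family_id = fam, event_type = e$type,
          event_branch = e$event_branch,
          realized_branch = branch_names[v],
          t_event = e$t_event, t_divergence = e$time,
          stringsAsFactors = FALSE)
        cross <- expand.grid(gene_a = left$leaves, gene_b = right$leaves,
                             stringsAsFactors = FALSE)
        swap <- cross$gene_a > cross$gene_b
        tmp <- cross$gene_a[swap]
        cross$gene_a[swap] <- cross$gene_b[swap]
        cross$gene_b[swap] <- tmp
        pairs[[length(pairs) + 1L]] <<- cbind(
          data.frame(family_id = rep(fam, nrow(cross)),
                     stringsAsFactors = FALSE),
          cross,
          data.frame(event_type = rep(e$type, nrow(cross)),
                     event_branch = rep(e$event_branch, nrow(cross)),
                     realized_branch = rep(branch_names[v], nrow(cross)),
                     t_divergence = rep(e$time, nrow(cross)),
                     stringsAsFactors = FALSE))
        nwk <- sprintf("(%s:%.10g,%s:%.10g)",
                       left$nwk, left$top - e$time,
                       right$nwk, right$top - e$time)
        return(list(nwk = nwk, top = e$time,
                    leaves = c(left$leaves, right$leaves)))
      }
      if (v <= ntip) {
        id <- new_leaf(v, copy, tidx)
        return(list(nwk = id, top = t_bot, leaves = id))
      }
      ch <- kids[[as.character(v)]]
      sub <- lapply(ch, function(c2)
        descend(c2, t_bot, future, copy, tidx, check = TRUE))
      nwk <- sprintf("(%s:%.10g,%s:%.10g)",
                     sub[[1L]]$nwk, sub[[1L]]$top - t_bot,
                     sub[[2L]]$nwk, sub[[2L]]$top - t_bot)
      list(nwk = nwk, top = t_bot,
           leaves = unlist(lapply(sub, `[[`, "leaves")))
    }

    ch <- kids[[as.character(root)]]
    sub <- lapply(ch, function(c2)
      descend(c2, 0, no_events, 1L, 0L, check = TRUE))
    nwk <- sprintf("(%s:%.10g,%s:%.10g);",
                   sub[[1L]]$nwk, sub[[1L]]$top,
                   sub[[2L]]$nwk, sub[[2L]]$top)
    gene_trees[[f]] <- ape::read.tree(text = nwk)
    leaf_acc[[f]] <- do.call(rbind, leaves)
    if (length(events)) event_acc[[length(event_acc) + 1L]] <-
      do.call(rbind, events)
    if (length(pairs)) pair_acc[[length(pair_acc) + 1L]] <-
      do.call(rbind, pairs)
  }

  leaf_df <- do.call(rbind, leaf_acc)
  rownames(leaf_df) <- NULL
  empty_ev <- data.frame(family_id = character(0), event_type = character(0),
                         event_branch = character(0),
                         realized_branch = character(0),
                         t_event = numeric(0), t_divergence = numeric(0),
                         stringsAsFactors = FALSE)
  empty_pr <- data.frame(family_id = character(0), gene_a = character(0),
                         gene_b = character(0), event_type = character(0),
                         event_branch = character(0),
                         realized_branch = character(0),
                         t_divergence = numeric(0), stringsAsFactors = FALSE)
  truth_events <- if (length(event_acc)) do.call(rbind, event_acc)
                  else empty_ev
  truth_pairs <- if (length(pair_acc)) do.call(rbind, pair_acc)
                 else empty_pr
  rownames(truth_events) <- rownames(truth_pairs) <- NULL
  list(gene_trees = gene_trees,
       gene_to_species = leaf_df[c("gene_id", "species_id")],
       families = leaf_df[c("gene_id", "family_id", "species_id")],
       gene_meta = leaf_df,
       truth_events = truth_events,
       truth_pairs = truth_pairs)
}

#' Evolve fourfold-degenerate codon sites along a gene tree
#'
#' Each of `n_sites` codons draws its first two positions from the eight
#' fourfold-degenerate codon families and holds them fixed; the third
#' position evolves along the tree under Jukes-Cantor with rate `mu`, so
#' every substitution is synonymous and the expected raw 4dTv between two
#' leaves separated by total path time T is (1 - exp(-4 mu T / 3)) / 2,
#' giving an expected corrected 4dTv of 2 mu T / 3.
#'
#' @param gene_tree `phylo` with branch lengths in time units.
#' @param mu substitution rate per site per time unit.
#' @param n_sites number of fourfold codon sites.
#' @param seed integer seed.
#' @return a `codon_alignment`: named character vector of in-frame,
#'   gap-free codon rows (one per leaf).
#' @export
evolve_fourfold_sites <- function(gene_tree, mu, n_sites, seed = 1L) {
  stopifnot(inherits(gene_tree, "phylo"),
            !is.null(gene_tree$edge.length))
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    prefixes <- sample(FOURFOLD_PREFIXES, n_sites, replace = TRUE)
    ntip <- ape::Ntip(gene_tree)
    n_nodes <- ntip + gene_tree$Nnode
    third <- vector("list", n_nodes)
    root <- ntip + 1L
    third[[root]] <- sample(bases, n_sites, replace = TRUE)
    pre <- ape::reorder.phylo(gene_tree, "cladewise")
    for (i in seq_len(nrow(pre$edge))) {
      p <- pre$edge[i, 1L]; ch <- pre$edge[i, 2L]
      t <- pre$edge.length[i]
      p_any <- 0.75 * (1 - exp(-4 * mu * t / 3))
      s <- third[[p]]
      hit <- stats::runif(n_sites) < p_any
      if (any(hit)) {
        # replacement uniform among the three other bases
        s[hit] <- vapply(s[hit],
                         function(b) sample(setdiff(bases, b), 1L), "")
      }
      third[[ch]] <- s
    }
    out <- vapply(seq_len(ntip), function(i)
      paste0(prefixes, third[[i]], collapse = ""), "")
    names(out) <- gene_tree$tip.label
    class(out) <- "codon_alignment"
    out
  })
}

#' Simulate genome gene orders with planted synteny structure
#'
#' For each extant species, families are laid out in a fixed ancestral
#' order. Locus copy k of each family goes to scaffold(s) `scf*_ck` in
#' that ancestral order, so a WGD pair sits on different scaffolds
#' surrounded by shared neighbour families (truth SOME_SYNTENY), while
#' tandem-SD copies are inserted adjacent to their source gene on its own
#' scaffold (truth CLOSE). The genome is then degraded: each gene is
#' removed with probability `loss_frac` and a `shuffle_frac` fraction of
#' the survivors undergo a local position swap. Truth labels account for
#' degradation: a pair with a lost member, or with fewer than 2 surviving
#' annotated neighbour families around either member, becomes NO_INFO.
#'
#' @param config a [simulation_config()].
#' @param fam_sim output of [simulate_families()] under the same config.
#' @return list with `positions` (data.frame gene_id, genome_id,
#'   scaffold_id, gene_index), `genomes` (named list of [gene_order()]
#'   objects) and `truth_synteny` (within-species truth pairs with a
#'   `truth_label` column).
#' @export
simulate_genomes <- function(config, fam_sim) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed + 1L, simulate_genomes_impl(config, fam_sim))
}

simulate_genomes_impl <- function(config, fam_sim) {
  meta <- fam_sim$gene_meta
  fams <- sort(unique(meta$family_id))
  fam_pos <- stats::setNames(seq_along(fams), fams)
  gps <- config$genes_per_scaffold
  pos_list <- list()
  species <- sort(unique(meta$species_id))
  for (sp in species) {
    m <- meta[meta$species_id == sp, , drop = FALSE]
    for (copy in sort(unique(m$copy))) {
      mc <- m[m$copy == copy, , drop = FALSE]
      ord <- order(fam_pos[mc$family_id], mc$tandem_idx)
      mc <- mc[ord, , drop = FALSE]
      chunk <- (unname(fam_pos[mc$family_id]) - 1L) %/% gps
      scafs <- sprintf("scf%d_c%d", chunk + 1L, copy)
      for (sc in unique(scafs)) {
        g <- mc$gene_id[scafs == sc]
        pos_list[[length(pos_list) + 1L]] <-
          data.frame(gene_id = g, genome_id = sp, scaffold_id = sc,
                     gene_index = seq_along(g) - 1L,
                     stringsAsFactors = FALSE)
      }
    }
  }
  pos <- do.call(rbind, pos_list)

  if (config$loss_frac > 0)
    pos <- pos[stats::runif(nrow(pos)) >= config$loss_frac, , drop = FALSE]
  pos_list <- split(pos, paste(pos$genome_id, pos$scaffold_id))
  pos_list <- lapply(pos_list, function(d) {
    d <- d[order(d$gene_index), , drop = FALSE]
    n <- nrow(d)
    d$gene_index <- seq_len(n) - 1L
    n_shuffle <- round(config$shuffle_frac * n)
    if (n_shuffle > 0L && n > 1L) {
      who <- sample(n, n_shuffle)
      for (i in who) {
        j <- i + sample(c(-3:-1, 1:3), 1L)
        if (j >= 1L && j <= n) {
          tmp <- d$gene_id[i]
          d$gene_id[i] <- d$gene_id[j]
          d$gene_id[j] <- tmp
        }
      }
    }
    d
  })
  pos <- do.call(rbind, pos_list)
  rownames(pos) <- NULL

  fam_tab <- fam_sim$families
  genomes <- lapply(species, function(sp)
    gene_order(pos[pos$genome_id == sp, , drop = FALSE], fam_tab))
  names(genomes) <- species

  tp <- fam_sim$truth_pairs
  sp_of <- stats::setNames(fam_tab$species_id, fam_tab$gene_id)
  within <- tp[sp_of[tp$gene_a] == sp_of[tp$gene_b], , drop = FALSE]
  if (nrow(within)) {
    within$species_id <- unname(sp_of[within$gene_a])
    win <- pipeline_config()$synteny_window
    copy_of <- stats::setNames(meta$copy, meta$gene_id)
    within$truth_label <- vapply(seq_len(nrow(within)), function(i) {
      g <- genomes[[within$species_id[i]]]
      a <- within$gene_a[i]; b <- within$gene_b[i]
      if (is.na(g$lookup[a]) || is.na(g$lookup[b])) return("NO_INFO")
      if (length(neighborhood_families(g, a, win)) < 2L ||
          length(neighborhood_families(g, b, win)) < 2L) return("NO_INFO")
      # a tandem pair stays CLOSE only while both members share the locus
      # copy; a later WGD moves one member to the mirrored scaffold, where
      # the expected signature is shared neighbours
      if (within$event_type[i] == "SD" && copy_of[a] == copy_of[b])
        "CLOSE" else "SOME_SYNTENY"
    }, "")
  } else {
    within$species_id <- character(0)
    within$truth_label <- character(0)
  }
  rownames(within) <- NULL
  list(positions = pos, genomes = genomes, truth_synteny = within)
}

#' Simulate a complete ground-truthed dataset
#'
#' Runs [simulate_families()], [evolve_fourfold_sites()] per family (with
#' per-family sub-seeds derived from the config seed) and
#' [simulate_genomes()], returning everything the pipeline consumes plus
#' the truth tables.
#'
#' @param config a [simulation_config()].
#' @return list: all fields of [simulate_families()], plus `alignments`
#'   (named list of codon alignments) and the fields of
#'   [simulate_genomes()].
#' @export
simulate_dataset <- function(config) {
  fam_sim <- simulate_families(config)
  aln <- vector("list", length(fam_sim$gene_trees))
  names(aln) <- names(fam_sim$gene_trees)
  for (i in seq_along(aln)) {
    tr <- fam_sim$gene_trees[[i]]
    if (ape::Ntip(tr) < 2L) next
    aln[[i]] <- evolve_fourfold_sites(tr, config$mu, config$n_sites,
                                      seed = (config$seed %% 1000L) * 10000L + i)
  }
  gen <- simulate_genomes(config, fam_sim)
  c(fam_sim, list(alignments = aln), gen)
}
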