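four_taxa <- ape::read.tree(
  text = "(((A:0.6666666667,B:0.6666666667):1.3333333333,C:2):1,D:3);")

test_that("simulation configs validate event placement", {
  expect_error(simulation_config(four_taxa, wgd_branch = "XX"),
               "unknown wgd_branch")
  expect_error(simulation_config(four_taxa, wgd_branch = "N1"),
               "root has no branch")
  expect_error(simulation_config(four_taxa, wgd_branch = "N3",
                                 divergence_onset = 2),
               "beyond the tips")
  expect_error(simulation_config(four_taxa, wgd_branch = "N3",
                                 retention = 1.2), "retention")
  expect_error(simulation_config(ape::read.tree(text = "((A,B),C);"),
                                 n_families = 5L), "branch lengths")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- two_burst_scenario(seed = 19, n_families = 15L,
                            tandem_rate = 0.05, loss_frac = 0.2,
                            shuffle_frac = 0.1)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(lapply(s1$gene_trees, ape::write.tree),
                   lapply(s2$gene_trees, ape::write.tree))
  expect_identical(s1$alignments, s2$alignments)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$truth_pairs, s2$truth_pairs)
  expect_identical(s1$truth_synteny, s2$truth_synteny)
})

test_that("gene counts obey retention bookkeeping", {
  st <- four_taxa
  # full retention of a WGD on N3 doubles the A/B complement only
  cfg1 <- simulation_config(st, n_families = 40L, wgd_branch = "N3",
                            retention = 1, seed = 2)
  sim1 <- simulate_families(cfg1)
  tab <- table(sim1$families$species_id)
  expect_equal(as.integer(tab[c("A", "B")]), c(80L, 80L))
  expect_equal(as.integer(tab[c("C", "D")]), c(40L, 40L))
  expect_equal(nrow(sim1$truth_events), 40L)
  expect_true(all(sim1$truth_events$event_branch == "N3"))

  # zero retention: single-copy families, no duplication nodes anywhere
  cfg0 <- simulation_config(st, n_families = 40L, wgd_branch = "N3",
                            retention = 0, seed = 2)
  sim0 <- simulate_families(cfg0)
  expect_equal(nrow(sim0$truth_events), 0L)
  g2s <- stats::setNames(sim0$families$species_id, sim0$families$gene_id)
  for (tr in sim0$gene_trees) {
    r <- lca_map(tr, st, g2s)
    expect_equal(sum(r$label == "duplication"), 0L)
  }
})

test_that("zero substitution rate yields identical sequences", {
  tr <- ape::read.tree(text = "(x:1,y:1);")
  aln <- evolve_fourfold_sites(tr, mu = 0, n_sites = 100L, seed = 3L)
  expect_equal(aln[["x"]], aln[["y"]])
  d <- four_dtv(aln[["x"]], aln[["y"]])
  expect_equal(d$raw_4dtv, 0)
  expect_equal(d$n_4d_sites, 100L)
})

test_that("deep divergence saturates the raw distance near one half", {
  tr <- ape::read.tree(text = "(x:50,y:50);")
  raws <- vapply(1:30, function(i) {
    aln <- evolve_fourfold_sites(tr, mu = 1, n_sites = 300L, seed = i)
    four_dtv(aln[["x"]], aln[["y"]])$raw_4dtv
  }, 0)
  expect_lt(abs(mean(raws) - 0.5), 0.01)
  statuses <- vapply(1:30, function(i) {
    aln <- evolve_fourfold_sites(tr, mu = 1, n_sites = 300L, seed = i)
    four_dtv(aln[["x"]], aln[["y"]])$status
  }, "")
  expect_gt(mean(statuses == "SATURATED"), 0.3)
})

test_that("instant-onset WGDs reconcile onto the planted branch", {
  cfg <- simulation_config(four_taxa, n_families = 60L, wgd_branch = "N2",
                           retention = 1, divergence_onset = 0, seed = 6)
  sim <- simulate_families(cfg)
  g2s <- stats::setNames(sim$families$species_id, sim$families$gene_id)
  recs <- lapply(sim$gene_trees, lca_map, species_tree = four_taxa,
                 gene_to_species = g2s)
  tg <- tag_duplications(recs, names(sim$gene_trees))
  expect_equal(nrow(tg$events), 60L)
  expect_true(all(tg$events$branch == "N2"))
})

test_that("delayed onset shifts assignment to descendant branches", {
  # constructed three-species check: WGD on the (A,B,C) stem at t = 0.5,
  # onset 1.0 puts divergence at t = 1.5, after the speciation at t = 1
  cfg <- simulation_config(four_taxa, n_families = 20L, wgd_branch = "N2",
                           retention = 1, divergence_onset = 1.0, seed = 6)
  sim <- simulate_families(cfg)
  expect_setequal(unique(sim$truth_events$realized_branch), c("N3", "C"))
  expect_true(all(sim$truth_events$event_branch == "N2"))
  g2s <- stats::setNames(sim$families$species_id, sim$families$gene_id)
  recs <- lapply(sim$gene_trees, lca_map, species_tree = four_taxa,
                 gene_to_species = g2s)
  tg <- tag_duplications(recs, names(sim$gene_trees))
  expect_setequal(unique(tg$events$branch), c("N3", "C"))
  expect_equal(sum(tg$events$branch == "N3"), 20L)
  expect_equal(sum(tg$events$branch == "C"), 20L)
})

test_that("tandem events land on random branches with adjacent copies", {
  cfg <- simulation_config(four_taxa, n_families = 150L,
                           tandem_rate = 0.1, seed = 23)
  sim <- simulate_dataset(cfg)
  ev <- sim$truth_events
  expect_gt(nrow(ev), 10L)
  expect_true(all(ev$event_type == "SD"))
  expect_true(all(ev$event_branch == ev$realized_branch))
  ts <- sim$truth_synteny
  cl <- ts[ts$truth_label == "CLOSE", ]
  expect_gt(nrow(cl), 0L)
  for (i in seq_len(nrow(cl))) {
    g <- sim$genomes[[cl$species_id[i]]]$genes
    ia <- g$gene_index[g$gene_id == cl$gene_a[i]]
    ib <- g$gene_index[g$gene_id == cl$gene_b[i]]
    sa <- g$scaffold_id[g$gene_id == cl$gene_a[i]]
    sb <- g$scaffold_id[g$gene_id == cl$gene_b[i]]
    expect_equal(sa, sb)
    expect_lte(abs(ia - ib), 50L)
  }
})

test_that("single-gene scaffolds produce NO_INFO truth", {
  st <- ape::read.tree(text = "(A:1,B:1);")
  # one family per scaffold: neighbourhoods are empty
  cfg <- simulation_config(st, n_families = 5L, wgd_branch = "A",
                           retention = 1, genes_per_scaffold = 1L,
                           seed = 4)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth_synteny$truth_label == "NO_INFO"))
})
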