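test_that("neighbourhoods truncate at scaffold ends and exclude own family", {
  pos <- data.frame(gene_id = c("q", "g1", "g2"), genome_id = "G",
                    scaffold_id = "s", gene_index = 0:2,
                    stringsAsFactors = FALSE)
  fam <- data.frame(gene_id = c("q", "g1", "g2"),
                    family_id = c("Fq", "F1", "F2"), species_id = "sp")
  g <- gene_order(pos, fam)
  expect_setequal(neighborhood_families(g, "q", 50L), c("F1", "F2"))

  # unannotated neighbours contribute nothing
  fam2 <- fam; fam2$family_id <- c("Fq", "UNASSIGNED", "UNASSIGNED")
  g2 <- gene_order(pos, fam2)
  expect_length(neighborhood_families(g2, "q", 50L), 0L)

  # a neighbour of the query's own family is excluded
  fam3 <- fam; fam3$family_id <- c("Fq", "Fq", "F2")
  g3 <- gene_order(pos, fam3)
  expect_setequal(neighborhood_families(g3, "q", 50L), "F2")

  expect_error(neighborhood_families(g, "nope", 50L), "not located")
})

test_that("best-hit coordinates convert to per-scaffold ordinals", {
  hits <- data.frame(
    gene_id = c("g3", "g1", "g2", "h1", "h2"),
    genome_id = "G",
    scaffold_id = c("s1", "s1", "s1", "s2", "s2"),
    start = c(9000L, 100L, 4000L, 700L, 50L),
    stringsAsFactors = FALSE)
  pos <- positions_from_hits(hits)
  expect_equal(pos$gene_id[pos$scaffold_id == "s1"][order(
    pos$gene_index[pos$scaffold_id == "s1"])], c("g1", "g2", "g3"))
  expect_equal(pos$gene_index[pos$gene_id == "h2"], 0L)
  # output satisfies the position-table invariants directly
  expect_silent(gene_order(pos, data.frame(gene_id = pos$gene_id,
                                           family_id = "F1",
                                           species_id = "sp")))
  expect_error(positions_from_hits(rbind(hits, hits[1L, ])),
               "best hit")
})

test_that("the rule cascade labels pairs with the stated precedence", {
  g <- toy_genome()
  cfg <- pipeline_config()
  # paralogues two positions apart on one scaffold: CLOSE
  expect_equal(classify_pair_in_genome("a3", "a5", g, cfg), "CLOSE")
  # mirrored scaffolds share every family: SOME_SYNTENY
  expect_equal(classify_pair_in_genome("a3", "b3", g, cfg), "SOME_SYNTENY")

  # one shared family only: NO_SYNTENY
  pos <- data.frame(gene_id = c("qa", "x1", "x2", "qb", "y1", "y2"),
                    genome_id = "G",
                    scaffold_id = rep(c("s1", "s2"), each = 3L),
                    gene_index = rep(0:2, 2L), stringsAsFactors = FALSE)
  fam <- data.frame(gene_id = pos$gene_id,
                    family_id = c("FQ", "F1", "F9", "FQ", "F1", "F7"),
                    species_id = "sp")
  g2 <- gene_order(pos, fam)
  expect_equal(classify_pair_in_genome("qa", "qb", g2, cfg), "NO_SYNTENY")

  # an isolated paralogue gives NO_INFO even if the pair is adjacent
  pos3 <- data.frame(gene_id = c("qa", "qb", "z1"), genome_id = "G",
                     scaffold_id = c("s1", "s1", "s2"),
                     gene_index = c(0L, 1L, 0L), stringsAsFactors = FALSE)
  fam3 <- data.frame(gene_id = pos3$gene_id,
                     family_id = c("FQ", "FQ", "F1"), species_id = "sp")
  g3 <- gene_order(pos3, fam3)
  expect_equal(classify_pair_in_genome("qa", "qb", g3, cfg), "NO_INFO")

  # unlocatable gene propagates NO_INFO
  expect_equal(classify_pair_in_genome("a1", "missing", g, cfg), "NO_INFO")
})

test_that("labels are invariant under scaffold reversal and pair swap", {
  set.seed(61)
  n <- 120L
  fams <- sprintf("F%03d", 1:n)
  mk <- function(idx_a, idx_b) {
    pos <- data.frame(
      gene_id = c(paste0("u", 1:n), paste0("v", 1:n)),
      genome_id = "G",
      scaffold_id = rep(c("s1", "s2"), each = n),
      gene_index = c(idx_a, idx_b), stringsAsFactors = FALSE)
    fam <- data.frame(gene_id = pos$gene_id, family_id = rep(fams, 2L),
                      species_id = "sp", stringsAsFactors = FALSE)
    gene_order(pos, fam)
  }
  fwd <- mk(0:(n - 1L), 0:(n - 1L))
  rev_ <- mk((n - 1L):0, 0:(n - 1L))
  cfg <- pipeline_config()
  pairs <- data.frame(a = paste0("u", sample(n, 30L)),
                      b = paste0("v", sample(n, 30L)))
  for (i in seq_len(nrow(pairs))) {
    l1 <- classify_pair_in_genome(pairs$a[i], pairs$b[i], fwd, cfg)
    l2 <- classify_pair_in_genome(pairs$a[i], pairs$b[i], rev_, cfg)
    l3 <- classify_pair_in_genome(pairs$b[i], pairs$a[i], fwd, cfg)
    expect_equal(l1, l2)
    expect_equal(l1, l3)
  }
})

test_that("widening the window never turns SOME_SYNTENY into NO_SYNTENY", {
  set.seed(62)
  sim <- simulate_dataset(two_burst_scenario(seed = 8, n_families = 40L,
                                             loss_frac = 0.3,
                                             shuffle_frac = 0.1))
  ts <- sim$truth_synteny
  narrow <- pipeline_config(synteny_window = 25L)
  wide <- pipeline_config(synteny_window = 50L)
  for (i in seq_len(min(nrow(ts), 200L))) {
    g <- sim$genomes[[ts$species_id[i]]]
    l_narrow <- classify_pair_in_genome(ts$gene_a[i], ts$gene_b[i], g,
                                        narrow)
    l_wide <- classify_pair_in_genome(ts$gene_a[i], ts$gene_b[i], g, wide)
    if (l_narrow == "SOME_SYNTENY")
      expect_true(l_wide != "NO_SYNTENY")
  }
})

test_that("consensus drops NO_INFO, requires unanimity, flags conflicts", {
  expect_equal(consensus_label(c("CLOSE", "CLOSE")), "CLOSE")
  expect_equal(consensus_label(c("SOME_SYNTENY", "NO_INFO")),
               "SOME_SYNTENY")
  expect_equal(consensus_label(c("CLOSE", "SOME_SYNTENY")), "CONFLICTING")
  expect_equal(consensus_label(c("NO_INFO", "NO_INFO")), "NO_INFO")
  expect_equal(consensus_label(character(0)), "NO_INFO")
  expect_error(consensus_label("NEARBY"))

  g <- toy_genome("G1")
  out <- classify_pair_across_genomes("a3", "b3", list(g), pipeline_config())
  expect_equal(out$consensus, "SOME_SYNTENY")
  expect_equal(unname(out$votes), "SOME_SYNTENY")
})

test_that("per-branch percentages use informative pairs as denominator", {
  labels <- data.frame(
    branch = c(rep("X", 4L), "Y"),
    label = c("CLOSE", "SOME_SYNTENY", "SOME_SYNTENY", "NO_INFO",
              "NO_INFO"),
    stringsAsFactors = FALSE)
  s <- synteny_summary(labels)
  x <- s[s$branch == "X", ]
  expect_equal(x$n_informative, 3L)
  expect_equal(x$pct_close, 100 / 3, tolerance = 1e-9)
  expect_equal(x$pct_some_synteny, 200 / 3, tolerance = 1e-9)
  expect_equal(x$n_no_info, 1L)
  y <- s[s$branch == "Y", ]
  expect_true(is.na(y$pct_close))
  expect_equal(y$n_no_info, 1L)
})

test_that("planted synteny labels are recovered perfectly on clean genomes", {
  sim <- simulate_dataset(two_burst_scenario(seed = 12, n_families = 40L,
                                             tandem_rate = 0.05))
  ts <- sim$truth_synteny
  expect_gt(sum(ts$truth_label == "CLOSE"), 0L)
  expect_gt(sum(ts$truth_label == "SOME_SYNTENY"), 100L)
  pred <- mapply(function(a, b, sp)
    classify_pair_in_genome(a, b, sim$genomes[[sp]], pipeline_config()),
    ts$gene_a, ts$gene_b, ts$species_id)
  expect_equal(mean(pred == ts$truth_label), 1)
})
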