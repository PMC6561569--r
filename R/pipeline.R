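translate_codon_row <- function(row) {
  codons <- codon_matrix(row)
  aa <- ifelse(codons == "---", "-",
               ifelse(is.na(Biostrings::GENETIC_CODE[codons]), "X",
                      Biostrings::GENETIC_CODE[codons]))
  paste(aa, collapse = "")
}

stage_file <- function(dir, name) file.path(dir, name)

require_input <- function(dir, name, producer) {
  p <- stage_file(dir, name)
  if (!file.exists(p))
    stop("missing input '", name, "'; run stage '", producer,
         "' first (or place the file in ", dir, ")", call. = FALSE)
  p
}

manifest_add <- function(dir, stage, outputs, config, seed) {
  mf_path <- stage_file(dir, "manifest.json")
  mf <- if (file.exists(mf_path))
    jsonlite::read_json(mf_path, simplifyVector = FALSE) else list()
  rows <- lapply(outputs, function(p) {
    n <- tryCatch(length(readLines(p, warn = FALSE)), error = function(e) NA)
    list(file = basename(p), md5 = unname(tools::md5sum(p)), n_lines = n)
  })
  mf[[stage]] <- list(stage = stage,
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                      version = as.character(utils::packageVersion("wgdtv")),
                      seed = seed,
                      config = unclass(config)[setdiff(names(config),
                                                       "species_tree")],
                      outputs = rows)
  jsonlite::write_json(mf, mf_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mf_path)
}

read_alignment_by_family <- function(fasta_path, families) {
  seqs <- read_fasta(fasta_path)
  fam_of <- stats::setNames(families$family_id, families$gene_id)
  unknown <- setdiff(names(seqs), names(fam_of))
  if (length(unknown))
    stop("sequence id(s) not in family table: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  split(seqs, fam_of[names(seqs)])
}

stage_simulate <- function(dir, config, sim_config) {
  if (is.null(sim_config))
    stop("stage 'simulate' needs a simulation_config", call. = FALSE)
  sim <- simulate_dataset(sim_config)
  write_newick(sim_config$species_tree, stage_file(dir, "species_tree.nwk"))
  trees <- sim$gene_trees
  class(trees) <- "multiPhylo"
  write_newick(trees, stage_file(dir, "gene_trees.nwk"))
  write_tsv(sim$families, stage_file(dir, "families.tsv"))
  write_tsv(sim$gene_to_species, stage_file(dir, "gene_to_species.tsv"))
  write_tsv(sim$positions, stage_file(dir, "positions.tsv"))
  write_tsv(sim$truth_events, stage_file(dir, "truth_events.tsv"))
  write_tsv(sim$truth_pairs, stage_file(dir, "truth_pairs.tsv"))
  write_tsv(sim$truth_synteny, stage_file(dir, "truth_synteny.tsv"))
  aln <- unlist(unname(lapply(sim$alignments, unclass)))
  cds <- gsub("-", "", aln, fixed = TRUE)
  prot <- vapply(aln, translate_codon_row, "", USE.NAMES = FALSE)
  names(prot) <- names(aln)
  write_fasta(aln, stage_file(dir, "codon_alignments_true.fasta"))
  write_fasta(cds, stage_file(dir, "cds.fasta"))
  write_fasta(prot, stage_file(dir, "protein_alignments.fasta"))
  outs <- file.path(dir, c("species_tree.nwk", "gene_trees.nwk",
                           "families.tsv", "gene_to_species.tsv",
                           "positions.tsv", "truth_events.tsv",
                           "truth_pairs.tsv", "truth_synteny.tsv",
                           "codon_alignments_true.fasta", "cds.fasta",
                           "protein_alignments.fasta"))
  manifest_add(dir, "simulate", outs, config, sim_config$seed)
  invisible(sim)
}

stage_prep <- function(dir, config) {
  fam_path <- require_input(dir, "families.tsv", "simulate")
  prot_path <- require_input(dir, "protein_alignments.fasta", "simulate")
  cds_path <- require_input(dir, "cds.fasta", "simulate")
  families <- read_family_table(fam_path)
  prot_by_fam <- read_alignment_by_family(prot_path, families)
  cds <- read_fasta(cds_path)
  out_rows <- list()
  removals <- list()
  for (fam in names(prot_by_fam)) {
    aln <- prot_by_fam[[fam]]
    if (length(aln) < 2L) next
    filt <- filter_family_alignment(aln, cds[intersect(names(aln),
                                                       names(cds))], config)
    if (nrow(filt$removed)) {
      removals[[length(removals) + 1L]] <-
        cbind(data.frame(family_id = fam, stringsAsFactors = FALSE),
              filt$removed)
    }
    if (filt$discarded) next
    out_rows[[length(out_rows) + 1L]] <-
      backtranslate_alignment(filt$alignment, cds)
  }
  codon <- unlist(lapply(out_rows, unclass))
  write_fasta(codon, stage_file(dir, "codon_alignments.fasta"))
  rem <- if (length(removals)) do.call(rbind, removals)
         else data.frame(family_id = character(0), gene_id = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  write_tsv(rem, stage_file(dir, "prep_removals.tsv"))
  manifest_add(dir, "prep",
               file.path(dir, c("codon_alignments.fasta",
                                "prep_removals.tsv")),
               config, config$rng_seed)
  invisible(codon)
}

stage_reconcile <- function(dir, config) {
  st <- read_newick(require_input(dir, "species_tree.nwk", "simulate"))
  gt <- read_newick(require_input(dir, "gene_trees.nwk", "simulate"),
                    multi = TRUE)
  families <- read_family_table(require_input(dir, "families.tsv",
                                              "simulate"))
  g2s <- stats::setNames(families$species_id, families$gene_id)
  fam_of <- stats::setNames(families$family_id, families$gene_id)
  recons <- list()
  fam_ids <- character(0)
  for (tr in gt) {
    fam <- unname(fam_of[tr$tip.label[1L]])
    if (is.na(fam))
      stop("gene '", tr$tip.label[1L], "' missing from family table",
           call. = FALSE)
    if (ape::Ntip(tr) < 2L) next
    recons[[length(recons) + 1L]] <- lca_map(tr, st, g2s)
    fam_ids <- c(fam_ids, fam)
  }
  tagged <- tag_duplications(recons, fam_ids)
  write_tsv(tagged$events, stage_file(dir, "duplication_events.tsv"))
  write_tsv(tagged$pairs, stage_file(dir, "duplication_pairs.tsv"))
  write_tsv(count_duplications_per_branch(tagged$events, st),
            stage_file(dir, "branch_counts.tsv"))
  manifest_add(dir, "reconcile",
               file.path(dir, c("duplication_events.tsv",
                                "duplication_pairs.tsv",
                                "branch_counts.tsv")),
               config, config$rng_seed)
  invisible(tagged)
}

stage_fourdtv <- function(dir, config) {
  families <- read_family_table(require_input(dir, "families.tsv",
                                              "simulate"))
  aln_by_fam <- read_alignment_by_family(
    require_input(dir, "codon_alignments.fasta", "prep"), families)
  pairs <- utils::read.table(require_input(dir, "duplication_pairs.tsv",
                                           "reconcile"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  out <- list()
  for (fam in unique(pairs$family_id)) {
    aln <- aln_by_fam[[fam]]
    pf <- pairs[pairs$family_id == fam, , drop = FALSE]
    if (is.null(aln)) next
    pf <- pf[pf$gene_a %in% names(aln) & pf$gene_b %in% names(aln), ,
             drop = FALSE]
    if (!nrow(pf)) next
    d <- family_pairwise_4dtv(aln, pf[c("gene_a", "gene_b")],
                              min_sites = config$min_4d_sites)
    d <- merge(pf, d, by = c("gene_a", "gene_b"), sort = FALSE)
    out[[length(out) + 1L]] <- d
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(gene_a = character(0), gene_b = character(0),
                         family_id = character(0), node_id = integer(0),
                         branch = character(0), n_4d_sites = integer(0),
                         n_transversions = integer(0),
                         raw_4dtv = numeric(0), corrected_4dtv = numeric(0),
                         status = character(0), stringsAsFactors = FALSE)
  res <- res[order(res$family_id, res$gene_a, res$gene_b), , drop = FALSE]
  write_tsv(res, stage_file(dir, "fourdtv.tsv"))
  manifest_add(dir, "fourdtv", stage_file(dir, "fourdtv.tsv"),
               config, config$rng_seed)
  invisible(res)
}

stage_synteny <- function(dir, config) {
  families <- read_family_table(require_input(dir, "families.tsv",
                                              "simulate"))
  pos <- read_gene_positions(require_input(dir, "positions.tsv",
                                           "simulate"))
  pairs <- utils::read.table(require_input(dir, "duplication_pairs.tsv",
                                           "reconcile"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  genomes <- lapply(split(pos, pos$genome_id), gene_order,
                    families = families)
  labels <- character(nrow(pairs))
  votes_txt <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cl <- classify_pair_across_genomes(pairs$gene_a[i], pairs$gene_b[i],
                                       genomes, config)
    labels[i] <- cl$consensus
    v <- cl$votes[cl$votes != "NO_INFO"]
    votes_txt[i] <- if (length(v))
      paste(names(v), v, sep = ":", collapse = ",") else ""
  }
  out <- cbind(pairs, data.frame(label = labels, votes = votes_txt,
                                 stringsAsFactors = FALSE))
  write_tsv(out, stage_file(dir, "synteny_labels.tsv"))
  write_tsv(synteny_summary(out[c("branch", "label")]),
            stage_file(dir, "synteny_summary.tsv"))
  manifest_add(dir, "synteny",
               file.path(dir, c("synteny_labels.tsv",
                                "synteny_summary.tsv")),
               config, config$rng_seed)
  invisible(out)
}

stage_density <- function(dir, config) {
  d <- utils::read.table(require_input(dir, "fourdtv.tsv", "fourdtv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  vals <- d$corrected_4dtv[d$status == "OK"]
  vals <- vals[is.finite(vals) & vals > 0]
  ks <- config$mixture_k_candidates
  ks <- ks[10L * ks <= length(vals)]
  comp_path <- stage_file(dir, "mixture_components.tsv")
  max_path <- stage_file(dir, "density_maxima.tsv")
  if (!length(ks)) {
    log_msg("density: only ", length(vals),
            " usable distances; skipping mixture fit")
    write_tsv(data.frame(component = integer(0), weight = numeric(0),
                         meanlog = numeric(0), sdlog = numeric(0),
                         mode = numeric(0)), comp_path)
    write_tsv(data.frame(maximum_4dtv = numeric(0)), max_path)
  } else {
    fit <- fit_lognormal_mixture(vals, ks, seed = config$rng_seed)
    write_tsv(data.frame(component = seq_len(fit$k), weight = fit$weight,
                         meanlog = fit$meanlog, sdlog = fit$sdlog,
                         mode = fit$mode), comp_path)
    write_tsv(data.frame(maximum_4dtv = density_local_maxima(fit)),
              max_path)
  }
  h <- histogram_4dtv(d$corrected_4dtv[d$status == "OK"], config)
  write_tsv(h$bins, stage_file(dir, "histogram.tsv"))
  manifest_add(dir, "density",
               file.path(dir, c("mixture_components.tsv",
                                "density_maxima.tsv", "histogram.tsv")),
               config, config$rng_seed)
  invisible(NULL)
}

stage_enrich <- function(dir, config) {
  ann <- read_annotation_table(require_input(
    dir, "annotation.tsv", "(user-provided annotation input)"))
  fg_path <- require_input(dir, "foreground.txt",
                           "(user-provided foreground gene list)")
  bg_path <- require_input(dir, "background.txt",
                           "(user-provided background gene list)")
  fg <- readLines(fg_path, warn = FALSE)
  bg <- readLines(bg_path, warn = FALSE)
  res <- fisher_enrichment(ann, fg[nzchar(fg)], bg[nzchar(bg)])
  write_tsv(res, stage_file(dir, "enrichment.tsv"))
  manifest_add(dir, "enrich", stage_file(dir, "enrichment.tsv"),
               config, config$rng_seed)
  invisible(res)
}

stage_summary <- function(dir, config) {
  st <- read_newick(require_input(dir, "species_tree.nwk", "simulate"))
  events <- utils::read.table(require_input(dir, "duplication_events.tsv",
                                            "reconcile"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  d4 <- utils::read.table(require_input(dir, "fourdtv.tsv", "fourdtv"),
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  syn <- utils::read.table(require_input(dir, "synteny_labels.tsv",
                                         "synteny"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  counts <- count_duplications_per_branch(events, st)
  ok <- d4[d4$status == "OK", , drop = FALSE]
  med <- tapply(ok$corrected_4dtv, ok$branch, stats::median)
  counts$median_corrected_4dtv <- unname(med[counts$branch])
  ssum <- synteny_summary(syn[c("branch", "label")])
  out <- merge(counts, ssum, by = "branch", all.x = TRUE, sort = FALSE)
  write_tsv(out, stage_file(dir, "branch_summary.tsv"))
  manifest_add(dir, "summary", stage_file(dir, "branch_summary.tsv"),
               config, config$rng_seed)
  invisible(out)
}

#' Run one pipeline stage in a working directory
#'
#' Stages communicate through files in `dir` so each stage's outputs can
#' be inspected or consumed independently: `simulate` writes the
#' ground-truthed inputs, `prep` builds filtered codon alignments,
#' `reconcile` tags duplications and assigns branches, `fourdtv` computes
#' pair distances, `synteny` classifies pairs, `density` fits the mixture
#' and histograms, `enrich` runs Fisher/FDR on user-provided annotation
#' files, `summary` joins the per-branch tables and `all` chains
#' everything after `simulate`. Every stage appends an entry (file
#' checksums, row counts, config snapshot, seed) to `manifest.json`.
#'
#' @param stage one of simulate, prep, reconcile, fourdtv, synteny,
#'   density, enrich, summary, all.
#' @param dir working directory (created if needed).
#' @param config a [pipeline_config()].
#' @param sim_config a [simulation_config()]; required by `simulate`.
#' @return invisibly, the stage's main result object.
#' @export
run_stage <- function(stage = c("simulate", "prep", "reconcile", "fourdtv",
                                "synteny", "density", "enrich", "summary",
                                "all"),
                      dir, config = pipeline_config(), sim_config = NULL) {
  stage <- match.arg(stage)
  validate_config(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log_msg("stage '", stage, "' in ", dir)
  switch(stage,
         simulate = stage_simulate(dir, config, sim_config),
         prep = stage_prep(dir, config),
         reconcile = stage_reconcile(dir, config),
         fourdtv = stage_fourdtv(dir, config),
         synteny = stage_synteny(dir, config),
         density = stage_density(dir, config),
         enrich = stage_enrich(dir, config),
         summary = stage_summary(dir, config),
         all = {
           stage_prep(dir, config)
           stage_reconcile(dir, config)
           stage_fourdtv(dir, config)
           stage_synteny(dir, config)
           stage_density(dir, config)
           if (file.exists(stage_file(dir, "annotation.tsv")))
             stage_enrich(dir, config)
           stage_summary(dir, config)
         })
}

#' Simulate a dataset and run the full pipeline on it
#'
#' Convenience wrapper: `simulate` followed by `all`.
#'
#' @inheritParams run_stage
#' @return invisibly, the per-branch summary table.
#' @export
run_pipeline <- function(dir, config = pipeline_config(), sim_config) {
  run_stage("simulate", dir, config, sim_config)
  run_stage("all", dir, config)
  invisible(utils::read.table(stage_file(dir, "branch_summary.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' A two-burst demonstration scenario
#'
#' Four-species time tree of total depth 3 with an old WGD on the basal
#' branch of the (A,B,C) clade and a younger WGD on the (A,B) branch.
#' With third-position rate mu = 0.225 the expected corrected 4dTv
#' between copies is 0.75 for the old event and 0.40 for the young one,
#' giving a bimodal paralogue-age distribution similar in shape to what
#' teleost transcriptomes show for the fish-specific WGD plus a younger
#' lineage-specific burst.
#'
#' @param seed integer seed.
#' @param n_families number of families.
#' @param retention per-event retention, recycled to length 2.
#' @param divergence_onset per-event onset offsets, recycled to length 2.
#' @param ... passed on to [simulation_config()].
#' @return a [simulation_config()].
#' @export
two_burst_scenario <- function(seed = 1L, n_families = 120L,
                               retention = c(0.8, 0.8),
                               divergence_onset = c(0, 0),
                               n_sites = 500L, ...) {
  st <- ape::read.tree(text = paste0(
    "(((A:0.6666666667,B:0.6666666667):1.3333333333,C:2):1,D:3);"))
  simulation_config(st, n_families = n_families,
                    wgd_branch = c("N2", "N3"),
                    retention = rep_len(retention, 2L),
                    divergence_onset = rep_len(divergence_onset, 2L),
                    mu = 0.225, n_sites = n_sites, seed = seed, ...)
}
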