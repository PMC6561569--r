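SYNTENY_LABELS <- c("CLOSE", "SOME_SYNTENY", "NO_SYNTENY", "NO_INFO",
                    "CONFLICTING")

#' Convert tabular best-hit gene locations to order ordinals
#'
#' Takes per-gene best-hit coordinates (e.g. from a tabular BLAST search
#' of representative transcripts against a genome assembly) and converts
#' them to the 0-based gene-order ordinals the synteny classifier uses,
#' by sorting hits along each scaffold by start coordinate. Ties on start
#' are broken by gene id for reproducibility.
#'
#' @param hits data.frame with columns `gene_id`, `genome_id`,
#'   `scaffold_id`, `start` (base-pair coordinate of the best hit); one
#'   row per gene.
#' @return a gene position data.frame (gene_id, genome_id, scaffold_id,
#'   gene_index) suitable for [gene_order()].
#' @export
positions_from_hits <- function(hits) {
  stopifnot(all(c("gene_id", "genome_id", "scaffold_id", "start") %in%
                  names(hits)))
  if (anyDuplicated(hits$gene_id))
    stop("multiple hits per gene; keep only the best hit", call. = FALSE)
  out <- do.call(rbind, lapply(
    split(hits, paste(hits$genome_id, hits$scaffold_id)), function(d) {
      d <- d[order(d$start, d$gene_id), , drop = FALSE]
      d$gene_index <- seq_len(nrow(d)) - 1L
      d
    }))
  rownames(out) <- NULL
  out[c("gene_id", "genome_id", "scaffold_id", "gene_index")]
}

#' Build a genome gene-order object
#'
#' Combines a position table for one genome with the family membership
#' table into a lookup structure used by the synteny classifier. Genes
#' absent from the family table are kept in the gene order (they occupy
#' window positions) but carry no family annotation.
#'
#' @param positions data.frame with columns gene_id, genome_id,
#'   scaffold_id, gene_index (0-based, contiguous per scaffold); one
#'   genome only.
#' @param families data.frame with columns gene_id, family_id, or a named
#'   character vector gene_id -> family_id.
#' @return object of class `genome_order`.
#' @export
gene_order <- function(positions, families) {
  stopifnot(all(c("gene_id", "genome_id", "scaffold_id", "gene_index") %in%
                  names(positions)))
  if (length(unique(positions$genome_id)) > 1L)
    stop("gene_order() takes one genome at a time", call. = FALSE)
  if (anyDuplicated(positions$gene_id))
    stop("a gene appears more than once in the genome", call. = FALSE)
  validate_gene_positions(positions)
  if (is.data.frame(families))
    families <- stats::setNames(families$family_id, families$gene_id)
  fam <- unname(families[positions$gene_id])
  fam[is.na(fam) | fam == "UNASSIGNED"] <- NA_character_
  ord <- order(positions$scaffold_id, positions$gene_index)
  df <- data.frame(gene_id = positions$gene_id[ord],
                   scaffold_id = positions$scaffold_id[ord],
                   gene_index = positions$gene_index[ord],
                   family_id = fam[ord], stringsAsFactors = FALSE)
  out <- list(genome_id = positions$genome_id[1L],
              genes = df,
              by_scaffold = split(df, df$scaffold_id),
              lookup = stats::setNames(seq_len(nrow(df)), df$gene_id))
  class(out) <- "genome_order"
  out
}

#' @export
print.genome_order <- function(x, ...) {
  cat("Genome '", x$genome_id, "': ", nrow(x$genes), " genes on ",
      length(x$by_scaffold), " scaffold(s)\n", sep = "")
  invisible(x)
}

locate_gene <- function(genome, gene) {
  i <- genome$lookup[gene]
  if (is.na(i)) return(NULL)
  genome$genes[i, , drop = FALSE]
}

#' Families found near a gene
#'
#' Returns the distinct family ids annotated on the up-to-`window` genes
#' on each side of the query gene along its scaffold, truncated at
#' scaffold ends. The query gene's own family and unannotated genes are
#' excluded: synteny evidence must come from other gene families.
#'
#' @param genome a [gene_order()] object.
#' @param gene gene id; must be located in the genome.
#' @param window genes examined on each side.
#' @return character vector of distinct family ids (possibly empty).
#' @export
neighborhood_families <- function(genome, gene, window = 50L) {
  loc <- locate_gene(genome, gene)
  if (is.null(loc))
    stop("gene '", gene, "' is not located in genome '", genome$genome_id,
         "'", call. = FALSE)
  scaf <- genome$by_scaffold[[loc$scaffold_id]]
  idx <- loc$gene_index
  nb <- scaf[abs(scaf$gene_index - idx) <= window &
               scaf$gene_index != idx, , drop = FALSE]
  fams <- nb$family_id[!is.na(nb$family_id)]
  own <- loc$family_id
  if (!is.na(own)) fams <- fams[fams != own]
  unique(fams)
}

#' Classify one paralogue pair within one genome
#'
#' Applies the rule cascade, in order of precedence:
#' \enumerate{
#'   \item NO_INFO when either gene cannot be located, or fewer than 2
#'     gene families are identified among the neighbours of either gene;
#'   \item CLOSE when the genes sit on the same scaffold within `window`
#'     gene positions of each other (the tandem-duplication signature);
#'   \item SOME_SYNTENY when the two neighbourhoods share at least
#'     `min_shared_families` gene families (duplicated-block signature,
#'     collinear order not required);
#'   \item NO_SYNTENY otherwise.
#' }
#' Shared families are counted with set semantics, pooling both sides of
#' each gene's neighbourhood.
#'
#' @param gene_a,gene_b the paralogue pair.
#' @param genome a [gene_order()] object.
#' @param config a [pipeline_config()] (window and sharing threshold).
#' @return a single synteny label string.
#' @export
classify_pair_in_genome <- function(gene_a, gene_b, genome,
                                    config = pipeline_config()) {
  validate_config(config)
  loc_a <- locate_gene(genome, gene_a)
  loc_b <- locate_gene(genome, gene_b)
  if (is.null(loc_a) || is.null(loc_b)) return("NO_INFO")
  w <- config$synteny_window
  fam_a <- neighborhood_families(genome, gene_a, w)
  fam_b <- neighborhood_families(genome, gene_b, w)
  if (length(fam_a) < config$min_shared_families ||
      length(fam_b) < config$min_shared_families) return("NO_INFO")
  if (loc_a$scaffold_id == loc_b$scaffold_id &&
      abs(loc_a$gene_index - loc_b$gene_index) <= w) return("CLOSE")
  if (length(intersect(fam_a, fam_b)) >= config$min_shared_families)
    return("SOME_SYNTENY")
  "NO_SYNTENY"
}

#' Combine per-genome synteny votes into a consensus label
#'
#' Uninformative (NO_INFO) votes are dropped; unanimity among the
#' remaining votes gives that label, disagreement gives CONFLICTING, and
#' no informative vote at all gives NO_INFO.
#'
#' @param votes character vector of synteny labels.
#' @return consensus label.
#' @export
consensus_label <- function(votes) {
  stopifnot(all(votes %in% SYNTENY_LABELS))
  votes <- votes[votes != "NO_INFO"]
  if (!length(votes)) return("NO_INFO")
  u <- unique(votes)
  if (length(u) == 1L) u else "CONFLICTING"
}

#' Classify a paralogue pair across several genomes
#'
#' Classifies the pair in every genome where it can be assessed and
#' combines the votes with [consensus_label()]. Duplication events shared
#' by several species can thus be labelled from all the affected genomes,
#' with disagreement surfacing as CONFLICTING rather than being averaged
#' away.
#'
#' @param gene_a,gene_b the paralogue pair.
#' @param genomes list of [gene_order()] objects.
#' @param config a [pipeline_config()].
#' @return list with `consensus` (label) and `votes` (named character
#'   vector of per-genome labels).
#' @export
classify_pair_across_genomes <- function(gene_a, gene_b, genomes,
                                         config = pipeline_config()) {
  votes <- vapply(genomes, function(g)
    classify_pair_in_genome(gene_a, gene_b, g, config), "")
  names(votes) <- vapply(genomes, function(g) g$genome_id, "")
  list(consensus = consensus_label(votes), votes = votes)
}

#' Per-branch synteny percentages
#'
#' Summarises consensus labels per species-tree branch. Percentages of
#' CLOSE / SOME_SYNTENY / NO_SYNTENY are computed over the informative
#' pairs only (NO_INFO pairs carry no positional evidence and CONFLICTING
#' pairs no single label); both are reported as separate counts.
#'
#' @param labels data.frame with columns `branch` and `label` (consensus
#'   synteny labels, one row per paralogue pair).
#' @return data.frame: branch, n_informative, pct_close,
#'   pct_some_synteny, pct_no_synteny, n_no_info, n_conflicting. Branches
#'   whose pairs are all uninformative get NA percentages.
#' @export
synteny_summary <- function(labels) {
  stopifnot(all(c("branch", "label") %in% names(labels)),
            all(labels$label %in% SYNTENY_LABELS))
  out <- do.call(rbind, lapply(split(labels, labels$branch), function(d) {
    inf <- d$label[d$label %in% c("CLOSE", "SOME_SYNTENY", "NO_SYNTENY")]
    n <- length(inf)
    pct <- function(l) if (n > 0L) 100 * sum(inf == l) / n else NA_real_
    data.frame(branch = d$branch[1L], n_informative = n,
               pct_close = pct("CLOSE"),
               pct_some_synteny = pct("SOME_SYNTENY"),
               pct_no_synteny = pct("NO_SYNTENY"),
               n_no_info = sum(d$label == "NO_INFO"),
               n_conflicting = sum(d$label == "CONFLICTING"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
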