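#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Duplicate ids and empty files are structured errors, since downstream
#' tables key on the id.
#'
#' @param path FASTA file.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file is empty: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, max(1L, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a rooted tree (or forest) from a Newick file
#'
#' Wraps [ape::read.tree] with the validation the pipeline relies on:
#' unique leaf labels and balanced parentheses. Polytomies are preserved
#' and flagged via the `binary` attribute so callers that require binary
#' trees can refuse them with a clear message.
#'
#' @param path Newick file; may contain one tree or several (one per line).
#' @param multi if TRUE always return a list of trees (class `multiPhylo`).
#' @return an [ape::read.tree] `phylo` object (or `multiPhylo`).
#' @export
read_newick <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("Newick file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick file: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("cannot parse Newick '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("no tree found in: ", path, call. = FALSE)
  check_one <- function(t) {
    dup <- t$tip.label[duplicated(t$tip.label)]
    if (length(dup))
      stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    attr(t, "binary") <- ape::is.binary(t)
    t
  }
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, check_one)
    class(out) <- "multiPhylo"
    return(out)
  }
  tr <- check_one(tr)
  if (multi) {
    out <- list(tr)
    class(out) <- "multiPhylo"
    return(out)
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` or `multiPhylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " table not found: ", path,
                               call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) warning(what, " table is empty: ", path, call. = FALSE)
  log_msg("read ", nrow(df), " rows from ", path)
  df
}

#' Read the gene-family membership table
#'
#' Tab-separated with header columns `gene_id`, `family_id`, `species_id`.
#' Gene ids must be unique.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_family_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "family_id", "species_id"),
                         "family")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup))
    stop("duplicate gene_id(s) in family table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  df[c("gene_id", "family_id", "species_id")]
}

#' Read a gene-order position table
#'
#' Tab-separated with header columns `gene_id`, `genome_id`, `scaffold_id`,
#' `gene_index`. Positions are 0-based ordinals along each scaffold and must
#' be contiguous from 0: synteny windows count neighbouring genes, so a gap
#' in the ordinals would silently widen windows.
#'
#' @param path TSV file.
#' @return data.frame with the four columns.
#' @export
read_gene_positions <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "genome_id", "scaffold_id",
                                 "gene_index"), "position")
  df$gene_index <- as.integer(df$gene_index)
  validate_gene_positions(df)
  df[c("gene_id", "genome_id", "scaffold_id", "gene_index")]
}

validate_gene_positions <- function(df) {
  key <- paste(df$genome_id, df$scaffold_id, df$gene_index)
  if (anyDuplicated(key))
    stop("duplicate (genome, scaffold, index) in position table: ",
         key[duplicated(key)][1], call. = FALSE)
  by_scaf <- split(df$gene_index, paste(df$genome_id, df$scaffold_id,
                                        sep = "/"))
  for (nm in names(by_scaf)) {
    idx <- sort(by_scaf[[nm]])
    if (!identical(idx, seq(0L, length(idx) - 1L)))
      stop("gene_index not contiguous from 0 on scaffold ", nm,
           call. = FALSE)
  }
  invisible(df)
}

#' Read a gene-to-term annotation table
#'
#' Tab-separated with header columns `gene_id`, `term_id`; one row per
#' gene/term assignment (genes may carry several terms).
#'
#' @param path TSV file.
#' @return data.frame with columns gene_id, term_id.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("gene_id", "term_id"), "annotation")
  unique(df[c("gene_id", "term_id")])
}

#' Write a data.frame as a TSV with header
#'
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
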