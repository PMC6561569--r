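#' DUST low-complexity score of a nucleotide sequence
#'
#' Triplet-based low-complexity score in the style of the BLAST DUST
#' module. For a window holding k overlapping triplets with counts c_t per
#' triplet type, the window score is sum(c_t * (c_t - 1) / 2) / (k - 1);
#' the sequence score is the maximum over sliding windows (step = half the
#' window, with a final window flushed to the sequence end). A homopolymer
#' window of 64 bases scores 31; a window of all-distinct triplets scores 0.
#' Sequences shorter than 4 bases score 0 by convention.
#'
#' @param sequence nucleotide string.
#' @param window window size in bases (default 64).
#' @return numeric score.
#' @examples
#' dust_score(strrep("A", 64))   # 31
#' dust_score("ACGTACGTACGT")    # periodic, high relative to length
#' @export
dust_score <- function(sequence, window = 64L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, window >= 4L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 4L) return(0)
  window <- as.integer(window)
  if (n <= window) {
    starts <- 1L
  } else {
    starts <- seq(1L, n - window + 1L, by = max(1L, window %/% 2L))
    if (starts[length(starts)] != n - window + 1L)
      starts <- c(starts, n - window + 1L)
  }
  score <- 0
  for (s in starts) {
    w <- substr(sequence, s, min(s + window - 1L, n))
    k <- nchar(w) - 2L
    if (k < 2L) next
    tri <- substring(w, 1:k, 3:(k + 2L))
    cnt <- table(tri)
    score <- max(score, sum(cnt * (cnt - 1) / 2) / (k - 1L))
  }
  score
}

#' Filter assembled transcripts on length, expression and complexity
#'
#' Keeps transcripts that are at least `min_transcript_len` bases long
#' (inclusive), expressed at or above `min_tpm` (inclusive), and whose DUST
#' score does not exceed `dust_threshold` (a score strictly above the
#' threshold rejects). Each rejected transcript is tagged with the first
#' failing rule, checked in the order length, expression, complexity.
#'
#' @param records data.frame with columns `id`, `sequence`, `tpm`.
#' @param config a [pipeline_config()].
#' @return list with `retained` (the surviving rows, plus a `length`
#'   column) and `rejected` (rows plus a `reason` column).
#' @export
filter_transcripts <- function(records, config = pipeline_config()) {
  stopifnot(all(c("id", "sequence", "tpm") %in% names(records)))
  validate_config(config)
  records$length <- nchar(records$sequence)
  if (nrow(records) == 0L)
    return(list(retained = records,
                rejected = cbind(records, reason = character(0))))
  dust <- vapply(records$sequence, dust_score, 0,
                 window = config$dust_window, USE.NAMES = FALSE)
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$length < config$min_transcript_len] <- "length"
  reason[is.na(reason) & records$tpm < config$min_tpm] <- "expression"
  reason[is.na(reason) & dust > config$dust_threshold] <- "complexity"
  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Cluster transcripts into genes by transitive overlap
#'
#' Two transcripts are isoforms of the same gene when they share at least
#' `isoform_min_overlap` aligned bases at `isoform_min_identity` identity
#' or better; genes are the transitive closure of that relation. Each
#' gene's representative is its most expressed transcript (highest TPM,
#' ties broken by the lexicographically smallest id) so that downstream
#' analyses see one sequence per gene.
#'
#' @param matches data.frame with columns `id_a`, `id_b`, `overlap`,
#'   `identity` from any upstream pairwise aligner.
#' @param transcripts data.frame with columns `id`, `tpm` covering every id
#'   in `matches`.
#' @param config a [pipeline_config()].
#' @return data.frame with columns `transcript_id`, `gene_id`,
#'   `is_representative`; `gene_id` is the representative's id.
#' @export
cluster_isoforms <- function(matches, transcripts,
                             config = pipeline_config()) {
  stopifnot(all(c("id", "tpm") %in% names(transcripts)))
  validate_config(config)
  ids <- transcripts$id
  if (anyDuplicated(ids)) stop("duplicate transcript ids", call. = FALSE)
  if (nrow(matches) > 0L) {
    stopifnot(all(c("id_a", "id_b", "overlap", "identity") %in%
                    names(matches)))
    unknown <- setdiff(unique(c(matches$id_a, matches$id_b)), ids)
    if (length(unknown))
      stop("match list references unknown transcript id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  # union-find over transcript ids
  parent <- seq_along(ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(matches) > 0L) {
    ok <- matches$overlap >= config$isoform_min_overlap &
      matches$identity >= config$isoform_min_identity
    ia <- match(matches$id_a[ok], ids)
    ib <- match(matches$id_b[ok], ids)
    for (j in seq_along(ia)) {
      ra <- find(ia[j]); rb <- find(ib[j])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(ids), find, 0L)
  out <- do.call(rbind, lapply(split(seq_along(ids), root), function(members) {
    tpm <- transcripts$tpm[members]
    mids <- ids[members]
    rep_id <- mids[order(-tpm, mids)][1L]
    data.frame(transcript_id = mids, gene_id = rep_id,
               is_representative = mids == rep_id,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

split_rows <- function(alignment) {
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  w <- unique(nchar(alignment))
  if (length(w) != 1L)
    stop("alignment rows have unequal lengths", call. = FALSE)
  do.call(rbind, strsplit(alignment, "", fixed = TRUE))
}

#' Filter rows of a family protein alignment
#'
#' Drops alignment rows whose ungapped protein is strictly longer than
#' `max_protein_len` residues, whose CDS has a DUST score strictly above
#' `dust_threshold`, or whose gap fraction is strictly above
#' `max_gap_frac`; columns left with only gaps are then removed. A family
#' reduced below 2 rows is discarded (alignment set to NULL), since a
#' single sequence supports no paralogue comparison.
#'
#' @param alignment named character vector of equal-length aligned protein
#'   rows ('-' for gaps); names are gene ids.
#' @param cds named character vector of unaligned CDS sequences for the
#'   same gene ids (used for the complexity filter); may be NULL to skip
#'   the complexity rule.
#' @param config a [pipeline_config()].
#' @return list with `alignment` (filtered rows or NULL if discarded),
#'   `removed` (data.frame gene_id, reason) and `discarded` (logical).
#' @export
filter_family_alignment <- function(alignment, cds = NULL,
                                    config = pipeline_config()) {
  validate_config(config)
  mat <- split_rows(alignment)
  width <- ncol(mat)
  gaps <- rowSums(mat == "-")
  ungapped <- width - gaps
  reason <- rep(NA_character_, length(alignment))
  reason[ungapped > config$max_protein_len] <- "protein_length"
  if (!is.null(cds)) {
    has_cds <- names(alignment) %in% names(cds)
    d <- rep(0, length(alignment))
    d[has_cds] <- vapply(cds[names(alignment)[has_cds]], dust_score, 0,
                         window = config$dust_window, USE.NAMES = FALSE)
    reason[is.na(reason) & d > config$dust_threshold] <- "complexity"
  }
  reason[is.na(reason) & gaps / width > config$max_gap_frac] <- "gap_fraction"
  keep <- is.na(reason)
  removed <- data.frame(gene_id = names(alignment)[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE)
  if (sum(keep) < 2L) {
    if (nrow(removed)) log_msg("family discarded: ", sum(keep),
                               " row(s) left after filtering")
    return(list(alignment = NULL, removed = removed, discarded = TRUE))
  }
  mat <- mat[keep, , drop = FALSE]
  all_gap <- colSums(mat != "-") == 0L
  mat <- mat[, !all_gap, drop = FALSE]
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- names(alignment)[keep]
  list(alignment = out, removed = removed, discarded = FALSE)
}

#' Translate a CDS under the standard genetic code
#'
#' @param cds nucleotide string; length must be a multiple of 3.
#' @return amino-acid string ('*' for stops, 'X' for ambiguous codons).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment into an in-frame codon alignment
#'
#' Uses the protein alignment as a template: every gap column becomes
#' '---', every residue column becomes the corresponding codon of that
#' gene's CDS, in order. The CDS must translate exactly to the ungapped
#' protein row under the standard genetic code (a trailing stop codon is
#' tolerated and trimmed); any disagreement is an error naming the gene,
#' the residue position and the expected/observed residues.
#'
#' @param alignment named character vector of aligned protein rows.
#' @param cds named character vector of CDS sequences covering every row.
#' @return named character vector of aligned codon rows (class
#'   `codon_alignment`); each row has 3x the protein alignment width.
#' @examples
#' backtranslate_alignment(c(g1 = "M-K"), c(g1 = "ATGAAA"))
#' @export
backtranslate_alignment <- function(alignment, cds) {
  mat <- split_rows(alignment)
  missing <- setdiff(names(alignment), names(cds))
  if (length(missing))
    stop("no CDS for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- vapply(names(alignment), function(g) {
    row <- mat[match(g, names(alignment)), ]
    s <- toupper(cds[[g]])
    n_res <- sum(row != "-")
    if (nchar(s) == 3L * (n_res + 1L) &&
        translate_cds(substr(s, nchar(s) - 2L, nchar(s))) == "*")
      s <- substr(s, 1L, nchar(s) - 3L)
    if (nchar(s) != 3L * n_res)
      stop("CDS of '", g, "' has ", nchar(s), " bases but the protein row ",
           "has ", n_res, " residues", call. = FALSE)
    obs <- strsplit(translate_cds(s), "", fixed = TRUE)[[1]]
    exp_res <- row[row != "-"]
    bad <- which(obs != exp_res)
    if (length(bad))
      stop("translation mismatch for '", g, "' at residue ", bad[1],
           ": expected ", exp_res[bad[1]], ", observed ", obs[bad[1]],
           call. = FALSE)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    filled <- rep("---", length(row))
    filled[row != "-"] <- codons
    paste(filled, collapse = "")
  }, "")
  names(out) <- names(alignment)
  class(out) <- "codon_alignment"
  out
}
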