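#' Fisher exact enrichment of annotation terms
#'
#' For every term annotated in the background, tests whether the
#' foreground gene set (e.g. the genes duplicated on one species-tree
#' branch) is enriched for that term with a one-sided Fisher exact test
#' on the 2x2 table (foreground-with-term, foreground-without-term;
#' background-only-with-term, background-only-without-term), then adjusts
#' across terms with Benjamini-Hochberg. `expected` is the count expected
#' under independence, foreground_size x annotated / background_size.
#'
#' @param annotation data.frame with columns gene_id, term_id (one row
#'   per assignment).
#' @param foreground character vector of gene ids; must be a subset of
#'   `background`.
#' @param background character vector of gene ids (the gene universe).
#' @param alternative "greater" (enrichment, default) or "two.sided".
#' @return data.frame sorted by p-value: term_id, annotated, significant,
#'   expected, p_value, fdr.
#' @export
fisher_enrichment <- function(annotation, foreground, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  foreground <- unique(foreground)
  background <- unique(background)
  outside <- setdiff(foreground, background)
  if (length(outside))
    stop("foreground gene(s) absent from background: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  ann <- unique(annotation[annotation$gene_id %in% background, ,
                           drop = FALSE])
  n_bg <- length(background)
  n_fg <- length(foreground)
  terms <- sort(unique(ann$term_id))
  if (!length(terms))
    return(data.frame(term_id = character(0), annotated = integer(0),
                      significant = integer(0), expected = numeric(0),
                      p_value = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE))
  in_fg <- ann$gene_id %in% foreground
  annotated <- as.integer(table(factor(ann$term_id, levels = terms)))
  significant <- as.integer(table(factor(ann$term_id[in_fg],
                                         levels = terms)))
  p <- vapply(seq_along(terms), function(i) {
    k <- significant[i]; K <- annotated[i]
    tab <- matrix(c(k, n_fg - k, K - k, n_bg - n_fg - K + k), nrow = 2L)
    stats::fisher.test(tab, alternative = alternative)$p.value
  }, 0)
  out <- data.frame(term_id = terms, annotated = annotated,
                    significant = significant,
                    expected = n_fg * annotated / n_bg,
                    p_value = p, fdr = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: the i-th smallest p-value is
#' mapped to min over j >= i of (m p_(j) / j), capped at 1, preserving
#' the input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values in the same order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  bad <- which(!is.na(p) & (p < 0 | p > 1))
  if (length(bad))
    stop("p-value(s) outside [0, 1] at index(es): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
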