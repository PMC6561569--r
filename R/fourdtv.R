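# prefixes whose codons are fourfold degenerate under the standard code:
# Leu CTN, Val GTN, Ser TCN, Pro CCN, Thr ACN, Ala GCN, Arg CGN, Gly GGN
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

codon_matrix <- function(row) {
  n <- nchar(row)
  if (n %% 3L != 0L)
    stop("codon row length ", n, " is not a multiple of 3", call. = FALSE)
  substring(toupper(row), seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Is an aligned codon-pair site fourfold degenerate?
#'
#' A site qualifies for 4dTv counting when both codons are gap-free and
#' unambiguous (ACGT only), both belong to one of the eight fourfold
#' codon families of the standard genetic code, and the first two codon
#' positions are identical between the two sequences. Requiring identical
#' prefixes guarantees the third-position difference is synonymous.
#'
#' @param codon_a,codon_b aligned 3-mers over A,C,G,T,N,-; vectorised.
#' @return logical vector.
#' @examples
#' is_fourfold_site("GGA", "GGT")  # TRUE  (Gly, same prefix)
#' is_fourfold_site("TTA", "TTG")  # FALSE (Leu TTR is twofold)
#' @export
is_fourfold_site <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a)
  codon_b <- toupper(codon_b)
  ok <- grepl("^[ACGT]{3}$", codon_a) & grepl("^[ACGT]{3}$", codon_b)
  pa <- substr(codon_a, 1L, 2L)
  pb <- substr(codon_b, 1L, 2L)
  ok & pa == pb & pa %in% FOURFOLD_PREFIXES
}

#' Is a base substitution a transversion?
#'
#' @param base_a,base_b single bases; vectorised.
#' @return logical: TRUE iff one base is a purine (A,G) and the other a
#'   pyrimidine (C,T).
#' @export
is_transversion <- function(base_a, base_b) {
  base_a <- toupper(base_a)
  base_b <- toupper(base_b)
  (base_a %in% PURINES & base_b %in% PYRIMIDINES) |
    (base_a %in% PYRIMIDINES & base_b %in% PURINES)
}

#' 4dTv distance between two aligned codon rows
#'
#' Counts the fourfold-degenerate sites shared by the pair and the
#' transversions at their third codon positions. The raw distance d is
#' transversions / sites; the saturation-corrected distance is
#' -ln(1 - 2 d) / 2, defined only while d < 0.5. Pairs with fewer than
#' `min_sites` qualifying sites are reported UNDEFINED rather than
#' contributing noisy distances; pairs at or beyond d = 0.5 are SATURATED
#' and excluded from density fitting downstream.
#'
#' @param row_a,row_b equal-length aligned codon rows (nucleotide strings).
#' @param min_sites minimum qualifying sites for a defined distance.
#' @return one-row data.frame: n_4d_sites, n_transversions, raw_4dtv,
#'   corrected_4dtv, status (OK / SATURATED / UNDEFINED).
#' @examples
#' four_dtv("GGAGGA", "GGTGGA")  # one transversion over two Gly sites
#' @export
four_dtv <- function(row_a, row_b, min_sites = 10L) {
  ca <- codon_matrix(row_a)
  cb <- codon_matrix(row_b)
  if (length(ca) != length(cb))
    stop("codon rows have different lengths", call. = FALSE)
  q <- is_fourfold_site(ca, cb)
  n_sites <- sum(q)
  n_tv <- if (n_sites)
    sum(is_transversion(substr(ca[q], 3L, 3L), substr(cb[q], 3L, 3L)))
  else 0L
  raw <- if (n_sites > 0L) n_tv / n_sites else NA_real_
  if (n_sites == 0L) {
    status <- "UNDEFINED"; corrected <- NA_real_
  } else if (n_sites < min_sites) {
    status <- "UNDEFINED"; corrected <- NA_real_
  } else if (raw >= 0.5) {
    status <- "SATURATED"; corrected <- NA_real_
  } else {
    status <- "OK"; corrected <- -log(1 - 2 * raw) / 2
  }
  data.frame(n_4d_sites = n_sites, n_transversions = n_tv,
             raw_4dtv = raw, corrected_4dtv = corrected, status = status,
             stringsAsFactors = FALSE)
}

#' 4dTv distances for paralogue pairs of one codon alignment
#'
#' Computes [four_dtv()] for every requested pair of alignment rows
#' (all within-alignment pairs by default). Pairs are normalised so
#' gene_a < gene_b lexicographically and rows are returned sorted, making
#' the output order deterministic.
#'
#' @param alignment named character vector of aligned codon rows.
#' @param pairs data.frame with columns gene_a, gene_b, or NULL for all
#'   pairs.
#' @param min_sites minimum qualifying sites; see [four_dtv()].
#' @return data.frame: gene_a, gene_b, n_4d_sites, n_transversions,
#'   raw_4dtv, corrected_4dtv, status.
#' @export
family_pairwise_4dtv <- function(alignment, pairs = NULL, min_sites = 10L) {
  ids <- names(alignment)
  if (is.null(pairs)) {
    if (length(ids) < 2L)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        n_4d_sites = integer(0), n_transversions = integer(0),
                        raw_4dtv = numeric(0), corrected_4dtv = numeric(0),
                        status = character(0), stringsAsFactors = FALSE))
    cmb <- utils::combn(sort(ids), 2L)
    pairs <- data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                        stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      n_4d_sites = integer(0), n_transversions = integer(0),
                      raw_4dtv = numeric(0), corrected_4dtv = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  unknown <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), ids)
  if (length(unknown))
    stop("pair list references absent gene id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  a <- pmin(pairs$gene_a, pairs$gene_b)
  b <- pmax(pairs$gene_a, pairs$gene_b)
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  cod <- lapply(alignment, codon_matrix)
  rows <- lapply(seq_along(a), function(i) {
    ca <- cod[[a[i]]]; cb <- cod[[b[i]]]
    q <- is_fourfold_site(ca, cb)
    n_sites <- sum(q)
    n_tv <- if (n_sites)
      sum(is_transversion(substr(ca[q], 3L, 3L), substr(cb[q], 3L, 3L)))
    else 0L
    c(n_sites, n_tv)
  })
  counts <- do.call(rbind, rows)
  n_sites <- counts[, 1L]
  n_tv <- counts[, 2L]
  raw <- ifelse(n_sites > 0L, n_tv / n_sites, NA_real_)
  status <- ifelse(n_sites < min_sites, "UNDEFINED",
                   ifelse(raw >= 0.5, "SATURATED", "OK"))
  corrected <- rep(NA_real_, length(raw))
  ok <- status == "OK"
  corrected[ok] <- -log(1 - 2 * raw[ok]) / 2
  data.frame(gene_a = a, gene_b = b, n_4d_sites = n_sites,
             n_transversions = n_tv, raw_4dtv = raw,
             corrected_4dtv = corrected, status = status,
             stringsAsFactors = FALSE)
}
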