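test_that("dust score matches the triplet formula on constructed cases", {
  # homopolymer window: 62 identical triplets -> (62*61/2)/61 = 31
  expect_equal(dust_score(strrep("A", 64), 64L), 31)
  # all 62 window triplets distinct -> 0 (a de Bruijn-style 64-mer)
  distinct <-
    "AACAAAGAATACCACGACTAGCAGGAGTATCATGATTCCCGCCTCGGCGTCTGCTTGGGTGTTA"
  tri <- substring(distinct, 1:62, 3:64)
  expect_equal(anyDuplicated(tri), 0L)
  expect_equal(dust_score(distinct, 64L), 0)
  # determinism and the short-sequence convention
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
             collapse = "")
  expect_identical(dust_score(s), dust_score(s))
  expect_equal(dust_score("AC"), 0)
})

test_that("transcript filtering applies inclusive/exclusive boundaries", {
  set.seed(17)
  complex500 <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                      collapse = "")
  complex600 <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                      collapse = "")
  recs <- data.frame(
    id = c("short", "boundary", "lowtpm", "lowcomplexity", "good"),
    sequence = c(substr(complex600, 1L, 490L),  # 490 bp: fails length
                 complex500,                    # 500 bp, tpm exactly 1
                 complex600,                    # fails expression only
                 strrep("A", 600L),             # homopolymer
                 complex600),
    tpm = c(5, 1, 0.5, 10, 3),
    stringsAsFactors = FALSE)
  out <- filter_transcripts(recs)
  expect_setequal(out$retained$id, c("boundary", "good"))
  expect_equal(out$rejected$reason[out$rejected$id == "short"], "length")
  expect_equal(out$rejected$reason[out$rejected$id == "lowtpm"],
               "expression")
  expect_equal(out$rejected$reason[out$rejected$id == "lowcomplexity"],
               "complexity")
  # idempotence
  again <- filter_transcripts(out$retained[c("id", "sequence", "tpm")])
  expect_equal(again$retained$id, out$retained$id)
  expect_equal(nrow(again$rejected), 0L)
})

test_that("isoform clustering is a transitive, order-invariant partition", {
  tx <- data.frame(id = paste0("t", 1:4), tpm = c(5, 9, 1, 2),
                   stringsAsFactors = FALSE)
  m <- data.frame(id_a = c("t1", "t2"), id_b = c("t2", "t3"),
                  overlap = c(150, 120), identity = c(0.98, 0.99),
                  stringsAsFactors = FALSE)
  cl <- cluster_isoforms(m, tx)
  expect_equal(unname(cl$gene_id[match(paste0("t", 1:4), cl$transcript_id)]),
               c("t2", "t2", "t2", "t4"))
  expect_true(cl$is_representative[cl$transcript_id == "t2"])

  # below-threshold matches do not join
  m2 <- data.frame(id_a = "t1", id_b = "t2", overlap = 99, identity = 0.99)
  cl2 <- cluster_isoforms(m2, tx)
  expect_equal(length(unique(cl2$gene_id)), 4L)
  m3 <- data.frame(id_a = "t1", id_b = "t2", overlap = 150,
                   identity = 0.969)
  expect_equal(length(unique(cluster_isoforms(m3, tx)$gene_id)), 4L)

  # permuting the match list never changes the partition
  set.seed(21)
  tx_big <- data.frame(id = paste0("x", 1:30),
                       tpm = round(stats::runif(30, 0, 20), 2))
  mm <- data.frame(id_a = sample(tx_big$id, 40, replace = TRUE),
                   id_b = sample(tx_big$id, 40, replace = TRUE),
                   overlap = sample(50:300, 40, replace = TRUE),
                   identity = stats::runif(40, 0.9, 1))
  mm <- mm[mm$id_a != mm$id_b, ]
  base <- cluster_isoforms(mm, tx_big)
  for (i in 1:5) {
    perm <- cluster_isoforms(mm[sample(nrow(mm)), ], tx_big)
    expect_equal(perm, base)
  }
  expect_setequal(base$transcript_id, tx_big$id)

  expect_error(cluster_isoforms(
    data.frame(id_a = "t1", id_b = "zz", overlap = 150, identity = 0.99),
    tx), "unknown transcript")
})

test_that("family alignment filter drops long, gappy and low-complexity rows", {
  aln <- c(long = paste(rep("K", 1501), collapse = ""),
           keep1 = paste(c(rep("K", 1000), rep("-", 501)), collapse = ""),
           keep2 = paste(c(rep("M", 1500), "-"), collapse = ""))
  out <- filter_family_alignment(aln)
  expect_equal(out$removed$gene_id, "long")
  expect_equal(out$removed$reason, "protein_length")
  expect_false(out$discarded)
  # gap fraction is strictly-greater-than 40%
  aln2 <- c(a = paste(c(rep("A", 59), rep("-", 41)), collapse = ""),
            b = strrep("A", 100), c = strrep("C", 100))
  out2 <- filter_family_alignment(aln2)
  expect_equal(out2$removed$reason, "gap_fraction")
  aln3 <- c(a = paste(c(rep("A", 60), rep("-", 40)), collapse = ""),
            b = strrep("A", 100))
  expect_equal(nrow(filter_family_alignment(aln3)$removed), 0L)
  # a 2-row family losing a row is discarded
  out4 <- filter_family_alignment(
    c(a = strrep("K", 1501), b = paste0(strrep("M", 1500), "-")))
  expect_true(out4$discarded)
  expect_null(out4$alignment)
  # all-gap columns are removed after row filtering
  aln5 <- c(x = "MK-A-", y = "MR-C-", z = "WY-D-")
  out5 <- filter_family_alignment(aln5)
  expect_equal(unname(nchar(out5$alignment)), rep(3L, 3L))
})

test_that("filtering is idempotent on its own output", {
  set.seed(31)
  aln <- vapply(1:20, function(i) {
    n <- 120L
    r <- sample(c("A", "C", "D", "E", "-"), n, replace = TRUE,
                prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    paste(r, collapse = "")
  }, "")
  names(aln) <- paste0("p", 1:20)
  once <- filter_family_alignment(aln)
  twice <- filter_family_alignment(once$alignment)
  expect_equal(twice$alignment, once$alignment)
  expect_equal(nrow(twice$removed), 0L)
})

test_that("back-translation maps residues to codons and catches mismatches", {
  expect_equal(unclass(backtranslate_alignment(c(g = "M-K"),
                                               c(g = "ATGAAA"))),
               c(g = "ATG---AAA"))
  expect_equal(unclass(backtranslate_alignment(c(g = "MK"),
                                               c(g = "ATGAAG"))),
               c(g = "ATGAAG"))
  expect_error(backtranslate_alignment(c(g = "MK"), c(g = "ATGAAT")),
               "residue 2.*expected K, observed N")
  # a trailing stop codon on the CDS is tolerated
  expect_equal(unclass(backtranslate_alignment(c(g = "MK"),
                                               c(g = "ATGAAATAA"))),
               c(g = "ATGAAA"))
})

test_that("codon alignments translate back to their protein rows", {
  # random-fixture round trip across 200 families
  set.seed(7)
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], NULL)
  rev_code <- split(names(Biostrings::GENETIC_CODE),
                    Biostrings::GENETIC_CODE)
  for (f in 1:200) {
    n_col <- sample(5:40, 1L)
    n_row <- sample(2:5, 1L)
    prot <- replicate(n_row, {
      r <- sample(aas, n_col, replace = TRUE)
      gaps <- stats::runif(n_col) < 0.2
      r[gaps] <- "-"
      r
    })
    rows <- apply(prot, 2L, paste, collapse = "")
    names(rows) <- paste0("g", seq_len(n_row))
    cds <- vapply(seq_len(n_row), function(i) {
      res <- prot[prot[, i] != "-", i]
      paste(vapply(res, function(a) sample(rev_code[[a]], 1L), ""),
            collapse = "")
    }, "")
    names(cds) <- names(rows)
    codon <- backtranslate_alignment(rows, cds)
    back <- vapply(codon, function(r) {
      s <- gsub("-", "", r, fixed = TRUE)
      translate_cds(s)
    }, "")
    expect_equal(unname(back), gsub("-", "", unname(rows), fixed = TRUE))
    expect_true(all(nchar(codon) == 3L * nchar(rows)))
  }
})
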