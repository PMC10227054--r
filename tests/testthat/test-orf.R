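# ORF prediction, CDS grouping, ORF typing, peptide mapping

random_codons <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cods <- setdiff(as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                        paste0), c("A", "C", "G", "T"), paste0)),
                  c("TAA", "TAG", "TGA"))
  paste(sample(cods, n, replace = TRUE), collapse = "")
}

test_that("longest ATG-initiated ORF with in-sequence stop, >=100 codons", {
  set.seed(2)
  utr <- "GCCGCCGCCG"                      # 10-nt UTR, no ATG
  body <- random_codons(150)
  seqv <- paste0(utr, "ATG", body, "TAA", "GGGCCC")
  orf <- predict_orf(seqv)
  expect_equal(nchar(orf$protein), 151L)
  expect_identical(substr(orf$protein, 1L, 1L), "M")
  expect_equal(orf$orf_start, 10L)
  # 99 codons falls below the default threshold
  short <- paste0(utr, "ATG", random_codons(98), "TAA")
  expect_null(predict_orf(short))
  expect_equal(nchar(predict_orf(short, min_codons = 99L)$protein), 99L)
  # no in-frame stop within the sequence -> no ORF
  expect_null(predict_orf(paste0("ATG", random_codons(120))))
  expect_error(predict_orf("ATGNNN"), "position 4")
})

test_that("predict_orf equals the exhaustive ATG-scan oracle", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(200:1200, 1L)
    seqv <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    got <- predict_orf(seqv, min_codons = 10L)
    want <- oracle_orf(seqv, min_codons = 10L)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(nchar(got$protein), want$len)
      expect_equal(got$orf_start, want$start - 1L)
    }
  }
})

test_that("skipping a frame-preserving 63-nt exon deletes exactly 21 AA", {
  # two-isoform gene: the skipped internal exon is 63 nt (21 codons)
  set.seed(33)
  e1 <- paste0("ATG", random_codons(40))          # 123 nt
  e2 <- random_codons(21)                         # 63 nt, frame-preserving
  e3 <- paste0(random_codons(40), "TAA")          # stop in-frame at the end
  inclusion <- paste0(e1, e2, e3)
  skip <- paste0(e1, e3)
  p_inc <- predict_orf(inclusion, min_codons = 50L)
  p_skp <- predict_orf(skip, min_codons = 50L)
  expect_equal(nchar(p_inc$protein) - nchar(p_skp$protein), 21L)
  # and the flanks are unchanged
  expect_identical(substr(p_inc$protein, 1L, 41L),
                   substr(p_skp$protein, 1L, 41L))
})

test_that("in-frame 3k-nt deletions shorten the protein by exactly k AA", {
  set.seed(44)
  for (k in c(5L, 21L, 33L)) {
    pre <- paste0("ATG", random_codons(30))
    del <- random_codons(k)
    post <- paste0(random_codons(30), "TAA")
    a <- predict_orf(paste0(pre, del, post), min_codons = 10L)
    b <- predict_orf(paste0(pre, post), min_codons = 10L)
    expect_equal(nchar(a$protein) - nchar(b$protein), k)
  }
})

test_that("unique CDS groups count distinct proteins", {
  orfs <- data.table::data.table(
    isoform_id = c("i1", "i2", "i3"),
    orf_start = 0L,
    protein = c("MABCDEF", "MABCDEF", "MABCDXF"))
  g <- unique_cds(orfs)
  expect_equal(nrow(g$groups), 2L)
  expect_equal(sum(g$groups$n_isoforms), 3L)
  expect_equal(g$membership$cds_group[1L], g$membership$cds_group[2L])
  expect_false(g$membership$cds_group[1L] == g$membership$cds_group[3L])
  # cardinality oracle on random protein sets
  set.seed(3)
  prot <- replicate(60, paste(sample(LETTERS[1:20], 30, TRUE), collapse = ""))
  prot <- sample(prot, 100, TRUE)
  orfs2 <- data.table::data.table(isoform_id = sprintf("x%d", 1:100),
                                  orf_start = 0L, protein = prot)
  expect_equal(nrow(unique_cds(orfs2)$groups), length(unique(prot)))
})

test_that("ORF typing: annotated / variant / novel-locus", {
  ref <- c(P1 = "MAAAAKRRRR", P2 = "MCCCCKDDDD")
  orfs <- data.table::data.table(
    isoform_id = c("a", "b", "c"),
    orf_start = 0L,
    protein = c("MAAAAKRRRR", "MAAAAKRRRX", "MEEEE"))
  typed <- classify_orfs(orfs, ref, gene_ids = c("G1", "G1", NA))
  expect_identical(typed$orf_type, c("annotated", "variant", "novel-locus"))
})

test_that("peptide mapping: substring rule, specificity, decoys", {
  orfs <- data.table::data.table(
    isoform_id = c("iso_inc", "iso_skp"),
    orf_start = 0L,
    protein = c("MAAAKWWWCCCKDDDR", "MAAAKDDDR"))
  ref <- c(P1 = "MAAAKWWWCCCKDDDR")
  peps <- c("WWWCCCK",    # in both iso_inc and the reference proteome
            "MAAAKDDDR",  # spans the skip junction: only iso_skp, not in ref
            "EEEEEEE")    # decoy
  res <- map_peptides(peps, orfs, ref)
  m <- res$matches
  expect_equal(m$n_isoforms, c(1L, 1L, 0L))
  expect_identical(m$in_reference_proteome, c(TRUE, FALSE, FALSE))
  expect_identical(m$isoform_specific, c(FALSE, TRUE, FALSE))
  expect_identical(res$support$supported, c(TRUE, TRUE))
  expect_error(map_peptides("MAAX1", orfs, ref), "non-amino-acid")
})

test_that("tryptic digest cleaves after K/R except before P", {
  peps <- tryptic_digest("MAAAKPBBBBBBKCCCCCCRDDDDDDD", min_len = 5L)
  expect_setequal(peps, c("MAAAKPBBBBBBK", "CCCCCCR", "DDDDDDD"))
  # sampled truth peptides match their isoform of origin in the pipeline
  nf <- sim_noise_free()
  run <- run_noise_free()
  peps <- readLines(nf$sim$paths$peptides)
  decoys <- nf$sim$manifest$decoy_peptides
  matches <- run$stages$peptides$matches
  dec <- matches[matches$peptide %in% decoys, ]
  expect_true(all(dec$n_isoforms == 0L))
  real <- matches[!matches$peptide %in% decoys, ]
  expect_true(all(real$n_isoforms >= 1L))
})
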