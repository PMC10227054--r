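# CIGAR -> exon chains, and junction-chain collapse

sam_line <- function(qname, flag, rname, pos, mapq, cigar) {
  paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*", sep = "\t")
}

read_sam_text <- function(lines) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100000", lines), f)
  read_sam(f)
}

test_that("CIGAR arithmetic: N splits exons, D advances within an exon", {
  sam <- read_sam_text(c(
    sam_line("r1", 0, "chr1", 1, 60, "100M100N100M"),
    sam_line("r2", 0, "chr1", 1, 60, "50M2D48M100N100M"),
    sam_line("r3", 0, "chr1", 1, 10, "100M"),
    sam_line("r4", 4, "*", 0, 0, "*")))
  res <- chain_from_alignment(sam, min_mapq = 20L)
  expect_equal(unname(res$chains$exons[[1L]]),
               unname(cbind(c(0L, 200L), c(100L, 300L))))
  expect_equal(unname(res$chains$exons[[2L]]),
               unname(cbind(c(0L, 200L), c(100L, 300L))))
  rej <- setNames(res$rejects$reason, res$rejects$read_id)
  expect_identical(rej[["r3"]], "low-mapq")
  expect_identical(rej[["r4"]], "unmapped")
  # flag 16 records a minus-strand alignment
  sam2 <- read_sam_text(sam_line("r5", 16, "chr1", 11, 60, "10M10N10M"))
  res2 <- chain_from_alignment(sam2)
  expect_identical(res2$chains$strand, "-")
  expect_error(chain_from_alignment(
    read_sam_text(sam_line("r6", 0, "chr1", 1, 60, "10M5B10M"))),
    "r6")
})

test_that("simulated alignments reproduce the truth exon chains", {
  nf <- sim_noise_free()
  sam <- read_sam(nf$sim$paths$sam)
  res <- chain_from_alignment(sam)
  man <- data.table::as.data.table(nf$sim$manifest$reads)
  iso <- data.table::as.data.table(nf$sim$manifest$isoforms)
  truth_chain <- setNames(iso$chain, iso$transcript_id)
  m <- merge(res$chains[, .(read_id, chain)], man[, .(read_id, transcript_id)],
             by = "read_id")
  expect_identical(m$chain, unname(truth_chain[m$transcript_id]))
})

test_that("collapse merges identical chains with 5'-most TSS, keeps distinct ones", {
  ch <- data.table::data.table(
    read_id = c("a", "b", "c"),
    chrom = "chr1", strand = "+",
    start = c(100L, 130L, 95L), end = c(500L, 500L, 500L),
    chain = c("chr1:+:200-300", "chr1:+:200-300", "chr1:+:210-300"),
    n_exons = 2L,
    exons = list(rbind(c(100L, 200L), c(300L, 500L)),
                 rbind(c(130L, 200L), c(300L, 500L)),
                 rbind(c(95L, 210L), c(300L, 500L))))
  res <- collapse_chains(ch)
  expect_equal(nrow(res$isoforms), 2L)
  merged <- res$isoforms[res$isoforms$chain == "chr1:+:200-300", ]
  expect_equal(merged$tss, 100L)     # 5'-most start among members
  expect_equal(merged$n_reads, 2L)
  # support conservation
  expect_equal(sum(res$isoforms$n_reads), nrow(ch))
  # permutation invariance of IDs and membership
  res2 <- collapse_chains(ch[c(3, 1, 2)])
  expect_identical(
    res$isoforms[order(isoform_id), .(isoform_id, chain, n_reads)],
    res2$isoforms[order(isoform_id), .(isoform_id, chain, n_reads)])
  # idempotence: collapsing representatives is a no-op on the chain set
  rep_ch <- res$isoforms[, .(read_id = isoform_id, chrom, strand, start, end,
                             chain, n_exons)]
  rep_ch$exons <- res$isoforms$exons
  res3 <- collapse_chains(rep_ch)
  expect_setequal(res3$isoforms$chain, res$isoforms$chain)
})

test_that("mono-exon reads merge under reciprocal overlap within end fuzz", {
  mk <- function(id, s, e) data.table::data.table(
    read_id = id, chrom = "chr1", strand = "+", start = s, end = e,
    chain = "chr1:+:", n_exons = 1L, exons = list(cbind(s, e)))
  ch <- data.table::rbindlist(list(
    mk("a", 100L, 500L), mk("b", 150L, 540L),   # merge (diffs 50, 40)
    mk("c", 100L, 700L),                        # end diff 200 -> separate
    mk("d", 2000L, 2400L)))                     # disjoint -> separate
  res <- collapse_chains(ch, end_fuzz = 100L)
  expect_equal(nrow(res$isoforms), 3L)
  m <- res$isoforms[res$isoforms$n_reads == 2L, ]
  expect_equal(m$start, 100L); expect_equal(m$end, 540L)
})

test_that("loci are overlap components numbered in genomic order", {
  ch <- data.table::data.table(
    read_id = c("a", "b", "c"),
    chrom = "chr1", strand = c("+", "+", "+"),
    start = c(100L, 150L, 5000L), end = c(500L, 600L, 5500L),
    chain = c("chr1:+:200-300", "chr1:+:200-350", "chr1:+:5200-5300"),
    n_exons = 2L,
    exons = list(rbind(c(100L, 200L), c(300L, 500L)),
                 rbind(c(150L, 200L), c(350L, 600L)),
                 rbind(c(5000L, 5200L), c(5300L, 5500L))))
  res <- collapse_chains(ch)
  locus <- sub("^PB\\.([0-9]+)\\..*", "\\1", res$isoforms$isoform_id)
  expect_equal(sort(unique(locus)), c("1", "2"))
  expect_true(all(locus[res$isoforms$start < 1000L] == "1"))
})

test_that("noise-free collapse recovers the expressed truth chain set", {
  run <- run_noise_free()
  nf <- sim_noise_free()
  iso <- data.table::as.data.table(nf$sim$manifest$isoforms)
  expect_setequal(run$stages$isoforms$chain, iso[n_full_length > 0L, chain])
})
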