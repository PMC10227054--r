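# structural classification and the artifact/end-support filters

test_that("spec-style toys: FSM, ISM, NIC, NNC", {
  ann <- toy_reference()
  fsm <- classify_isoform("chr1", "+", rbind(c(90L, 200L), c(300L, 420L)), ann)
  expect_identical(fsm$category, "FSM")
  expect_identical(fsm$evidence, "T1")
  # consecutive suffix of a longer reference chain
  ann2 <- annotation(list(
    toy_tx("T1", rbind(c(100L, 200L), c(300L, 400L), c(500L, 600L)))))
  ism <- classify_isoform("chr1", "+", rbind(c(310L, 400L), c(500L, 620L)), ann2)
  expect_identical(ism$category, "ISM")
  # novel combination of annotated sites
  annN <- annotation(list(
    toy_tx("T1", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))))
  nic <- classify_isoform("chr1", "+", rbind(c(0L, 100L), c(400L, 500L)), annN)
  expect_identical(nic$category, "NIC")
  nnc <- classify_isoform("chr1", "+", rbind(c(0L, 100L), c(413L, 500L)), annN)
  expect_identical(nnc$category, "NNC")
  expect_identical(nnc$evidence, "413")
})

test_that("non-catalog categories: antisense, fusion, genic_intron, genic, intergenic", {
  ann <- annotation(list(
    toy_tx("T1", rbind(c(100L, 200L), c(300L, 400L)), gene = "GA"),
    toy_tx("T2", rbind(c(5000L, 5100L), c(5200L, 5300L)), gene = "GB")))
  as_ <- classify_isoform("chr1", "-", rbind(c(120L, 180L)), ann)
  expect_identical(as_$category, "antisense")
  # spans two disjoint loci without touching exons on either strand
  fus <- classify_isoform("chr1", "+", rbind(c(220L, 280L), c(5110L, 5180L)), ann)
  expect_identical(fus$category, "fusion")
  gi <- classify_isoform("chr1", "-", cbind(220L, 280L), ann)
  expect_identical(gi$category, "genic_intron")
  ig <- classify_isoform("chr1", "+", cbind(9000L, 9100L), ann)
  expect_identical(ig$category, "intergenic")
  # mono-exon overlapping exon partially but not contained -> genic
  g <- classify_isoform("chr1", "+", cbind(150L, 250L), ann)
  expect_identical(g$category, "genic")
  # mono-exon contained in an exon -> ISM; matching a mono reference -> FSM
  ism <- classify_isoform("chr1", "+", cbind(120L, 180L), ann)
  expect_identical(ism$category, "ISM")
  annM <- annotation(list(toy_tx("M1", cbind(100L, 600L))))
  fsm <- classify_isoform("chr1", "+", cbind(150L, 560L), annM)
  expect_identical(fsm$category, "FSM")
})

test_that("classifier agrees with the brute-force oracle on random queries", {
  ref <- big_annotation()
  queries <- make_queries(ref$annotation, 150L, seed = 31L)
  for (q in queries) {
    got <- classify_isoform(q$chrom, q$strand, q$exons, ref$annotation)
    want <- oracle_classify(q$chrom, q$strand, q$exons, ref$annotation)
    expect_identical(got$category, want$category,
                     info = paste(q$chrom, q$strand,
                                  paste(t(q$exons), collapse = ",")))
  }
})

test_that("strand symmetry: mirrored annotation and queries classify identically", {
  # mirror all coordinates around a fixed point and flip strands
  ref <- big_annotation()
  ann <- ref$annotation
  M <- 10000000L
  mirror_tx <- function(t) transcript_model(
    t$transcript_id, t$gene_id, t$chrom, if (t$strand == "+") "-" else "+",
    cbind(M - t$exons[, 2L], M - t$exons[, 1L]))
  ann_m <- annotation(lapply(unname(ann$transcripts), mirror_tx))
  queries <- make_queries(ann, 40L, seed = 17L)
  for (q in queries) {
    a <- classify_isoform(q$chrom, q$strand, q$exons, ann)
    me <- cbind(M - q$exons[, 2L], M - q$exons[, 1L])
    me <- me[order(me[, 1L]), , drop = FALSE]
    b <- classify_isoform(q$chrom, if (q$strand == "+") "-" else "+",
                          me, ann_m)
    expect_identical(a$category, b$category)
  }
})

test_that("junction artifact checks: motifs and RT-switch direct repeats", {
  # hand-built plus-strand genome: exon(0,20) intron(20,80) exon(80,100)
  base <- paste(rep("ACGT", 30), collapse = "")         # 120 nt, repeat-free 8-mers? no: periodic!
  # use an aperiodic sequence instead
  set.seed(41)
  base <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  plant <- function(s, at, what) { substr(s, at + 1L, at + nchar(what)) <- what; s }
  g <- plant(base, 20L, "GT"); g <- plant(g, 78L, "AG")
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  exons <- rbind(c(0L, 20L), c(80L, 100L))
  ok <- junction_artifact_check("chr1", "+", exons, genome)
  expect_false(ok$noncanonical_novel_junction)
  # CT..AC intron motif -> non-canonical
  g2 <- plant(base, 20L, "CT"); g2 <- plant(g2, 78L, "AC")
  bad <- junction_artifact_check("chr1", "+", exons,
                                 Biostrings::DNAStringSet(c(chr1 = g2)))
  expect_true(bad$noncanonical_novel_junction)
  # annotated junctions are exempt
  known <- junction_artifact_check("chr1", "+", exons,
                                   Biostrings::DNAStringSet(c(chr1 = g2)),
                                   known_junctions = "20-80")
  expect_false(known$noncanonical_novel_junction)
  # 8-nt direct repeat ending at donor and at the acceptor boundary (the
  # intronic copy's last two bases coincide with the AG motif, so the
  # repeat must end in AG)
  rep8 <- "GACCTGAG"
  g3 <- plant(g, 20L - 8L, rep8)       # exonic, ends at donor (pos 20)
  g3 <- plant(g3, 80L - 8L, rep8)      # intronic, ends at acceptor (pos 80)
  g3 <- plant(g3, 20L, "GT")           # donor motif unaffected by the repeat
  rt <- junction_artifact_check("chr1", "+", exons,
                                Biostrings::DNAStringSet(c(chr1 = g3)))
  expect_true(rt$rt_switch)
  # with only 7 matching positions the flag stays off
  g4 <- plant(g3, 12L, "T")            # break the first repeat base
  if (substr(g4, 73L, 73L) == "T") g4 <- plant(g4, 12L, "C")
  rt7 <- junction_artifact_check("chr1", "+", exons,
                                 Biostrings::DNAStringSet(c(chr1 = g4)))
  expect_false(rt7$rt_switch)
})

test_that("end support: 50 nt inclusive window, FSM exempt, AND semantics", {
  cage <- data.table::data.table(chrom = "chr1", start = 150L, end = 160L,
                                 strand = "+")
  polya <- data.table::data.table(chrom = "chr1", start = 950L, end = 960L,
                                  strand = "+")
  mk <- function(id, tss, tes, cat) data.table::data.table(
    isoform_id = id, chrom = "chr1", strand = "+", tss = tss, tes = tes,
    category = cat, noncanonical_novel_junction = FALSE, rt_switch = FALSE)
  cl <- data.table::rbindlist(list(
    mk("at50", 100L, 955L, "NIC"),     # TSS exactly 50 from the peak edge
    mk("at51", 99L, 955L, "NIC"),      # 51 -> unsupported
    mk("inside", 155L, 955L, "NIC"),   # inside a peak -> distance 0
    mk("fsm", 99L, 2000L, "FSM"),      # FSM exempt from the filter
    mk("no_tes", 150L, 2000L, "NNC")))
  out <- end_support_filter(cl, cage, polya)
  ret <- setNames(out$retained, out$isoform_id)
  expect_true(ret[["at50"]]);  expect_false(ret[["at51"]])
  expect_true(ret[["inside"]]); expect_true(ret[["fsm"]])
  expect_false(ret[["no_tes"]])   # CAGE alone is not enough (AND rule)
  # artifact flags veto retention for filtered categories
  cl2 <- mk("art", 100L, 955L, "NIC")
  cl2$rt_switch <- TRUE
  expect_false(end_support_filter(cl2, cage, polya)$retained)
})
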