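# local AS event detection and summaries

T1 <- function() toy_tx("T1", rbind(c(0L, 100L), c(200L, 300L), c(400L, 500L)))
T2 <- function() toy_tx("T2", rbind(c(0L, 100L), c(400L, 500L)))
T3 <- function() toy_tx("T3", rbind(c(0L, 120L), c(200L, 300L), c(400L, 500L)))
T4 <- function() toy_tx("T4", rbind(c(0L, 300L), c(400L, 500L)))

test_that("toy events: ES, A5, RI with correct coordinates and sets", {
  es <- detect_events(list(T1(), T2()), gene_id = "G")
  expect_equal(nrow(es), 1L)
  expect_identical(es$event_type, "ES")
  expect_identical(es$coords, "100;200;300;400")
  expect_identical(es$inclusion, "T1")
  expect_identical(es$exclusion, "T2")

  a5 <- detect_events(list(T1(), T3()))
  expect_identical(a5$event_type, "A5")
  expect_identical(a5$coords, "100;120;200")

  ri <- detect_events(list(T1(), T4()))
  expect_identical(ri$event_type, "RI")
  expect_identical(ri$coords, "0;100;200;300")
  expect_identical(ri$inclusion, "T4")   # retention side
  expect_identical(ri$exclusion, "T1")

  # with all four transcripts: the ES, two A5 (donors 100/120 at acceptor
  # 200; donors 100/300 at acceptor 400 via T4's long exon) and two RI
  # (T4's exon retains T1's and T3's first intron variants)
  all4 <- detect_events(list(T1(), T2(), T3(), T4()))
  expect_setequal(all4$event_type, c("ES", "A5", "RI"))
  expect_equal(nrow(all4), 5L)
})

test_that("A5/A3 and AF/AL are strand-aware", {
  # same structures on the minus strand: alternative genomic-left donor
  # becomes an alternative acceptor
  t1m <- toy_tx("T1", rbind(c(0L, 100L), c(200L, 300L)), strand = "-")
  t3m <- toy_tx("T3", rbind(c(0L, 120L), c(200L, 300L)), strand = "-")
  ev <- detect_events(list(t1m, t3m))
  expect_identical(ev$event_type, "A3")
  # disjoint first exons sharing the downstream acceptor -> AF (plus)
  tf1 <- toy_tx("F1", rbind(c(0L, 60L), c(400L, 500L)))
  tf2 <- toy_tx("F2", rbind(c(150L, 210L), c(400L, 500L)))
  ev2 <- detect_events(list(tf1, tf2))
  expect_identical(ev2$event_type, "AF")
  # same exons on minus strand: those are now last exons from a shared donor
  tf1m <- toy_tx("F1", rbind(c(0L, 60L), c(400L, 500L)), strand = "-")
  tf2m <- toy_tx("F2", rbind(c(150L, 210L), c(400L, 500L)), strand = "-")
  expect_identical(detect_events(list(tf1m, tf2m))$event_type, "AL")
})

test_that("MX requires non-overlapping alternatives that never co-occur", {
  tm1 <- toy_tx("M1", rbind(c(0L, 100L), c(200L, 260L), c(600L, 700L)))
  tm2 <- toy_tx("M2", rbind(c(0L, 100L), c(400L, 460L), c(600L, 700L)))
  ev <- detect_events(list(tm1, tm2))
  expect_identical(ev$event_type, "MX")
  expect_identical(ev$coords, "100;200;260;400;460;600")
  # a transcript containing both alternatives vetoes the MX call
  tboth <- toy_tx("MB", rbind(c(0L, 100L), c(200L, 260L), c(400L, 460L),
                              c(600L, 700L)))
  ev2 <- detect_events(list(tm1, tm2, tboth))
  expect_false("MX" %in% ev2$event_type)
})

test_that("event detection equals exhaustive enumeration on synthetic genes", {
  nf <- sim_noise_free()
  ann <- nf$sim$annotation
  novels <- nf$sim$novels$novels
  novel_gene <- vapply(novels, `[[`, "", "gene_id")
  checked <- 0L
  for (g in names(ann$genes)) {
    txs <- c(gene_transcripts(ann, g), novels[novel_gene == g])
    if (length(txs) < 2L || length(txs) > 5L) next
    got <- detect_events(txs, gene_id = g)
    got_keys <- paste(got$event_type, got$coords)
    want_keys <- oracle_events(txs)
    expect_setequal(got_keys, want_keys)
    checked <- checked + 1L
  }
  expect_gte(checked, 5L)
})

test_that("event detection is permutation-invariant and monotone", {
  txs <- list(T1(), T2(), T3(), T4())
  base <- detect_events(txs)
  perm <- detect_events(txs[c(3, 1, 4, 2)])
  expect_identical(base, perm)
  # monotone growth over nested transcript sets of synthetic genes
  nf <- sim_noise_free()
  ann <- nf$sim$annotation
  novels <- nf$sim$novels$novels
  novel_gene <- vapply(novels, `[[`, "", "gene_id")
  n_novel <- vapply(names(ann$genes), function(g) sum(novel_gene == g), 0L)
  for (g in utils::head(names(ann$genes)[n_novel >= 2L], 4L)) {
    txs <- c(gene_transcripts(ann, g), novels[novel_gene == g])
    prev <- character(0)
    for (k in 2:length(txs)) {
      ev <- detect_events(txs[seq_len(k)])
      keys <- paste(ev$event_type, ev$coords)
      expect_true(all(prev %in% keys))
      prev <- keys
    }
  }
})

test_that("every planted perturbation surfaces as an event of its type", {
  nf <- sim_noise_free()
  ann <- nf$sim$annotation
  truth <- nf$sim$novels$truth
  novels <- nf$sim$novels$novels
  expected_type <- c(ES = "ES", A5 = "A5", A3 = "A3", AF = "AF", AL = "AL",
                     RI = "RI", MX = "MX", novel_exon = "ES")
  for (i in seq_len(nrow(truth))) {
    txs <- c(gene_transcripts(ann, truth$gene_id[i]), novels[i])
    ev <- detect_events(txs)
    type <- expected_type[[truth$origin[i]]]
    hit <- ev[ev$event_type == type, ]
    involves <- grepl(truth$transcript_id[i],
                      paste(hit$inclusion, hit$exclusion))
    expect_true(any(involves),
                info = paste(truth$transcript_id[i], truth$origin[i]))
  }
})

test_that("summaries stratify by novelty and conserve totals", {
  ev <- detect_events(list(T1(), T2(), T3(), T4()), gene_id = "G")
  nov <- c(T1 = "known", T2 = "novel", T3 = "novel", T4 = "novel")
  s <- summarize_events(ev, nov)
  expect_equal(sum(s$n), nrow(ev))
  expect_equal(s[s$event_type == "ES" & s$stratum == "novel", n], 1L)
  expect_equal(s[s$event_type == "A5" & s$stratum == "novel", n], 2L)
  expect_equal(s[s$event_type == "RI" & s$stratum == "novel", n], 2L)
  # all transcripts known -> novel stratum empty
  all_known <- summarize_events(ev, c(T1 = "known", T2 = "known",
                                      T3 = "known", T4 = "known"))
  expect_equal(sum(all_known[stratum == "novel", n]), 0L)
  # missing novelty entry is an error
  expect_error(summarize_events(ev, nov[1:2]), "missing")
})
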