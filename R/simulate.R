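## Deterministic synthetic single-cell isoform experiment with ground truth.
##
## The generator states a small but complete world: a multi-gene genome in
## which every reference junction is canonical GT-AG on the transcribed
## strand, reference transcripts that always carry an ORF (exon lengths are
## multiples of 3, exonic sequence is stop-free in frame 0, transcripts
## start ATG, the last exon ends in stop codons in all three frames), novel
## isoforms built as defined perturbations of a reference transcript,
## cluster-structured expression, and barcoded/UMI-tagged full-length reads
## with polyA tails, optional 5' truncation, barcode substitution errors and
## PCR duplicates. Every output is reproducible from (config, seed) and the
## TruthManifest records per-isoform and per-read provenance.
##
## So that `simulate_novel_isoforms(annotation, cfg)` never needs to edit
## the genome, `simulate_reference` pre-plants in every intron a fixed menu
## of cryptic, canonical, repeat-screened splice structures the novel
## simulator may later use: an alternative donor and acceptor 9 nt into the
## intron, and one 72-nt cryptic exon (ATG + 19 stop-free codons + stop
## tail) at intron offset 100. Their genomic coordinates are recorded in
## the annotation's `sim_info` table.

.sample1 <- function(x) x[sample.int(length(x), 1L)]

.ALT_SHIFT <- 9L
.CE_OFFSET <- 100L
.CE_LEN <- 72L

#' Simulation configuration
#'
#' Defaults describe the package's stated toy world: 20 genes, 4 clusters
#' of 50 cells, ~100 reads per cell (~20k reads), a 1:1 novel:reference
#' isoform ratio, novel isoforms cluster-exclusive with probability 0.8.
#'
#' @param seed integer master seed; all generator stages derive from it.
#' @param n_genes number of genes.
#' @param transcripts_per_gene integer range (min, max) of reference
#'   transcripts per gene.
#' @param exons_per_transcript integer range of exons in the gene's longest
#'   ("master") transcript; at least 4.
#' @param exon_len,intron_len length ranges in nt (exon lengths are drawn
#'   as multiples of 3; minimum intron 200).
#' @param n_clusters,cells_per_cluster cluster structure.
#' @param novel_isoform_fraction fraction of the final isoform catalog that
#'   is novel (0.5 means one novel per reference transcript).
#' @param event_mix named probabilities over perturbation types
#'   `ES, A5, A3, AF, AL, RI, MX, novel_exon`; must sum to 1.
#' @param reads_per_cell mean reads per cell (Poisson).
#' @param truncation_prob probability a molecule is 5'-truncated at an
#'   exon-internal point (produces ISM-type reads).
#' @param barcode_error_rate probability a read's barcode carries one
#'   substitution error.
#' @param duplicate_rate probability a molecule emits one PCR duplicate
#'   read.
#' @param polyA_len simulated polyA tail length (nt).
#' @param barcode_len,umi_len tag lengths (10x V3 chemistry: 16 and 12 nt).
#' @param cluster_exclusive_prob probability a novel isoform is expressed
#'   in exactly one cluster (else two).
#' @param short_read_depth junction-support depth factor: a junction backed
#'   by m long-read molecules draws Poisson(m * depth) unique short reads.
#' @param primer5,primer3 adapter primer sequences.
#' @param canonical_junctions plant GT-AG at annotated junctions (default
#'   TRUE; FALSE leaves random dinucleotides).
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 20L,
                              transcripts_per_gene = c(1L, 3L),
                              exons_per_transcript = c(4L, 8L),
                              exon_len = c(120L, 240L),
                              intron_len = c(300L, 600L),
                              n_clusters = 4L,
                              cells_per_cluster = 50L,
                              novel_isoform_fraction = 0.5,
                              event_mix = c(ES = 0.25, A5 = 0.10, A3 = 0.10,
                                            AF = 0.10, AL = 0.10, RI = 0.15,
                                            MX = 0.10, novel_exon = 0.10),
                              reads_per_cell = 100,
                              truncation_prob = 0.1,
                              barcode_error_rate = 0.02,
                              duplicate_rate = 0.05,
                              polyA_len = 30L,
                              barcode_len = 16L,
                              umi_len = 12L,
                              cluster_exclusive_prob = 0.8,
                              short_read_depth = 3,
                              primer5 = "AAGCAGTGGTATCAACGCAGAGTAC",
                              primer3 = "CTACACGACGCTCTTCCGATCT",
                              canonical_junctions = TRUE) {
  cfg <- as.list(environment())
  probs <- c(cfg$truncation_prob, cfg$barcode_error_rate, cfg$duplicate_rate,
             cfg$cluster_exclusive_prob, cfg$novel_isoform_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("simulation_config: probabilities must lie in [0, 1]")
  if (abs(sum(event_mix) - 1) > 1e-8)
    stop("simulation_config: event_mix must sum to 1")
  if (any(event_mix < 0)) stop("simulation_config: negative event_mix entry")
  if (exons_per_transcript[1L] < 4L)
    stop("simulation_config: need at least 4 exons per master transcript")
  if (intron_len[1L] < 200L)
    stop("simulation_config: introns must be at least 200 nt")
  if (any(c(exon_len, intron_len, polyA_len, barcode_len, umi_len,
            n_genes, n_clusters, cells_per_cluster) <= 0))
    stop("simulation_config: lengths and counts must be positive")
  if (exon_len[1L] < 120L)
    stop("simulation_config: exons must be at least 120 nt (ORF budget)")
  structure(cfg, class = "simulation_config")
}

## n random codon strings, each of `codons` sense codons
.codon_seq <- function(n_codons) {
  paste(sample(.sense_codons(), n_codons, replace = TRUE), collapse = "")
}

.splice_in <- function(s, at, repl) {
  ## overwrite substring of s starting at 0-based `at`
  substr(s, at + 1L, at + nchar(repl)) <- repl
  s
}

#' Simulate the reference genome and annotation
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (`DNAStringSet`) and `annotation` (an
#'   [annotation()] whose `sim_info` element records the pre-planted
#'   cryptic sites; see the package vignette).
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  chroms <- c("chr1", "chr2")
  chrom_seq <- stats::setNames(rep("", length(chroms)), chroms)
  txs <- list()
  sim_info <- list()
  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("G%02d", g)
    chrom <- chroms[(g - 1L) %% length(chroms) + 1L]
    strand <- sample(c("+", "-"), 1L)
    n_ex <- .sample1(cfg$exons_per_transcript[1L]:cfg$exons_per_transcript[2L])
    exon_lens <- sample(seq(cfg$exon_len[1L], cfg$exon_len[2L], by = 3L),
                        n_ex, replace = TRUE)
    intron_lens <- sample(cfg$intron_len[1L]:cfg$intron_len[2L],
                          n_ex - 1L, replace = TRUE)
    ## exon sequences (transcribed orientation, frame 0 stop-free)
    exon_seqs <- character(n_ex)
    for (i in seq_len(n_ex)) {
      if (i == 1L) {
        exon_seqs[i] <- paste0("ATG", .codon_seq((exon_lens[i] - 3L) %/% 3L))
      } else if (i == n_ex) {
        exon_seqs[i] <- paste0(.codon_seq((exon_lens[i] - 12L) %/% 3L),
                               .stop_tail())
      } else {
        exon_seqs[i] <- .codon_seq(exon_lens[i] %/% 3L)
      }
    }
    intron_seqs <- vapply(intron_lens, .random_dna, "")
    if (cfg$canonical_junctions) {
      for (i in seq_len(n_ex - 1L)) {
        L <- intron_lens[i]
        s <- intron_seqs[i]
        s <- .splice_in(s, 0L, "GT")
        s <- .splice_in(s, L - 2L, "AG")
        s <- .splice_in(s, .ALT_SHIFT, "GT")               # cryptic alt donor
        s <- .splice_in(s, L - .ALT_SHIFT - 2L, "AG")      # cryptic alt acceptor
        ce <- paste0("ATG", .codon_seq((.CE_LEN - 15L) %/% 3L), .stop_tail())
        s <- .splice_in(s, .CE_OFFSET - 2L, "AG")          # cryptic exon flank
        s <- .splice_in(s, .CE_OFFSET, ce)
        s <- .splice_in(s, .CE_OFFSET + .CE_LEN, "GT")
        intron_seqs[i] <- s
      }
    }
    ## local (transcribed-orientation) coordinates
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- 0L
    body_parts <- character(0)
    for (i in seq_len(n_ex)) {
      starts[i] <- pos; ends[i] <- pos + exon_lens[i]
      body_parts <- c(body_parts, exon_seqs[i])
      pos <- ends[i]
      if (i < n_ex) {
        body_parts <- c(body_parts, intron_seqs[i])
        pos <- pos + intron_lens[i]
      }
    }
    body <- paste(body_parts, collapse = "")
    Lbody <- nchar(body)
    ## RT-switch screening of all potential novel junctions (local coords:
    ## donor = left, acceptor = right of the local intron)
    k <- 8L
    for (pass in 1:10) {
      clean <- TRUE
      for (i in seq_len(n_ex - 1L)) {
        ds <- ends[i]; as_ <- starts[i + 1L]
        cand <- list(c(ds + .ALT_SHIFT, as_), c(ds, as_ - .ALT_SHIFT),
                     c(ds, ds + .CE_OFFSET), c(ds + .CE_OFFSET + .CE_LEN, as_))
        for (cj in cand) {
          x <- cj[1L]; y <- cj[2L]
          kd <- substr(body, x - k + 1L, x)
          ka <- substr(body, y - k + 1L, y)
          if (kd == ka) {
            cur <- substr(body, y - k + 1L, y - k + 1L)
            repl <- setdiff(c("A", "C", "G", "T"), cur)[1L]
            body <- .splice_in(body, y - k, repl)
            clean <- FALSE
          }
        }
      }
      if (clean) break
    }
    ## genomic placement
    gap <- .sample1(1000:3000)
    offset <- nchar(chrom_seq[[chrom]]) + gap
    if (strand == "+") {
      gseq <- body
      gstarts <- offset + starts; gends <- offset + ends
    } else {
      gseq <- revcomp(body)
      gstarts <- offset + Lbody - ends; gends <- offset + Lbody - starts
      o <- order(gstarts); gstarts <- gstarts[o]; gends <- gends[o]
    }
    chrom_seq[[chrom]] <- paste0(chrom_seq[[chrom]], strrep("N", gap), gseq)
    master_exons <- cbind(start = gstarts, end = gends)
    ## reference transcripts: master + distinct internal-exon-skip variants
    n_tx <- .sample1(cfg$transcripts_per_gene[1L]:cfg$transcripts_per_gene[2L])
    txs[[length(txs) + 1L]] <- transcript_model(
      sprintf("%s.T1", gene_id), gene_id, chrom, strand, master_exons)
    skippable <- 2:(n_ex - 1L)
    n_extra <- min(n_tx - 1L, length(skippable))
    if (n_extra > 0L) {
      ks <- sample(skippable, n_extra)
      for (j in seq_len(n_extra)) {
        txs[[length(txs) + 1L]] <- transcript_model(
          sprintf("%s.T%d", gene_id, j + 1L), gene_id, chrom, strand,
          master_exons[-ks[j], , drop = FALSE])
      }
    }
    ## cryptic-site bookkeeping (genomic coordinates, per genomic intron)
    for (i in seq_len(n_ex - 1L)) {
      ds <- ends[i]; as_ <- starts[i + 1L]      # local
      if (strand == "+") {
        d <- offset + ds; a <- offset + as_
        alt5 <- c(d + .ALT_SHIFT, a); alt3 <- c(d, a - .ALT_SHIFT)
        ce <- c(d + .CE_OFFSET, d + .CE_OFFSET + .CE_LEN)
        gidx <- i
      } else {
        d <- offset + Lbody - as_; a <- offset + Lbody - ds
        alt5 <- c(d, a - .ALT_SHIFT); alt3 <- c(d + .ALT_SHIFT, a)
        ce <- c(a - .CE_OFFSET - .CE_LEN, a - .CE_OFFSET)
        gidx <- n_ex - i
      }
      sim_info[[length(sim_info) + 1L]] <- data.table::data.table(
        gene_id = gene_id, intron_gidx = gidx, d = d, a = a,
        alt5_d = alt5[1L], alt5_a = alt5[2L],
        alt3_d = alt3[1L], alt3_a = alt3[2L],
        ce_start = ce[1L], ce_end = ce[2L])
    }
  }
  ## terminal padding so no junction sits at a contig edge
  for (cn in chroms) chrom_seq[[cn]] <- paste0(chrom_seq[[cn]], strrep("N", 500L))
  genome <- Biostrings::DNAStringSet(unlist(chrom_seq))
  names(genome) <- chroms
  ann <- annotation(txs, source = "synthetic-reference")
  ann$sim_info <- data.table::rbindlist(sim_info)
  list(genome = genome, annotation = ann)
}

## the gene's master transcript: most exons, ties by id
.master_of <- function(ann, gene_id) {
  ids <- ann$genes[[gene_id]]
  nex <- vapply(ann$transcripts[ids], function(t) nrow(t$exons), 0L)
  ann$transcripts[[ids[order(-nex, ids)[1L]]]]
}

## consecutive-subchain / equality / site checks used to verify novels
.verify_novel <- function(exons, gene_txs, strand) {
  qj <- junction_chain(exons)
  qstr <- paste(qj[, 1L], qj[, 2L], sep = "-")
  for (t in gene_txs) {
    tj <- junction_chain(t)
    tstr <- paste(tj[, 1L], tj[, 2L], sep = "-")
    if (length(tstr) == length(qstr) && all(tstr == qstr)) return("duplicate")
    if (.is_consecutive_subchain(qstr, tstr)) return("subchain")
  }
  cat_sites <- site_catalog(gene_txs)
  if (strand == "+") {
    q_don <- qj[, 1L]; q_acc <- qj[, 2L]
  } else {
    q_don <- qj[, 2L]; q_acc <- qj[, 1L]
  }
  novel_sites <- c(setdiff(q_don, cat_sites$donors),
                   setdiff(q_acc, cat_sites$acceptors))
  if (length(novel_sites)) "NNC" else "NIC"
}

#' Simulate novel isoforms by defined AS perturbations
#'
#' Each novel isoform perturbs the host gene's master transcript: exon
#' skipping (ES) and intron retention (RI) reuse annotated sites (intended
#' NIC); donor/acceptor shifts 9 nt into the intron (A5/A3), alternative
#' first/last exons, mutually exclusive exons and cassette novel exons use
#' the pre-planted cryptic sites (intended NNC). Infeasible or
#' chain-duplicating draws are resampled with bounded retries.
#'
#' @param ann annotation from [simulate_reference()] (must carry
#'   `sim_info`).
#' @param cfg a [simulation_config()].
#' @return list with `novels` (list of `transcript_model`s) and `truth`
#'   (`data.table`: `transcript_id`, `gene_id`, `origin`, `category`).
#' @export
simulate_novel_isoforms <- function(ann, cfg) {
  stopifnot(inherits(cfg, "simulation_config"), !is.null(ann$sim_info))
  set.seed(cfg$seed + 1000L)
  f <- cfg$novel_isoform_fraction
  n_ref <- length(ann$transcripts)
  n_novel <- round(f / (1 - f) * n_ref)
  gene_ids <- names(ann$genes)
  si_all <- ann$sim_info
  novels <- list(); truth <- list()
  seen_chains <- character(0)
  counter <- stats::setNames(rep(0L, length(gene_ids)), gene_ids)
  types <- names(cfg$event_mix)
  made <- 0L
  while (made < n_novel) {
    ok <- FALSE
    for (try in 1:100) {
      gid <- .sample1(gene_ids)
      type <- sample(types, 1L, prob = cfg$event_mix)
      master <- .master_of(ann, gid)
      E <- master$exons; n <- nrow(E); strand <- master$strand
      si <- si_all[gene_id == gid]
      data.table::setorder(si, intron_gidx)
      exons <- NULL
      if (type == "ES" && n >= 3L) {
        kx <- .sample1(2:(n - 1L))
        exons <- E[-kx, , drop = FALSE]
      } else if (type == "RI" && n >= 4L) {
        kx <- .sample1(2:(n - 2L))     # internal genomic intron
        exons <- E
        exons[kx, 2L] <- exons[kx + 1L, 2L]
        exons <- exons[-(kx + 1L), , drop = FALSE]
      } else if (type %in% c("A5", "A3")) {
        kx <- .sample1(seq_len(n - 1L))
        r <- si[intron_gidx == kx]
        nd <- if (type == "A5") c(r$alt5_d, r$alt5_a) else c(r$alt3_d, r$alt3_a)
        exons <- E
        exons[kx, 2L] <- nd[1L]
        exons[kx + 1L, 1L] <- nd[2L]
      } else if (type == "AF") {
        ## replace the biological first exon with the cryptic exon of the
        ## biological first intron
        if (strand == "+") {
          r <- si[intron_gidx == 1L]
          exons <- rbind(c(r$ce_start, r$ce_end), E[-1L, , drop = FALSE])
        } else {
          r <- si[intron_gidx == n - 1L]
          exons <- rbind(E[-n, , drop = FALSE], c(r$ce_start, r$ce_end))
        }
      } else if (type == "AL") {
        if (strand == "+") {
          r <- si[intron_gidx == n - 1L]
          exons <- rbind(E[-n, , drop = FALSE], c(r$ce_start, r$ce_end))
        } else {
          r <- si[intron_gidx == 1L]
          exons <- rbind(c(r$ce_start, r$ce_end), E[-1L, , drop = FALSE])
        }
      } else if (type == "MX" && n >= 3L) {
        kx <- .sample1(2:(n - 1L))
        side <- .sample1(c(kx - 1L, kx))
        r <- si[intron_gidx == side]
        exons <- E
        exons[kx, ] <- c(r$ce_start, r$ce_end)
      } else if (type == "novel_exon") {
        kx <- .sample1(seq_len(n - 1L))
        r <- si[intron_gidx == kx]
        exons <- rbind(E[seq_len(kx), , drop = FALSE],
                       c(r$ce_start, r$ce_end),
                       E[(kx + 1L):n, , drop = FALSE])
      }
      if (is.null(exons)) next
      colnames(exons) <- c("start", "end")
      gene_txs <- gene_transcripts(ann, gid)
      verdict <- .verify_novel(exons, gene_txs, strand)
      if (verdict %in% c("duplicate", "subchain")) next
      key <- chain_key(master$chrom, strand, junction_chain(exons))
      if (key %in% seen_chains) next
      expected <- if (type %in% c("ES", "RI")) "NIC" else "NNC"
      if (verdict != expected) next
      counter[gid] <- counter[gid] + 1L
      tid <- sprintf("%s.N%d", gid, counter[gid])
      novels[[length(novels) + 1L]] <-
        transcript_model(tid, gid, master$chrom, strand, exons)
      truth[[length(truth) + 1L]] <- data.table::data.table(
        transcript_id = tid, gene_id = gid, origin = type,
        category = verdict)
      seen_chains <- c(seen_chains, key)
      ok <- TRUE
      break
    }
    if (!ok) stop("simulate_novel_isoforms: could not place a novel isoform ",
                  "after 100 retries (constraints too tight)")
    made <- made + 1L
  }
  list(novels = novels, truth = data.table::rbindlist(truth))
}

## pairwise-Hamming>=3 random barcodes (guarantees unique 1-neighbour
## correction of single substitution errors)
.make_whitelist <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  acc <- matrix(character(0), nrow = len, ncol = 0)
  out <- character(0)
  while (length(out) < n) {
    cand <- sample(bases, len, replace = TRUE)
    if (ncol(acc) == 0L || all(colSums(acc != cand) >= 3L)) {
      acc <- cbind(acc, cand)
      out <- c(out, paste(cand, collapse = ""))
    }
  }
  out
}

.random_tags <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

.cigar_of <- function(exons) {
  n <- nrow(exons)
  lens <- exons[, 2L] - exons[, 1L]
  if (n == 1L) return(paste0(lens, "M"))
  gaps <- exons[-1L, 1L] - exons[-n, 2L]
  paste0(paste0(lens[-n], "M", gaps, "N", collapse = ""), lens[n], "M")
}

#' Simulate the single-cell long-read experiment
#'
#' Generates barcoded, UMI-tagged full-length reads with polyA tails from a
#' cluster-structured expression model over the reference plus novel
#' isoforms, together with their true spliced alignments, short-read
#' junction support counts, CAGE/polyA end-support peaks, tryptic peptides
#' (plus shuffled decoys), the reference proteome, and a truth manifest.
#' All outputs are plain text and deterministic under `(cfg, seed)`.
#'
#' @param ann annotation from [simulate_reference()].
#' @param novels result of [simulate_novel_isoforms()].
#' @param cfg a [simulation_config()].
#' @param genome `DNAStringSet` from [simulate_reference()].
#' @param out_dir directory for the output files (created if needed).
#' @return list with `paths` (named file paths) and `manifest` (the truth
#'   manifest as an R list; also written as JSON).
#' @export
simulate_experiment <- function(ann, novels, cfg, genome, out_dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2000L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  iso <- c(ann$transcripts, stats::setNames(
    novels$novels, vapply(novels$novels, `[[`, "", "transcript_id")))
  n_iso <- length(iso)
  iso_ids <- names(iso)
  is_novel <- iso_ids %in% novels$truth$transcript_id
  origin <- ifelse(is_novel,
                   novels$truth$origin[match(iso_ids, novels$truth$transcript_id)],
                   "reference")
  category <- ifelse(is_novel,
                     novels$truth$category[match(iso_ids, novels$truth$transcript_id)],
                     "FSM")
  chains <- vapply(iso, function(t)
    chain_key(t$chrom, t$strand, junction_chain(t)), "")
  full_seq <- vapply(iso, function(t)
    transcript_seq(genome, t$chrom, t$strand, t$exons), "")
  spans <- t(vapply(iso, function(t)
    c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L]), c(0L, 0L)))
  strands <- vapply(iso, `[[`, "", "strand")
  chrs <- vapply(iso, `[[`, "", "chrom")
  tss <- ifelse(strands == "+", spans[, 1L], spans[, 2L])
  tes <- ifelse(strands == "+", spans[, 2L], spans[, 1L])

  ## cells and clusters
  n_cells <- cfg$n_clusters * cfg$cells_per_cluster
  whitelist <- .make_whitelist(n_cells, cfg$barcode_len)
  cluster_names <- paste0("C", seq_len(cfg$n_clusters))
  cell_cluster <- rep(cluster_names, each = cfg$cells_per_cluster)

  ## expression design
  expr_clusters <- vector("list", n_iso)
  weight <- stats::rlnorm(n_iso, 0, 0.5)
  for (i in seq_len(n_iso)) {
    expr_clusters[[i]] <- if (!is_novel[i]) cluster_names
    else if (stats::runif(1) < cfg$cluster_exclusive_prob) .sample1(cluster_names)
    else sample(cluster_names, 2L)
  }

  ## molecules
  mol_cell <- integer(0); mol_iso <- integer(0)
  for (ci in seq_len(n_cells)) {
    cl <- cell_cluster[ci]
    eligible <- which(vapply(expr_clusters, function(x) cl %in% x, TRUE))
    nr <- stats::rpois(1L, cfg$reads_per_cell)
    if (nr == 0L || !length(eligible)) next
    draw <- eligible[sample.int(length(eligible), nr, replace = TRUE,
                                prob = weight[eligible])]
    mol_cell <- c(mol_cell, rep(ci, nr))
    mol_iso <- c(mol_iso, draw)
  }
  n_mol <- length(mol_iso)
  mol_umi <- .random_tags(n_mol, cfg$umi_len)
  mol_trunc <- stats::runif(n_mol) < cfg$truncation_prob

  ## per-molecule realized structure
  full_exons <- lapply(iso, `[[`, "exons")
  full_cigar <- vapply(full_exons, .cigar_of, "")
  mol_insert <- full_seq[mol_iso]
  mol_exons <- full_exons[mol_iso]
  if (any(mol_trunc)) {
    for (m in which(mol_trunc)) {
      t <- iso[[mol_iso[m]]]
      E <- t$exons; n <- nrow(E)
      lens_g <- E[, 2L] - E[, 1L]
      lens_bio <- if (t$strand == "+") lens_g else rev(lens_g)
      j <- .sample1(2:n)
      ## keep at least 30 nt of the entry exon: shorter 3' fragments would
      ## not survive library size selection
      off <- .sample1(seq_len(max(lens_bio[j] - 30L, 1L)))
      cut <- sum(lens_bio[seq_len(j - 1L)]) + off
      mol_insert[m] <- substring(mol_insert[m], cut + 1L)
      if (t$strand == "+") {
        re <- E[j:n, , drop = FALSE]; re[1L, 1L] <- re[1L, 1L] + off
      } else {
        g <- n - j + 1L
        re <- E[seq_len(g), , drop = FALSE]; re[g, 2L] <- re[g, 2L] - off
      }
      mol_exons[[m]] <- re
    }
  }
  mol_chain <- chains[mol_iso]
  if (any(mol_trunc)) {
    mol_chain[mol_trunc] <- vapply(which(mol_trunc), function(m)
      chain_key(chrs[mol_iso[m]], strands[mol_iso[m]],
                junction_chain(mol_exons[[m]])), "")
  }

  ## PCR duplicates -> reads
  copies <- 1L + stats::rbinom(n_mol, 1L, cfg$duplicate_rate)
  ridx <- rep(seq_len(n_mol), copies)
  is_dup <- unlist(lapply(copies, function(k) c(FALSE, rep(TRUE, k - 1L))))
  n_reads <- length(ridx)
  read_id <- sprintf("read%06d", seq_len(n_reads))
  bc_true <- whitelist[mol_cell[ridx]]
  bc_obs <- bc_true
  bc_err <- stats::runif(n_reads) < cfg$barcode_error_rate
  if (any(bc_err)) {
    bases <- c("A", "C", "G", "T")
    for (r in which(bc_err)) {
      p <- .sample1(seq_len(cfg$barcode_len))
      cur <- substr(bc_obs[r], p, p)
      substr(bc_obs[r], p, p) <- .sample1(setdiff(bases, cur))
    }
  }

  ## FASTQ
  read_seq <- paste0(cfg$primer5, mol_insert[ridx],
                     strrep("A", cfg$polyA_len), mol_umi[ridx], bc_obs,
                     cfg$primer3)
  flip <- stats::runif(n_reads) < 0.5
  read_seq[flip] <- revcomp(read_seq[flip])
  names(read_seq) <- read_id
  fq_path <- file.path(out_dir, "reads.fastq")
  write_fastq(read_seq, fq_path)

  ## SAM
  sam_path <- file.path(out_dir, "alignments.sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(genome), "\tLN:",
                  BiocGenerics::width(genome)))
  mol_cigar <- full_cigar[mol_iso]
  if (any(mol_trunc))
    mol_cigar[mol_trunc] <- vapply(mol_exons[mol_trunc], .cigar_of, "")
  mol_pos <- vapply(mol_exons, function(e) e[1L, 1L] + 1L, 0L)
  flag <- ifelse(strands[mol_iso[ridx]] == "-", 16L, 0L)
  sam_lines <- paste(read_id, flag, chrs[mol_iso[ridx]], mol_pos[ridx],
                     60L, mol_cigar[ridx], "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, sam_lines), sam_path)

  ## whitelist / clusters
  wl_path <- file.path(out_dir, "whitelist.tsv")
  writeLines(whitelist, wl_path)
  cl_path <- file.path(out_dir, "clusters.tsv")
  writeLines(c("barcode\tcluster",
               paste(whitelist, cell_cluster, sep = "\t")), cl_path)

  ## junction support (unique short-read counts)
  jt <- new.env(parent = emptyenv())
  jmeta <- list()
  for (i in seq_len(n_iso)) {
    j <- junction_chain(iso[[i]])
    if (!nrow(j)) next
    keys <- paste0(chrs[i], ":", strands[i], ":", j[, 1L], "-", j[, 2L])
    for (s in seq_along(keys)) {
      if (is.null(jt[[keys[s]]])) {
        jt[[keys[s]]] <- 0L
        jmeta[[keys[s]]] <- c(chrs[i], strands[i], j[s, 1L], j[s, 2L])
      }
    }
  }
  for (m in seq_len(n_mol)) {
    e <- mol_exons[[m]]
    j <- junction_chain(e)
    if (!nrow(j)) next
    keys <- paste0(chrs[mol_iso[m]], ":", strands[mol_iso[m]], ":",
                   j[, 1L], "-", j[, 2L])
    for (s in seq_along(keys)) {
      key <- keys[s]
      if (is.null(jt[[key]])) {
        jt[[key]] <- 0L
        jmeta[[key]] <- c(chrs[mol_iso[m]], strands[mol_iso[m]],
                          j[s, 1L], j[s, 2L])
      }
      jt[[key]] <- jt[[key]] + 1L
    }
  }
  jkeys <- sort(ls(jt))
  base_n <- vapply(jkeys, function(k) jt[[k]], 0L)
  jdt <- data.table::data.table(
    chrom = vapply(jmeta[jkeys], `[`, "", 1L),
    strand = vapply(jmeta[jkeys], `[`, "", 2L),
    donor = as.integer(vapply(jmeta[jkeys], `[`, "", 3L)),
    acceptor = as.integer(vapply(jmeta[jkeys], `[`, "", 4L)),
    unique_count = stats::rpois(length(jkeys), base_n * cfg$short_read_depth))
  data.table::setorder(jdt, chrom, donor, acceptor)
  jc_path <- file.path(out_dir, "junction_counts.tsv")
  data.table::fwrite(jdt, jc_path, sep = "\t")

  ## CAGE / polyA peaks at true ends
  peak <- function(pos) cbind(pmax(pos - 10L, 0L), pos + 10L)
  cage <- unique(data.table::data.table(chrom = chrs, start = peak(tss)[, 1L],
                                        end = peak(tss)[, 2L], name = "cage",
                                        score = 0L, strand = strands))
  polya <- unique(data.table::data.table(chrom = chrs, start = peak(tes)[, 1L],
                                         end = peak(tes)[, 2L], name = "polya",
                                         score = 0L, strand = strands))
  data.table::setorder(cage, chrom, start); data.table::setorder(polya, chrom, start)
  cage_path <- file.path(out_dir, "cage_peaks.bed")
  polya_path <- file.path(out_dir, "polya_peaks.bed")
  data.table::fwrite(cage, cage_path, sep = "\t", col.names = FALSE)
  data.table::fwrite(polya, polya_path, sep = "\t", col.names = FALSE)

  ## proteome + peptides
  ref_ids <- names(ann$transcripts)
  ref_orfs <- predict_orfs(full_seq[ref_ids])
  proteome <- stats::setNames(ref_orfs$protein, ref_orfs$isoform_id)
  prot_path <- file.path(out_dir, "proteome.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteome), prot_path)
  all_orfs <- predict_orfs(full_seq)
  mol_per_iso <- tabulate(mol_iso, nbins = n_iso)
  expressed_orf <- all_orfs[all_orfs$isoform_id %in% iso_ids[mol_per_iso > 0L], ]
  peps <- character(0)
  for (i in seq_len(nrow(expressed_orf))) {
    tp <- tryptic_digest(expressed_orf$protein[i])
    if (length(tp)) peps <- c(peps, sample(tp, min(2L, length(tp))))
  }
  peps <- sort(unique(peps))
  decoys <- character(0)
  n_dec <- max(1L, round(0.2 * length(peps)))
  all_prot <- c(all_orfs$protein, proteome)
  for (i in seq_len(min(n_dec, length(peps)))) {
    for (try in 1:50) {
      d <- paste(sample(strsplit(peps[i], "")[[1L]]), collapse = "")
      if (!any(grepl(d, all_prot, fixed = TRUE)) && !(d %in% peps)) {
        decoys <- c(decoys, d)
        break
      }
    }
  }
  pep_path <- file.path(out_dir, "peptides.txt")
  writeLines(c(peps, decoys), pep_path)

  ## truth manifest
  full_mol <- data.table::data.table(
    iso = mol_iso, cell = mol_cell, umi = mol_umi)[!mol_trunc]
  full_mol <- unique(full_mol)
  cl_counts <- full_mol[, .(n = .N),
                        by = .(transcript_id = iso_ids[iso],
                               cluster = cell_cluster[cell])]
  data.table::setorder(cl_counts, transcript_id, cluster)
  iso_df <- data.table::data.table(
    transcript_id = iso_ids, gene_id = vapply(iso, `[[`, "", "gene_id"),
    origin = origin, category = category, chain = chains,
    chrom = chrs, strand = strands, tss = tss, tes = tes,
    clusters = vapply(expr_clusters, paste, "", collapse = ","),
    n_molecules = as.integer(mol_per_iso),
    n_full_length = full_mol[, .N, by = iso][
      match(seq_len(n_iso), iso), ifelse(is.na(N), 0L, N)])
  reads_df <- data.table::data.table(
    read_id = read_id, transcript_id = iso_ids[mol_iso[ridx]],
    barcode = bc_true, barcode_observed = bc_obs, umi = mol_umi[ridx],
    truncated = mol_trunc[ridx], barcode_error = bc_err, duplicate = is_dup)
  manifest <- list(
    config = unclass(cfg),
    isoforms = iso_df,
    cluster_counts = cl_counts,
    reads = reads_df,
    junctions = jdt,
    decoy_peptides = decoys)
  man_path <- file.path(out_dir, "truth_manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  list(paths = list(fastq = fq_path, sam = sam_path, whitelist = wl_path,
                    clusters = cl_path, junction_counts = jc_path,
                    cage = cage_path, polya = polya_path,
                    peptides = pep_path, proteome = prot_path,
                    manifest = man_path),
       manifest = manifest)
}

#' Run the full synthetic-experiment generator
#'
#' Convenience wrapper: reference genome/annotation, novel isoforms, and
#' the experiment, all written under `out_dir` (`genome.fasta`,
#' `annotation.gtf` plus the [simulate_experiment()] outputs).
#'
#' @param cfg a [simulation_config()].
#' @param out_dir output directory.
#' @return list with `paths`, `manifest`, `annotation`, `genome`, `novels`.
#' @export
simulate_cochlea <- function(cfg, out_dir) {
  ref <- simulate_reference(cfg)
  nov <- simulate_novel_isoforms(ref$annotation, cfg)
  ex <- simulate_experiment(ref$annotation, nov, cfg, ref$genome, out_dir)
  g_path <- file.path(out_dir, "genome.fasta")
  Biostrings::writeXStringSet(ref$genome, g_path)
  gtf_path <- file.path(out_dir, "annotation.gtf")
  write_annotation(ref$annotation, gtf_path)
  ex$paths$genome <- g_path
  ex$paths$annotation <- gtf_path
  c(ex, list(annotation = ref$annotation, genome = ref$genome, novels = nov))
}
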