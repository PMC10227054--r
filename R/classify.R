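## SQANTI-style structural classification of discovered isoforms against a
## reference annotation, plus the two artifact filters (junction motifs /
## RT-switch direct repeats) and CAGE/polyA end-support filtering.
##
## Decision order (multi-exon queries):
##   same-strand exonic overlap ->
##     FSM  : junction chain identical to a reference transcript's chain
##     ISM  : chain is a consecutive proper subchain of a reference chain
##     NIC  : all donors and acceptors annotated for the assigned gene
##     NNC  : otherwise (>=1 unannotated splice site)
##   no same-strand exonic overlap ->
##     antisense (opposite-strand exonic overlap), fusion (span overlaps
##     >=2 disjoint annotated loci), genic_intron (wholly inside one
##     intron), genic (locus overlap otherwise), intergenic.
## Gene assignment: same-strand gene with maximal exonic overlap (>=1 nt).

.exonic_overlap <- function(exons, gexons) {
  ## total overlap in nt between a query exon matrix and a gene's exon set
  tot <- 0L
  for (i in seq_len(nrow(exons))) {
    ov <- pmin(exons[i, 2L], gexons$end) - pmax(exons[i, 1L], gexons$start)
    tot <- tot + sum(pmax(ov, 0L))
  }
  tot
}

## is `sub` a consecutive subsequence of `full`? (junction string vectors)
.is_consecutive_subchain <- function(sub, full) {
  if (length(sub) >= length(full) || length(sub) == 0L) return(FALSE)
  hay <- paste0(",", paste(full, collapse = ","), ",")
  needle <- paste0(",", paste(sub, collapse = ","), ",")
  grepl(needle, hay, fixed = TRUE)
}

#' Classify one discovered isoform against the annotation
#'
#' @param chrom,strand,exons query location and exon matrix (genomic order).
#' @param ann reference `annotation`.
#' @param end_fuzz mono-exon FSM end tolerance (default 100 nt).
#' @return list with `category`, `gene_id` (`NA` when unassigned) and
#'   `evidence` (matched transcript for FSM/ISM, comma-joined novel sites
#'   for NNC, else `NA`).
#' @export
classify_isoform <- function(chrom, strand, exons, ann, end_fuzz = 100L) {
  qchrom <- chrom; qstrand <- strand
  qj <- junction_chain(exons)
  qspan <- c(exons[1L, 1L], exons[nrow(exons), 2L])
  ge <- ann$exon_dt[chrom == qchrom]
  if (!nrow(ge))
    return(list(category = "intergenic", gene_id = NA_character_,
                evidence = NA_character_))
  same <- ge[strand == qstrand]
  ## same-strand exonic overlap per gene
  ov_by_gene <- integer(0)
  if (nrow(same)) {
    ov <- vapply(split(same, same$gene_id), function(g)
      .exonic_overlap(exons, g), 0L)
    ov_by_gene <- ov[ov > 0L]
  }
  if (length(ov_by_gene)) {
    cand_genes <- names(sort(ov_by_gene, decreasing = TRUE))
    cand_tx <- unlist(lapply(cand_genes, function(g) ann$genes[[g]]),
                      use.names = FALSE)
    if (nrow(qj) > 0L) {
      qstr <- paste(qj[, 1L], qj[, 2L], sep = "-")
      for (tid in cand_tx) {
        t <- ann$transcripts[[tid]]
        tj <- junction_chain(t)
        tstr <- paste(tj[, 1L], tj[, 2L], sep = "-")
        if (length(tstr) == length(qstr) && all(tstr == qstr))
          return(list(category = "FSM", gene_id = t$gene_id, evidence = tid))
      }
      for (tid in cand_tx) {
        t <- ann$transcripts[[tid]]
        tj <- junction_chain(t)
        tstr <- paste(tj[, 1L], tj[, 2L], sep = "-")
        if (.is_consecutive_subchain(qstr, tstr))
          return(list(category = "ISM", gene_id = t$gene_id, evidence = tid))
      }
      gene_id <- cand_genes[1L]
      cat_sites <- site_catalog(gene_transcripts(ann, gene_id))
      if (strand == "+") {
        q_don <- qj[, 1L]; q_acc <- qj[, 2L]
      } else {
        q_don <- qj[, 2L]; q_acc <- qj[, 1L]
      }
      novel <- c(setdiff(q_don, cat_sites$donors),
                 setdiff(q_acc, cat_sites$acceptors))
      if (length(novel) == 0L)
        return(list(category = "NIC", gene_id = gene_id,
                    evidence = NA_character_))
      return(list(category = "NNC", gene_id = gene_id,
                  evidence = paste(sort(novel), collapse = ",")))
    }
    ## mono-exon with same-strand exonic overlap
    for (g in cand_genes) {
      for (tid in ann$genes[[g]]) {
        t <- ann$transcripts[[tid]]
        if (nrow(t$exons) == 1L &&
            abs(t$exons[1L, 1L] - qspan[1L]) <= end_fuzz &&
            abs(t$exons[1L, 2L] - qspan[2L]) <= end_fuzz)
          return(list(category = "FSM", gene_id = g, evidence = tid))
      }
    }
    cont <- same[gene_id %in% cand_genes &
                   start <= qspan[1L] & end >= qspan[2L]]
    if (nrow(cont))
      return(list(category = "ISM", gene_id = cont$gene_id[1L],
                  evidence = cont$transcript_id[1L]))
    return(list(category = "genic", gene_id = cand_genes[1L],
                evidence = NA_character_))
  }
  ## no same-strand exonic overlap
  anti <- ge[strand != qstrand]
  if (nrow(anti)) {
    ov <- .exonic_overlap(exons, anti)
    if (ov > 0L) {
      gg <- vapply(split(anti, anti$gene_id), function(g)
        .exonic_overlap(exons, g), 0L)
      return(list(category = "antisense",
                  gene_id = names(which.max(gg)), evidence = NA_character_))
    }
  }
  gl <- ann$gene_dt[chrom == qchrom & start < qspan[2L] & end > qspan[1L]]
  if (nrow(gl) >= 2L) {
    ## fusion: span covers >=2 disjoint annotated loci
    o <- order(gl$start)
    disjoint <- 1L
    reach <- gl$end[o[1L]]
    for (k in o[-1L]) {
      if (gl$start[k] >= reach) disjoint <- disjoint + 1L
      reach <- max(reach, gl$end[k])
    }
    if (disjoint >= 2L)
      return(list(category = "fusion", gene_id = NA_character_,
                  evidence = paste(sort(gl$gene_id), collapse = ",")))
  }
  if (nrow(gl)) {
    for (gid in gl$gene_id) {
      for (tid in ann$genes[[gid]]) {
        t <- ann$transcripts[[tid]]
        tj <- junction_chain(t)
        if (nrow(tj) &&
            any(tj[, 1L] <= qspan[1L] & qspan[2L] <= tj[, 2L]))
          return(list(category = "genic_intron", gene_id = gid,
                      evidence = NA_character_))
      }
    }
    return(list(category = "genic", gene_id = gl$gene_id[1L],
                evidence = NA_character_))
  }
  list(category = "intergenic", gene_id = NA_character_,
       evidence = NA_character_)
}

#' Classify a table of isoforms
#'
#' @param isoforms `data.table` from [collapse_chains()]`$isoforms` (needs
#'   `isoform_id`, `chrom`, `strand` and the `exons` list-column).
#' @param ann reference `annotation`.
#' @param end_fuzz mono-exon FSM end tolerance.
#' @return the input with `category`, `gene_id`, `evidence` columns added.
#' @export
classify_isoforms <- function(isoforms, ann, end_fuzz = 100L) {
  res <- lapply(seq_len(nrow(isoforms)), function(i)
    classify_isoform(isoforms$chrom[i], isoforms$strand[i],
                     isoforms$exons[[i]], ann, end_fuzz = end_fuzz))
  out <- data.table::copy(data.table::as.data.table(isoforms))
  out$category <- vapply(res, `[[`, "", "category")
  out$gene_id <- vapply(res, function(r) r$gene_id %||% NA_character_, "")
  out$evidence <- vapply(res, function(r) r$evidence %||% NA_character_, "")
  out
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Junction artifact checks: splice motifs and RT-switch repeats
#'
#' For every query junction absent from the gene's annotated junction set,
#' reads the intron-boundary dinucleotides on the transcribed strand
#' (canonical motifs: GT-AG, GC-AG, AT-AC) and tests for a direct repeat of
#' `repeat_k` nt ending at the donor (exonic side) and at the acceptor's
#' intronic boundary -- the classic reverse-transcription template-switch
#' signature.
#'
#' @param chrom,strand,exons query isoform.
#' @param genome `DNAStringSet`.
#' @param known_junctions character set `"donor-acceptor"` (genomic
#'   left-right) of the assigned gene's annotated junctions; junctions in
#'   this set are exempt.
#' @param canonical character vector of accepted motifs (transcribed
#'   strand, donor+acceptor dinucleotides).
#' @param repeat_k direct-repeat length for the RT-switch test (default 8).
#' @return list with logical `noncanonical_novel_junction` and `rt_switch`.
#' @export
junction_artifact_check <- function(chrom, strand, exons, genome,
                                    known_junctions = character(0),
                                    canonical = c("GTAG", "GCAG", "ATAC"),
                                    repeat_k = 8L) {
  qj <- junction_chain(exons)
  if (!nrow(qj))
    return(list(noncanonical_novel_junction = FALSE, rt_switch = FALSE))
  if (!chrom %in% names(genome)) stop("unknown chrom: ", chrom)
  chr <- as.character(genome[[chrom]])
  clen <- nchar(chr)
  noncanon <- FALSE; rts <- FALSE
  for (i in seq_len(nrow(qj))) {
    d <- qj[i, 1L]; a <- qj[i, 2L]
    if (paste0(d, "-", a) %in% known_junctions) next
    if (d < repeat_k || a + repeat_k > clen)
      stop("junction ", d, "-", a, " too close to the contig edge")
    if (strand == "+") {
      motif <- paste0(substr(chr, d + 1L, d + 2L), substr(chr, a - 1L, a))
      kd <- substr(chr, d - repeat_k + 1L, d)        # exonic, ends at donor
      ka <- substr(chr, a - repeat_k + 1L, a)        # intronic, ends at acceptor
    } else {
      motif <- paste0(revcomp(substr(chr, a - 1L, a)),
                      revcomp(substr(chr, d + 1L, d + 2L)))
      kd <- substr(chr, a + 1L, a + repeat_k)        # exonic side (biological donor)
      ka <- substr(chr, d + 1L, d + repeat_k)        # intronic boundary
    }
    if (!motif %in% canonical) noncanon <- TRUE
    if (kd == ka) rts <- TRUE
  }
  list(noncanonical_novel_junction = noncanon, rt_switch = rts)
}

#' Read a BED file of peaks
#' @param path BED path (>= 6 columns expected when stranded).
#' @return `data.table` with `chrom`, `start`, `end`, `strand`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  out <- data.table::data.table(chrom = dt$V1, start = dt$V2, end = dt$V3)
  out$strand <- if (ncol(dt) >= 6L) dt$V6 else "*"
  out
}

## strand-aware distance from a position to the nearest peak; Inf when none
.peak_dist <- function(chrom, strand, pos, peaks) {
  p <- peaks[peaks$chrom == chrom & (peaks$strand == "*" | peaks$strand == strand), ]
  if (!nrow(p)) return(Inf)
  min(.point_interval_dist(pos, p$start, p$end))
}

#' End-support filter against CAGE and polyA peak tracks
#'
#' An isoform's TSS is supported when it lies within `window` nt (boundary
#' inclusive) of a CAGE peak, and its TES when within `window` nt of a
#' polyA peak. Isoforms in `categories_filtered` are retained only when
#' both ends are supported and no junction-artifact flag is set; other
#' categories pass unconditionally.
#'
#' @param classified `data.table` with `isoform_id`, `chrom`, `strand`,
#'   `tss`, `tes`, `category`, and logical columns
#'   `noncanonical_novel_junction`, `rt_switch`.
#' @param cage,polya peak tables from [read_bed()].
#' @param window distance threshold in nt (default 50, inclusive).
#' @param categories_filtered categories subject to the filter.
#' @return the input with `cage_supported`, `polya_supported`, `retained`
#'   columns added.
#' @export
end_support_filter <- function(classified, cage, polya, window = 50L,
                               categories_filtered = c("ISM", "NIC", "NNC")) {
  out <- data.table::copy(data.table::as.data.table(classified))
  n <- nrow(out)
  cs <- logical(n); ps <- logical(n)
  for (i in seq_len(n)) {
    cs[i] <- .peak_dist(out$chrom[i], out$strand[i], out$tss[i], cage) <= window
    ps[i] <- .peak_dist(out$chrom[i], out$strand[i], out$tes[i], polya) <= window
  }
  out$cage_supported <- cs
  out$polya_supported <- ps
  artifact <- out$noncanonical_novel_junction | out$rt_switch
  out$retained <- !(out$category %in% categories_filtered) |
    (cs & ps & !artifact)
  out
}
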