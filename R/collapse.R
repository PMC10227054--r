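## Spliced alignments -> exon chains -> collapsed unique isoforms with
## PB-style per-locus identifiers.

#' Read a SAM file (mandatory columns)
#'
#' @param path SAM path (text; headers skipped).
#' @return `data.table` with `qname`, `flag`, `rname`, `pos` (1-based),
#'   `mapq`, `cigar`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table::data.table(qname = character(0), flag = integer(0),
                                  rname = character(0), pos = integer(0),
                                  mapq = integer(0), cigar = character(0)))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
  data.table::data.table(qname = f[[1]], flag = as.integer(f[[2]]),
                         rname = f[[3]], pos = as.integer(f[[4]]),
                         mapq = as.integer(f[[5]]), cigar = f[[6]])
}

#' Exon chains from spliced SAM records
#'
#' M/=/X/D advance the reference within an exon; N closes an exon and opens
#' the next. Unmapped records and records below the mapping-quality
#' threshold are rejected with a reason.
#'
#' @param sam `data.table` from [read_sam()].
#' @param min_mapq minimum mapping quality (default 20).
#' @return list with `chains` (`data.table`: `read_id`, `chrom`, `strand`,
#'   `start`, `end`, `chain` ([chain_key()] string), `n_exons`, plus an
#'   `exons` list-column of exon matrices) and `rejects` (`read_id`,
#'   `reason`).
#' @export
chain_from_alignment <- function(sam, min_mapq = 20L) {
  unmapped <- bitwAnd(sam$flag, 4L) != 0L | sam$rname == "*"
  lowq <- !unmapped & sam$mapq < min_mapq
  bad_op <- !unmapped & grepl("[^0-9MIDNSHP=X]", sam$cigar)
  if (any(bad_op))
    stop("unsupported CIGAR opcode for read ", sam$qname[which(bad_op)[1L]])
  keep <- !unmapped & !lowq
  rejects <- data.table::data.table(
    read_id = sam$qname[!keep],
    reason = ifelse(unmapped[!keep], "unmapped", "low-mapq"))
  s <- sam[keep]
  if (!nrow(s)) {
    return(list(chains = data.table::data.table(
      read_id = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), chain = character(0),
      n_exons = integer(0), exons = list()), rejects = rejects))
  }
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    s$cigar, pos = s$pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  strand <- ifelse(bitwAnd(s$flag, 16L) != 0L, "-", "+")
  exons_list <- lapply(seq_len(nrow(s)), function(i) {
    r <- rr[[i]]
    cbind(start = BiocGenerics::start(r) - 1L, end = BiocGenerics::end(r))
  })
  chains <- data.table::data.table(
    read_id = s$qname, chrom = s$rname, strand = strand,
    start = vapply(exons_list, function(e) e[1L, 1L], 0L),
    end = vapply(exons_list, function(e) e[nrow(e), 2L], 0L),
    chain = vapply(seq_len(nrow(s)), function(i)
      chain_key(s$rname[i], strand[i], junction_chain(exons_list[[i]])), ""),
    n_exons = vapply(exons_list, nrow, 0L))
  chains$exons <- exons_list
  list(chains = chains, rejects = rejects)
}

## union-find for mono-exon merging
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse aligned chains into unique isoforms
#'
#' Multi-exon chains merge on exact junction-chain identity; the
#' representative TSS is the 5'-most start and the TES the 3'-most end among
#' members (by strand). Mono-exon chains merge when they overlap and both
#' end differences are within `end_fuzz`. Loci are connected components of
#' genomic overlap on one strand, numbered in genomic order; isoforms within
#' a locus are numbered by descending read support, then coordinate.
#'
#' @param chains `data.table` from [chain_from_alignment()]`$chains`.
#' @param end_fuzz mono-exon end tolerance (default 100 nt).
#' @return list with `isoforms` (`data.table`: `isoform_id`, `chrom`,
#'   `strand`, `start`, `end`, `tss`, `tes`, `chain`, `n_exons`,
#'   `n_reads`, `exons` list-column) and `read_map` (`read_id`,
#'   `isoform_id`).
#' @export
collapse_chains <- function(chains, end_fuzz = 100L) {
  dt <- data.table::as.data.table(chains)
  if (!nrow(dt)) {
    return(list(isoforms = data.table::data.table(
      isoform_id = character(0), chrom = character(0), strand = character(0),
      start = integer(0), end = integer(0), tss = integer(0), tes = integer(0),
      chain = character(0), n_exons = integer(0), n_reads = integer(0),
      exons = list()),
      read_map = data.table::data.table(read_id = character(0),
                                        isoform_id = character(0))))
  }
  dt$group <- NA_integer_
  next_grp <- 0L
  ## multi-exon: group by exact chain key
  multi <- which(dt$n_exons > 1L)
  if (length(multi)) {
    g <- match(dt$chain[multi], unique(dt$chain[multi]))
    dt$group[multi] <- g
    next_grp <- max(g)
  }
  ## mono-exon: union-find within chrom/strand
  mono <- which(dt$n_exons == 1L)
  if (length(mono)) {
    md <- dt[mono, .(idx = mono, chrom, strand, start, end)]
    data.table::setorder(md, chrom, strand, start, end)
    parent <- seq_len(nrow(md))
    for (i in seq_len(nrow(md) - 1L)) {
      j <- i + 1L
      while (j <= nrow(md) && md$chrom[j] == md$chrom[i] &&
             md$strand[j] == md$strand[i] && md$start[j] < md$end[i]) {
        if (abs(md$start[j] - md$start[i]) <= end_fuzz &&
            abs(md$end[j] - md$end[i]) <= end_fuzz) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        j <- j + 1L
      }
    }
    roots <- vapply(seq_len(nrow(md)), function(i) .uf_find(parent, i), 0L)
    dt$group[md$idx] <- next_grp + match(roots, unique(roots))
  }
  iso <- dt[, .(chrom = chrom[1L], strand = strand[1L],
                start = min(start), end = max(end),
                chain = chain[1L], n_exons = n_exons[1L], n_reads = .N,
                read_ids = list(read_id)),
            by = group]
  iso[, tss := data.table::fifelse(strand == "+", start, end)]
  iso[, tes := data.table::fifelse(strand == "+", end, start)]
  ## representative exon structure: span + junctions
  iso$exons <- lapply(seq_len(nrow(iso)), function(i) {
    j <- .parse_chain_key(iso$chain[i])$junctions
    exons_from_chain(c(iso$start[i], iso$end[i]), j)
  })
  ## loci: connected components of span overlap per chrom/strand
  data.table::setorder(iso, chrom, strand, start, end)
  iso[, locus_local := {
    n <- .N
    comp <- integer(n); cur <- 0L; reach <- -1L
    for (i in seq_len(n)) {
      if (start[i] >= reach) { cur <- cur + 1L; reach <- end[i] }
      else reach <- max(reach, end[i])
      comp[i] <- cur
    }
    comp
  }, by = .(chrom, strand)]
  loci <- unique(iso[, .(chrom, strand, locus_local)])
  lstart <- iso[, .(ls = min(start)), by = .(chrom, strand, locus_local)]
  loci <- merge(loci, lstart, by = c("chrom", "strand", "locus_local"))
  data.table::setorder(loci, chrom, ls, strand)
  loci[, locus := .I]
  iso <- merge(iso, loci[, .(chrom, strand, locus_local, locus)],
               by = c("chrom", "strand", "locus_local"), sort = FALSE)
  data.table::setorder(iso, locus, -n_reads, start, end, chain)
  iso[, idx := seq_len(.N), by = locus]
  iso[, isoform_id := sprintf("PB.%d.%d", locus, idx)]
  read_map <- iso[, .(read_id = unlist(read_ids)), by = isoform_id]
  iso[, c("group", "locus_local", "idx", "read_ids") := NULL]
  data.table::setcolorder(iso, c("isoform_id", "chrom", "strand", "start",
                                 "end", "tss", "tes", "chain", "n_exons",
                                 "n_reads"))
  list(isoforms = iso[], read_map = read_map)
}
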