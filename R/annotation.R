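## Transcript/gene data model, junction-chain algebra, GTF + FASTA I/O.
##
## Conventions used throughout the package:
##  * genomic intervals are 0-based half-open [start, end), strand "+"/"-";
##  * exon lists are kept in genomic order regardless of strand (biological
##    order is derived on demand);
##  * a junction is the pair (donor_pos, acceptor_pos) in genomic
##    coordinates: donor_pos = end of the genomic-upstream exon,
##    acceptor_pos = start of the genomic-downstream exon. The *biological*
##    donor (5' splice site) of a minus-strand junction is acceptor_pos.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (start, end), 0-based half-open.
#'   Rows may be given in any order; they are sorted into genomic order.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  stopifnot(.is_scalar_string(transcript_id), .is_scalar_string(gene_id),
            .is_scalar_string(chrom), strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript ", transcript_id, ": no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 1L] < 0L) || any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", transcript_id, ": invalid exon interval")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript ", transcript_id, ": overlapping exons")
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons),
            class = "transcript_model")
}

#' Junction chain of a transcript
#'
#' Returns the ordered (genomic) list of splice junctions. A mono-exonic
#' transcript yields a zero-row matrix.
#'
#' @param t a `transcript_model`, or a two-column exon matrix.
#' @return integer matrix with columns `donor` (upstream exon end) and
#'   `acceptor` (downstream exon start), genomic coordinates.
#' @export
junction_chain <- function(t) {
  exons <- if (inherits(t, "transcript_model")) t$exons else t
  n <- nrow(exons)
  if (n < 2L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = exons[-n, 2L], acceptor = exons[-1L, 1L])
}

#' String key identifying a junction chain
#'
#' `"chrom:strand:d1-a1,d2-a2,..."`; used as the exact-identity merge key in
#' collapse and classification. Mono-exon chains yield `"chrom:strand:"`.
#'
#' @param chrom,strand location.
#' @param junctions two-column matrix as from [junction_chain()].
#' @return character scalar.
#' @export
chain_key <- function(chrom, strand, junctions) {
  paste0(chrom, ":", strand, ":",
         paste(junctions[, 1L], junctions[, 2L], sep = "-", collapse = ","))
}

## parse a chain_key back to its parts
.parse_chain_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)[[1]]
  jstr <- if (length(parts) >= 3L) parts[3L] else ""
  if (identical(jstr, "") || is.na(jstr)) {
    j <- matrix(integer(0), ncol = 2L)
  } else {
    pr <- strsplit(strsplit(jstr, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
    j <- matrix(as.integer(unlist(pr)), ncol = 2L, byrow = TRUE)
  }
  colnames(j) <- c("donor", "acceptor")
  list(chrom = parts[1L], strand = parts[2L], junctions = j)
}

#' Reconstruct an exon matrix from a span and a junction chain
#'
#' Inverse of [junction_chain()] given the transcript's genomic span.
#'
#' @param span integer length-2 (start, end) of the transcript span.
#' @param junctions matrix as from [junction_chain()].
#' @return two-column exon matrix in genomic order.
#' @export
exons_from_chain <- function(span, junctions) {
  starts <- c(span[1L], junctions[, 2L])
  ends <- c(junctions[, 1L], span[2L])
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Donor/acceptor/junction catalog of a gene
#'
#' Sites are labelled biologically: a donor is the 5' splice site on the
#' transcribed strand (for a minus-strand gene this is the genomic *right*
#' edge of the intron).
#'
#' @param transcripts list of `transcript_model`s belonging to one gene.
#' @return list with `donors`, `acceptors` (integer sets) and `junctions`
#'   (character set `"d-a"` in genomic left-right order).
#' @export
site_catalog <- function(transcripts) {
  stopifnot(length(transcripts) >= 1L)
  strand <- transcripts[[1L]]$strand
  dn <- integer(0); ac <- integer(0); jn <- character(0)
  for (t in transcripts) {
    j <- junction_chain(t)
    if (nrow(j)) {
      if (strand == "+") {
        dn <- c(dn, j[, 1L]); ac <- c(ac, j[, 2L])
      } else {
        dn <- c(dn, j[, 2L]); ac <- c(ac, j[, 1L])
      }
      jn <- c(jn, paste(j[, 1L], j[, 2L], sep = "-"))
    }
  }
  list(donors = sort(unique(dn)), acceptors = sort(unique(ac)),
       junctions = sort(unique(jn)))
}

#' Assemble an annotation object from transcript models
#'
#' @param transcripts list of `transcript_model`s.
#' @param source tag recorded on the object (e.g. `"reference"`).
#' @return object of class `annotation`: named transcript list, per-gene
#'   index, and a flat exon `data.table`.
#' @export
annotation <- function(transcripts, source = "reference") {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript_id in annotation")
  names(transcripts) <- ids
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- lapply(split(ids, gene_ids), function(tx) unname(tx))
  exon_dt <- data.table::rbindlist(lapply(transcripts, function(t) {
    data.table::data.table(chrom = t$chrom, start = t$exons[, 1L],
                           end = t$exons[, 2L], strand = t$strand,
                           gene_id = t$gene_id, transcript_id = t$transcript_id)
  }))
  gene_dt <- exon_dt[, .(chrom = chrom[1L], strand = strand[1L],
                         start = min(start), end = max(end)),
                     by = gene_id]
  structure(list(transcripts = transcripts, genes = genes,
                 gene_dt = gene_dt, exon_dt = exon_dt, source = source),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("<annotation '%s': %d genes, %d transcripts>\n",
              x$source, length(x$genes), length(x$transcripts)))
  invisible(x)
}

#' Transcripts of one gene
#' @param ann an `annotation`.
#' @param gene_id gene identifier.
#' @return list of `transcript_model`s.
#' @export
gene_transcripts <- function(ann, gene_id) {
  ids <- ann$genes[[gene_id]]
  if (is.null(ids)) stop("unknown gene_id: ", gene_id)
  ann$transcripts[ids]
}

## ---- GTF I/O --------------------------------------------------------------

.gtf_attr <- function(attr, key, lineno) {
  m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))[[1]]
  if (length(m) < 2L)
    stop("GTF parse error at line ", lineno, ": missing attribute '", key, "'")
  m[2L]
}

#' Read a GTF annotation
#'
#' Accepts any GTF whose exon features carry `gene_id` and `transcript_id`
#' attributes. 1-based inclusive GTF coordinates are converted to the
#' package's 0-based half-open convention. Transcripts with overlapping
#' exons are rejected (dropped with a warning naming them).
#'
#' @param gtf_path path to a GTF file.
#' @param source tag stored on the returned annotation.
#' @return an `annotation` object.
#' @export
read_annotation <- function(gtf_path, source = "reference") {
  lines <- readLines(gtf_path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9L)
  if (length(bad))
    stop("GTF parse error at line ", lineno[bad[1L]], ": expected 9 tab-separated fields")
  feat <- vapply(fields, `[[`, "", 3L)
  ex <- which(feat == "exon")
  if (!length(ex)) stop("no exon features in ", gtf_path)
  recs <- data.table::data.table(
    chrom = vapply(fields[ex], `[[`, "", 1L),
    start = as.integer(vapply(fields[ex], `[[`, "", 4L)) - 1L,
    end = as.integer(vapply(fields[ex], `[[`, "", 5L)),
    strand = vapply(fields[ex], `[[`, "", 7L),
    gene_id = mapply(function(f, ln) .gtf_attr(f[[9L]], "gene_id", ln),
                     fields[ex], lineno[ex]),
    transcript_id = mapply(function(f, ln) .gtf_attr(f[[9L]], "transcript_id", ln),
                           fields[ex], lineno[ex]))
  txs <- list(); dropped <- character(0)
  for (tid in unique(recs$transcript_id)) {
    r <- recs[recs$transcript_id == tid, ]
    t <- tryCatch(
      transcript_model(tid, r$gene_id[1L], r$chrom[1L], r$strand[1L],
                       cbind(r$start, r$end)),
      error = function(e) e)
    if (inherits(t, "error")) dropped <- c(dropped, tid) else txs[[tid]] <- t
  }
  if (length(dropped))
    warning("rejected transcripts with invalid exon structure: ",
            paste(dropped, collapse = ", "))
  annotation(unname(txs), source = source)
}

#' Write an annotation as GTF
#'
#' Emits transcript and exon features with a deterministic attribute order
#' (`gene_id`, then `transcript_id`), sorted by chromosome, gene span and
#' transcript id, so that read -> write -> read round-trips exactly.
#'
#' @param ann an `annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  dt <- data.table::copy(ann$exon_dt)
  gd <- ann$gene_dt[, .(gene_id, gstart = start)]
  dt <- merge(dt, gd, by = "gene_id", sort = FALSE)
  data.table::setorder(dt, chrom, gstart, gene_id, transcript_id, start)
  lines <- character(0)
  for (tid in unique(dt$transcript_id)) {
    r <- dt[dt$transcript_id == tid, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', r$gene_id[1L], tid)
    lines <- c(lines,
               paste(r$chrom[1L], "scisokit", "transcript", min(r$start) + 1L,
                     max(r$end), ".", r$strand[1L], ".", attrs, sep = "\t"),
               paste(r$chrom, "scisokit", "exon", r$start + 1L, r$end, ".",
                     r$strand, ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

## ---- genome / sequences ---------------------------------------------------

#' Read a genome FASTA
#' @param fasta_path path to a FASTA file.
#' @return a named `DNAStringSet`.
#' @export
read_genome <- function(fasta_path) {
  g <- Biostrings::readDNAStringSet(fasta_path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences in genomic order and reverse-complements for
#' minus-strand transcripts, yielding the 5'->3' mature sequence.
#'
#' @param genome a `DNAStringSet` (see [read_genome()]).
#' @param chrom,strand location.
#' @param exons two-column exon matrix, genomic order.
#' @return character scalar.
#' @export
transcript_seq <- function(genome, chrom, strand, exons) {
  if (!chrom %in% names(genome)) stop("unknown chrom: ", chrom)
  chr <- genome[[chrom]]
  parts <- Biostrings::DNAStringSet(Biostrings::Views(
    chr, start = exons[, 1L] + 1L, end = exons[, 2L]))
  s <- Biostrings::DNAStringSet(unlist(parts))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s[[1L]])
}
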