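## FLNC extraction from raw long reads: primer location, orientation,
## polyA measurement, barcode/UMI extraction, whitelist correction and UMI
## deduplication.
##
## Read anatomy (as-sequenced or reverse-complemented):
##   5'primer | insert | polyA(>= min) | UMI(12) | barcode(16) | 3'primer
## Primer search is exact-match first, then Hamming (<= `max_mismatch`)
## via a sliding pattern match for the few reads that fail exact search.

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write a FASTQ file (constant qualities)
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  s <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

## first occurrence (1-based) of `pattern` in each of `seqs`, allowing up to
## `max_mm` mismatches; -1 when absent. Exact fast path, fuzzy fallback.
.find_primer <- function(seqs, pattern, max_mm) {
  pos <- as.integer(regexpr(pattern, seqs, fixed = TRUE))
  if (max_mm > 0L && any(pos < 0L)) {
    miss <- which(pos < 0L)
    hits <- Biostrings::vmatchPattern(pattern,
                                      Biostrings::DNAStringSet(seqs[miss]),
                                      max.mismatch = max_mm)
    st <- vapply(hits, function(h) if (length(h)) BiocGenerics::start(h)[1L] else -1L, 0L)
    pos[miss] <- as.integer(st)
  }
  pos
}

#' Correct observed cell barcodes against a whitelist
#'
#' Exact hits return themselves; otherwise a unique Hamming-distance-1
#' whitelist neighbour is accepted; anything else is unmatched or ambiguous.
#'
#' @param observed character vector of observed barcode sequences.
#' @param whitelist character vector of true barcodes (unique, equal length).
#' @return `data.table` with `observed`, `barcode` (corrected or `NA`) and
#'   `status` in `{exact, corrected, unmatched, ambiguous}`.
#' @export
correct_barcode <- function(observed, whitelist) {
  stopifnot(length(whitelist) >= 1L, !anyDuplicated(whitelist))
  bc_len <- nchar(whitelist[1L])
  stopifnot(all(nchar(whitelist) == bc_len))
  out <- data.table::data.table(observed = observed,
                                barcode = NA_character_,
                                status = "unmatched")
  exact <- !is.na(observed) & observed %in% whitelist
  out[exact, `:=`(barcode = observed, status = "exact")]
  todo <- which(!exact & !is.na(observed) & nchar(observed) == bc_len)
  if (length(todo)) {
    bases <- c("A", "C", "G", "T")
    for (i in todo) {
      obs <- out$observed[i]
      vars <- character(0)
      for (p in seq_len(bc_len)) {
        cur <- substr(obs, p, p)
        for (b in bases[bases != cur]) {
          v <- obs
          substr(v, p, p) <- b
          vars <- c(vars, v)
        }
      }
      hits <- unique(vars[vars %in% whitelist])
      if (length(hits) == 1L) {
        data.table::set(out, i, "barcode", hits)
        data.table::set(out, i, "status", "corrected")
      } else if (length(hits) > 1L) {
        data.table::set(out, i, "status", "ambiguous")
      }
    }
  }
  out
}

#' Extract FLNC records from raw reads
#'
#' Locates both primers in either orientation, requires a polyA run of at
#' least `min_polyA` nt adjacent to the UMI/barcode block, and corrects the
#' barcode against the whitelist. Reads failing any step are rejected with
#' a reason in `{no-5'-primer, no-3'-primer, no-polyA, barcode-unmatched,
#' barcode-ambiguous, empty-insert}`.
#'
#' @param seqs named character vector of read sequences (see [read_fastq()]).
#' @param primer5,primer3 primer sequences as they appear on the sequenced
#'   strand in the canonical orientation.
#' @param whitelist character vector of cell barcodes.
#' @param min_polyA minimum polyA run (default 20 nt, boundary inclusive).
#' @param bc_len,umi_len barcode and UMI lengths (defaults 16 and 12 nt).
#' @param max_mismatch mismatches tolerated in fuzzy primer search.
#' @return list with `flnc` (`data.table`: `read_id`, `barcode`, `umi`,
#'   `orientation`, `polyA_len`, `insert`) and `rejects` (`data.table`:
#'   `read_id`, `reason`).
#' @export
extract_flnc <- function(seqs, primer5, primer3, whitelist,
                         min_polyA = 20L, bc_len = 16L, umi_len = 12L,
                         max_mismatch = 2L) {
  n <- length(seqs)
  read_id <- names(seqs)
  if (is.null(read_id)) read_id <- as.character(seq_len(n))
  reason <- rep(NA_character_, n)
  orientation <- rep("as-sequenced", n)

  p5_fwd <- .find_primer(seqs, primer5, max_mismatch)
  rc <- revcomp(seqs)
  p5_rev <- .find_primer(rc, primer5, max_mismatch)
  use_rev <- p5_fwd < 0L & p5_rev > 0L
  oriented <- ifelse(use_rev, rc, seqs)
  orientation[use_rev] <- "reverse-complemented"
  p5 <- ifelse(use_rev, p5_rev, p5_fwd)
  reason[p5 < 0L] <- "no-5'-primer"

  p3 <- rep(-1L, n)
  ok <- is.na(reason)
  p3[ok] <- .find_primer(oriented[ok], primer3, max_mismatch)
  bad3 <- ok & (p3 < 0L | p3 <= p5 + nchar(primer5) + bc_len + umi_len)
  reason[bad3] <- "no-3'-primer"

  barcode_obs <- umi <- insert <- rep(NA_character_, n)
  polyA_len <- rep(NA_integer_, n)
  ok <- is.na(reason)
  if (any(ok)) {
    bc_start <- p3 - bc_len
    barcode_obs[ok] <- substr(oriented[ok], bc_start[ok], p3[ok] - 1L)
    umi[ok] <- substr(oriented[ok], bc_start[ok] - umi_len, bc_start[ok] - 1L)
    seg <- substr(oriented, p5 + nchar(primer5), bc_start - umi_len - 1L)
    tail_a <- regexpr("A*$", seg[ok])
    pa <- nchar(seg[ok]) - as.integer(tail_a) + 1L
    polyA_len[ok] <- pa
    insert[ok] <- substr(seg[ok], 1L, nchar(seg[ok]) - pa)
    short <- which(ok)[pa < min_polyA]
    reason[short] <- "no-polyA"
  }
  ok <- is.na(reason)
  empty <- ok & (is.na(insert) | insert == "")
  reason[empty] <- "empty-insert"
  ok <- is.na(reason)

  barcode <- rep(NA_character_, n)
  if (any(ok)) {
    corr <- correct_barcode(barcode_obs[ok], whitelist)
    barcode[ok] <- corr$barcode
    reason[which(ok)[corr$status == "unmatched"]] <- "barcode-unmatched"
    reason[which(ok)[corr$status == "ambiguous"]] <- "barcode-ambiguous"
  }
  ok <- is.na(reason)

  list(flnc = data.table::data.table(
         read_id = read_id[ok], barcode = barcode[ok], umi = umi[ok],
         orientation = orientation[ok], polyA_len = polyA_len[ok],
         insert = insert[ok]),
       rejects = data.table::data.table(
         read_id = read_id[!ok], reason = reason[!ok]))
}

#' Deduplicate FLNC records by (barcode, UMI, junction chain)
#'
#' Records sharing the triple collapse to one representative: the longest
#' insert, ties broken by lexicographically smallest `read_id`.
#'
#' @param records `data.table` with at least `read_id`, `barcode`, `umi`,
#'   `chain` (a [chain_key()] string) and `insert` columns.
#' @return the surviving records with an added `n_dups` column (group size).
#' @export
dedup_umis <- function(records) {
  stopifnot(all(c("read_id", "barcode", "umi", "chain", "insert") %in%
                  names(records)))
  dt <- data.table::copy(data.table::as.data.table(records))
  dt[, `:=`(.ilen = nchar(insert))]
  data.table::setorder(dt, barcode, umi, chain, -.ilen, read_id)
  dt[, .n := .N, by = .(barcode, umi, chain)]
  out <- dt[!duplicated(dt[, .(barcode, umi, chain)])]
  out[, n_dups := .n]
  out[, c(".ilen", ".n") := NULL]
  out[]
}
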