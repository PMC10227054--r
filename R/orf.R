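## ORF prediction, CDS grouping, ORF typing and peptide support.
##
## The ORF caller is deliberately deterministic: the longest ATG-initiated
## open reading frame that terminates at an in-frame stop codon *within* the
## sequence, ties broken 5'-most, rejected below `min_codons` (default 100
## codons counting the initiator Met, stop excluded).

#' Predict the ORF of a mature transcript sequence
#'
#' @param seq character scalar, spliced transcript 5'->3' (ACGT only).
#' @param min_codons minimum protein length in codons (default 100).
#' @return `NULL` when no qualifying ORF exists, else a list with
#'   `orf_start` (0-based nt offset of the ATG), `orf_end` (0-based
#'   half-open end, including the stop codon) and `protein` (AA string
#'   beginning with M, stop not included).
#' @export
predict_orf <- function(seq, min_codons = 100L) {
  stopifnot(.is_scalar_string(seq))
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop("non-ACGT character at position ", as.integer(bad))
  starts <- gregexpr("ATG", seq, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(NULL)
  starts <- as.integer(starts)          # 1-based
  stops <- sort(unique(unlist(lapply(c("TAA", "TAG", "TGA"), function(s) {
    p <- gregexpr(s, seq, fixed = TRUE)[[1L]]
    if (p[1L] == -1L) integer(0) else as.integer(p)
  }))))
  best_len <- -1L; best_start <- NA_integer_; best_stop <- NA_integer_
  for (f in 0:2) {
    fs <- starts[(starts - 1L) %% 3L == f]
    fe <- stops[(stops - 1L) %% 3L == f]
    if (!length(fs) || !length(fe)) next
    ## for each ATG, the first in-frame stop at or after ATG+3
    idx <- findInterval(fs + 2L, fe) + 1L
    ok <- idx <= length(fe)
    for (i in which(ok)) {
      aa_len <- (fe[idx[i]] - fs[i]) %/% 3L
      if (aa_len > best_len || (aa_len == best_len && fs[i] < best_start)) {
        best_len <- aa_len; best_start <- fs[i]; best_stop <- fe[idx[i]]
      }
    }
  }
  if (best_len < min_codons) return(NULL)
  cds <- substr(seq, best_start, best_stop - 1L)
  protein <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  list(orf_start = best_start - 1L, orf_end = best_stop + 2L,
       protein = protein)
}

#' Predict ORFs for a set of transcripts
#'
#' @param seqs named character vector of mature transcript sequences.
#' @param min_codons minimum protein length in codons.
#' @return `data.table` with columns `isoform_id`, `orf_start`, `protein`;
#'   transcripts without a qualifying ORF are omitted.
#' @export
predict_orfs <- function(seqs, min_codons = 100L) {
  res <- lapply(seqs, predict_orf, min_codons = min_codons)
  keep <- !vapply(res, is.null, TRUE)
  data.table::data.table(
    isoform_id = names(seqs)[keep],
    orf_start = vapply(res[keep], `[[`, 0L, "orf_start"),
    protein = vapply(res[keep], `[[`, "", "protein"))
}

#' Group ORFs by identical CDS (protein string)
#'
#' @param orfs `data.table` from [predict_orfs()].
#' @return list with `groups` (`data.table`: `cds_group`, `protein`,
#'   `n_isoforms`) and `membership` (`data.table`: `isoform_id`, `cds_group`).
#' @export
unique_cds <- function(orfs) {
  stopifnot(nrow(orfs) == 0L || all(c("isoform_id", "protein") %in% names(orfs)))
  if (nrow(orfs) == 0L) {
    return(list(groups = data.table::data.table(cds_group = integer(0),
                                                protein = character(0),
                                                n_isoforms = integer(0)),
                membership = data.table::data.table(isoform_id = character(0),
                                                    cds_group = integer(0))))
  }
  prot <- sort(unique(orfs$protein))
  grp <- match(orfs$protein, prot)
  groups <- data.table::data.table(cds_group = seq_along(prot), protein = prot)
  groups$n_isoforms <- as.integer(table(factor(grp, levels = groups$cds_group)))
  list(groups = groups,
       membership = data.table::data.table(isoform_id = orfs$isoform_id,
                                           cds_group = grp))
}

#' Type ORFs against a reference proteome
#'
#' `annotated`: the predicted protein exactly equals a reference protein;
#' `variant`: the isoform is assigned to a gene but its protein differs;
#' `novel-locus`: the isoform has no gene assignment (intergenic/antisense
#' origin).
#'
#' @param orfs `data.table` from [predict_orfs()].
#' @param ref_proteome named character vector of reference proteins.
#' @param gene_ids character vector aligned with `orfs` rows; `NA` means no
#'   gene was assigned.
#' @return the `orfs` table with an `orf_type` column added.
#' @export
classify_orfs <- function(orfs, ref_proteome, gene_ids) {
  stopifnot(length(gene_ids) == nrow(orfs))
  orfs <- data.table::copy(orfs)
  orfs$orf_type <- ifelse(orfs$protein %in% ref_proteome, "annotated",
                          ifelse(is.na(gene_ids), "novel-locus", "variant"))
  orfs
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R except before P (no missed cleavages), keeping
#' peptides within the configured length window.
#'
#' @param protein AA string.
#' @param min_len,max_len peptide length window (defaults 7-40).
#' @return character vector of peptides (possibly empty).
#' @export
tryptic_digest <- function(protein, min_len = 7L, max_len = 40L) {
  pieces <- strsplit(gsub("(?<=[KR])(?!P)", " ", protein, perl = TRUE), " ",
                     fixed = TRUE)[[1L]]
  pieces[nchar(pieces) >= min_len & nchar(pieces) <= max_len]
}

#' Map observed peptides onto predicted and reference proteins
#'
#' A peptide matches an isoform iff it is an exact substring of the
#' isoform's predicted protein. Isoform-specific peptides match exactly one
#' isoform and are absent from the reference proteome.
#'
#' @param peptides character vector of peptide AA strings.
#' @param orfs `data.table` from [predict_orfs()].
#' @param ref_proteome named character vector of reference proteins.
#' @return list with `matches` (`data.table`: `peptide`, `n_isoforms`,
#'   `isoform_ids` (comma-joined), `in_reference_proteome`,
#'   `isoform_specific`) and `support` (`data.table`: `isoform_id`,
#'   `n_peptides`, `n_specific`, `supported`).
#' @export
map_peptides <- function(peptides, orfs, ref_proteome) {
  bad <- grep("[^ACDEFGHIKLMNPQRSTVWY]", peptides)
  if (length(bad))
    stop("peptide with non-amino-acid characters: ", peptides[bad[1L]])
  prot <- orfs$protein
  match_list <- lapply(peptides, function(p) orfs$isoform_id[
    grepl(p, prot, fixed = TRUE)])
  in_ref <- vapply(peptides, function(p) any(grepl(p, ref_proteome, fixed = TRUE)),
                   TRUE, USE.NAMES = FALSE)
  n_iso <- lengths(match_list)
  matches <- data.table::data.table(
    peptide = peptides,
    n_isoforms = n_iso,
    isoform_ids = vapply(match_list, paste, "", collapse = ","),
    in_reference_proteome = in_ref,
    isoform_specific = n_iso == 1L & !in_ref)
  hit <- data.table::data.table(
    isoform_id = unlist(match_list),
    specific = rep(matches$isoform_specific, n_iso))
  support <- data.table::data.table(isoform_id = orfs$isoform_id)
  if (nrow(hit)) {
    agg <- hit[, .(n_peptides = .N, n_specific = sum(specific)), by = isoform_id]
    support <- merge(support, agg, by = "isoform_id", all.x = TRUE, sort = FALSE)
    support[is.na(n_peptides), `:=`(n_peptides = 0L, n_specific = 0L)]
  } else {
    support$n_peptides <- 0L; support$n_specific <- 0L
  }
  support$supported <- support$n_peptides >= 1L
  list(matches = matches, support = support)
}
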