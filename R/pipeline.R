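## Short-read junction validation, per-cell isoform matrix, cell-type
## specificity, report assembly, and the run-all pipeline driver.

#' Read a junction-support table
#' @param path TSV with columns chrom, strand, donor, acceptor, unique_count.
#' @return `data.table`.
#' @export
read_junction_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("chrom", "strand", "donor", "acceptor", "unique_count")
                %in% names(dt)))
  dt
}

#' Validate isoform junctions against short-read support
#'
#' A junction is validated when its unique-read count is strictly greater
#' than `min_unique`; an isoform is validated when every junction is.
#' Mono-exonic isoforms are reported as `NA` (not applicable).
#'
#' @param isoforms `data.table` with `isoform_id`, `chain`, `n_exons`.
#' @param support `data.table` from [read_junction_counts()].
#' @param min_unique strict threshold (default 5: six or more reads pass).
#' @return list with `junctions` (`isoform_id`, `chrom`, `strand`, `donor`,
#'   `acceptor`, `unique_count`, `validated`) and `isoforms`
#'   (`isoform_id`, `n_junctions`, `n_validated`, `validated`).
#' @export
validate_junctions <- function(isoforms, support, min_unique = 5L) {
  sup_key <- paste0(support$chrom, ":", support$strand, ":",
                    support$donor, "-", support$acceptor)
  sup <- stats::setNames(support$unique_count, sup_key)
  jrows <- list()
  iso_res <- data.table::data.table(
    isoform_id = isoforms$isoform_id,
    n_junctions = 0L, n_validated = 0L, validated = NA)
  for (i in seq_len(nrow(isoforms))) {
    p <- .parse_chain_key(isoforms$chain[i])
    if (!nrow(p$junctions)) next
    keys <- paste0(p$chrom, ":", p$strand, ":",
                   p$junctions[, 1L], "-", p$junctions[, 2L])
    cnt <- sup[keys]
    cnt[is.na(cnt)] <- 0L
    ok <- cnt > min_unique
    jrows[[length(jrows) + 1L]] <- data.table::data.table(
      isoform_id = isoforms$isoform_id[i], chrom = p$chrom, strand = p$strand,
      donor = p$junctions[, 1L], acceptor = p$junctions[, 2L],
      unique_count = as.integer(cnt), validated = ok)
    data.table::set(iso_res, i, "n_junctions", length(ok))
    data.table::set(iso_res, i, "n_validated", sum(ok))
    data.table::set(iso_res, i, "validated", all(ok))
  }
  junctions <- if (length(jrows)) data.table::rbindlist(jrows) else
    data.table::data.table(isoform_id = character(0), chrom = character(0),
                           strand = character(0), donor = integer(0),
                           acceptor = integer(0), unique_count = integer(0),
                           validated = logical(0))
  list(junctions = junctions, isoforms = iso_res)
}

#' Build the isoform-by-cell UMI count matrix
#'
#' Entries are deduplicated UMI counts per (isoform, barcode). The optional
#' filtered view drops isoforms seen in fewer than `min_cells` cells, then
#' cells with fewer than `min_features` isoforms; the raw matrix is always
#' kept (the filter mirrors matrix-loading defaults used for clustering and
#' never trims the catalog).
#'
#' @param assignments `data.table` with `barcode`, `umi`, `isoform_id`
#'   (already UMI-deduplicated rows, one per molecule).
#' @param clusters `data.table` with `barcode`, `cluster`.
#' @param min_cells,min_features filtered-view thresholds (defaults 3, 50).
#' @return list with `raw`, `filtered` (`dgCMatrix`), `cell_clusters`
#'   (named character vector over the raw matrix's columns).
#' @export
build_cell_matrix <- function(assignments, clusters, min_cells = 3L,
                              min_features = 50L) {
  a <- data.table::as.data.table(assignments)
  counts <- a[, .(n = .N), by = .(isoform_id, barcode)]
  isos <- sort(unique(counts$isoform_id))
  cells <- sort(unique(counts$barcode))
  m <- Matrix::sparseMatrix(i = match(counts$isoform_id, isos),
                            j = match(counts$barcode, cells),
                            x = counts$n, dims = c(length(isos), length(cells)),
                            dimnames = list(isos, cells))
  cl <- stats::setNames(clusters$cluster[match(cells, clusters$barcode)], cells)
  if (anyNA(cl)) {
    warning(sum(is.na(cl)), " barcodes absent from the cluster table; ",
            "assigned 'unknown'")
    cl[is.na(cl)] <- "unknown"
  }
  keep_iso <- Matrix::rowSums(m > 0) >= min_cells
  f <- m[keep_iso, , drop = FALSE]
  keep_cell <- Matrix::colSums(f > 0) >= min_features
  f <- f[, keep_cell, drop = FALSE]
  list(raw = m, filtered = f, cell_clusters = cl)
}

#' Write a cell matrix in MatrixMarket triplet format
#' @param mat `dgCMatrix` (isoforms x cells).
#' @param dir output directory; writes `matrix.mtx`, `isoforms.tsv`,
#'   `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat, file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "isoforms.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Cell-type-specificity sets and UpSet tally
#'
#' An isoform is detected in a cluster when its summed count over the
#' cluster's cells is at least `detect_min`; it is cell-type specific when
#' detected in exactly one cluster. The UpSet tally partitions the
#' isoform set by detected-cluster signature.
#'
#' @param mat raw matrix from [build_cell_matrix()].
#' @param cell_clusters named vector (columns of `mat` -> cluster).
#' @param detect_min detection threshold on summed counts (default 1).
#' @return list with `isoforms` (`isoform_id`, `clusters` (comma-joined),
#'   `n_clusters`, `specific`), `upset` (`clusters`, `n`), and
#'   `cluster_sums` (matrix isoform x cluster).
#' @export
specificity_sets <- function(mat, cell_clusters, detect_min = 1L) {
  cl <- cell_clusters[colnames(mat)]
  cl_names <- sort(unique(cl))
  ind <- Matrix::sparseMatrix(i = seq_along(cl), j = match(cl, cl_names),
                              x = 1, dims = c(length(cl), length(cl_names)),
                              dimnames = list(colnames(mat), cl_names))
  sums <- as.matrix(mat %*% ind)
  det <- sums >= detect_min
  sets <- apply(det, 1L, function(r) paste(cl_names[r], collapse = ","))
  iso <- data.table::data.table(isoform_id = rownames(mat), clusters = sets,
                                n_clusters = rowSums(det),
                                specific = rowSums(det) == 1L)
  upset <- iso[, .(n = .N), by = .(clusters)]
  data.table::setorder(upset, -n, clusters)
  list(isoforms = iso, upset = upset, cluster_sums = sums)
}

#' Per-barcode cross-platform correlation
#'
#' Pearson correlation, across shared barcodes, of per-cell total UMI
#' counts and per-cell feature (gene/isoform) counts between a short-read
#' matrix and the long-read matrix.
#'
#' @param short,long matrices (features x cells) with barcode colnames.
#' @return list with `umi_cor`, `feature_cor`, `n_cells`.
#' @export
cross_platform_correlation <- function(short, long) {
  common <- intersect(colnames(short), colnames(long))
  if (length(common) < 3L) stop("fewer than 3 shared barcodes")
  s <- short[, common, drop = FALSE]; l <- long[, common, drop = FALSE]
  list(umi_cor = stats::cor(Matrix::colSums(s), Matrix::colSums(l)),
       feature_cor = stats::cor(Matrix::colSums(s > 0), Matrix::colSums(l > 0)),
       n_cells = length(common))
}

#' Pipeline thresholds and options
#'
#' All thresholds of the run-all pipeline in one (recorded) place.
#' Defaults follow the workflow's stated values: polyA >= 20 nt, mapping
#' quality >= 20, CAGE/polyA window 50 nt, junction support > 5 unique
#' reads, ORFs >= 100 codons, RT-switch repeat 8 nt, detection threshold 1,
#' matrix-view filter min.cells 3 / min.features 50.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    primer5 = "AAGCAGTGGTATCAACGCAGAGTAC",
    primer3 = "CTACACGACGCTCTTCCGATCT",
    min_polyA = 20L, max_mismatch = 2L, barcode_len = 16L, umi_len = 12L,
    min_mapq = 20L, end_fuzz = 100L, window = 50L, repeat_k = 8L,
    canonical = c("GTAG", "GCAG", "ATAC"),
    categories_filtered = c("ISM", "NIC", "NNC"),
    excluded_categories = c("antisense", "fusion", "genic", "genic_intron",
                            "intergenic"),
    min_unique = 5L, detect_min = 1L, min_cells = 3L, min_features = 50L,
    min_codons = 100L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown pipeline options: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Assemble the machine-readable pipeline report
#'
#' A pure function of the stage outputs; any missing stage is reported as
#' `"stage not run"`.
#'
#' @param stages named list of stage outputs (see [run_pipeline()]).
#' @param config the `pipeline_config` used.
#' @return report list (JSON-serializable).
#' @export
pipeline_report <- function(stages, config) {
  not_run <- "stage not run"
  rep_ <- list(config = unclass(config))
  rep_$demux <- if (is.null(stages$demux)) not_run else {
    rj <- stages$demux$rejects
    list(n_reads = nrow(stages$demux$flnc) + nrow(rj),
         n_flnc = nrow(stages$demux$flnc),
         rejections = as.list(table(rj$reason)))
  }
  rep_$dedup <- if (is.null(stages$molecules)) not_run else
    list(n_molecules = nrow(stages$molecules),
         n_duplicates_removed = sum(stages$molecules$n_dups - 1L))
  rep_$collapse <- if (is.null(stages$isoforms)) not_run else
    list(n_isoforms = nrow(stages$isoforms),
         n_loci = length(unique(sub("^PB\\.([0-9]+)\\..*$", "\\1",
                                    stages$isoforms$isoform_id))))
  rep_$classification <- if (is.null(stages$classified)) not_run else {
    cl <- stages$classified
    dropped_excluded <- sum(cl$category %in% config$excluded_categories)
    dropped_artifact <- sum(!cl$category %in% config$excluded_categories &
                              !cl$retained &
                              (cl$noncanonical_novel_junction | cl$rt_switch))
    dropped_end <- sum(!cl$retained) - dropped_excluded - dropped_artifact
    list(category_counts = as.list(table(cl$category)),
         n_retained = sum(cl$retained),
         attrition = list(input = nrow(cl), retained = sum(cl$retained),
                          excluded_category = dropped_excluded,
                          junction_artifact = dropped_artifact,
                          no_end_support = dropped_end))
  }
  rep_$events <- if (is.null(stages$event_summary)) not_run else {
    es <- stages$event_summary
    list(by_type = stats::setNames(as.list(es$n),
                                   paste(es$event_type, es$stratum, sep = "_")),
         total = sum(es$n))
  }
  rep_$orf <- if (is.null(stages$orfs)) not_run else
    list(n_orfs = nrow(stages$orfs),
         n_unique_cds = nrow(stages$cds$groups),
         orf_types = as.list(table(stages$orfs$orf_type)))
  rep_$peptides <- if (is.null(stages$peptides)) not_run else
    list(n_peptides = nrow(stages$peptides$matches),
         n_matched = sum(stages$peptides$matches$n_isoforms > 0L),
         n_isoform_specific = sum(stages$peptides$matches$isoform_specific),
         n_supported_isoforms = sum(stages$peptides$support$supported))
  rep_$validation <- if (is.null(stages$validation)) not_run else {
    vi <- stages$validation$isoforms
    out <- list(n_junctions = nrow(stages$validation$junctions),
                n_junctions_validated = sum(stages$validation$junctions$validated),
                n_isoforms_validated = sum(vi$validated, na.rm = TRUE))
    if (!is.null(stages$cluster_validation))
      out$per_cluster_novel_validation_rate <- stages$cluster_validation
    out
  }
  rep_$matrix <- if (is.null(stages$matrix)) not_run else
    list(n_isoforms = nrow(stages$matrix$raw),
         n_cells = ncol(stages$matrix$raw),
         total_umis = sum(stages$matrix$raw),
         filtered_dim = dim(stages$matrix$filtered))
  rep_$specificity <- if (is.null(stages$specificity)) not_run else {
    sp <- stages$specificity$isoforms
    list(n_specific = sum(sp$specific), n_isoforms = nrow(sp),
         upset = stats::setNames(as.list(stages$specificity$upset$n),
                                 stages$specificity$upset$clusters))
  }
  rep_$cross_platform <- if (is.null(stages$cross_platform)) not_run else
    stages$cross_platform
  rep_
}

#' Run the full discovery pipeline on generated (or real) inputs
#'
#' Executes demultiplexing, chain extraction, UMI deduplication, collapse,
#' classification + filtering, AS events, ORF/peptide analysis, junction
#' validation, the per-cell matrix, specificity and the report. All stages
#' are deterministic; outputs are written under `out_dir`.
#'
#' @param paths named list of input paths: `genome`, `annotation`, `fastq`,
#'   `sam`, `whitelist`, `clusters`, `junction_counts`, `cage`, `polya`,
#'   `peptides`, `proteome` (as produced by [simulate_cochlea()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisible list of all stage outputs plus `report`.
#' @export
run_pipeline <- function(paths, config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_annotation(paths$annotation)
  genome <- read_genome(paths$genome)
  whitelist <- readLines(paths$whitelist)
  clusters <- data.table::fread(paths$clusters, sep = "\t")

  ## demux
  reads <- read_fastq(paths$fastq)
  demux <- extract_flnc(reads, config$primer5, config$primer3, whitelist,
                        min_polyA = config$min_polyA,
                        bc_len = config$barcode_len, umi_len = config$umi_len,
                        max_mismatch = config$max_mismatch)

  ## alignments -> chains (FLNC reads only)
  sam <- read_sam(paths$sam)
  ch <- chain_from_alignment(sam, min_mapq = config$min_mapq)
  rec <- merge(demux$flnc, ch$chains, by = "read_id", sort = TRUE)

  ## UMI dedup -> molecules
  molecules <- dedup_umis(rec)

  ## collapse
  col <- collapse_chains(molecules, end_fuzz = config$end_fuzz)

  ## classification + artifact + end-support filters
  cl <- classify_isoforms(col$isoforms, ann, end_fuzz = config$end_fuzz)
  flags <- lapply(seq_len(nrow(cl)), function(i) {
    known <- if (is.na(cl$gene_id[i])) character(0) else
      site_catalog(gene_transcripts(ann, cl$gene_id[i]))$junctions
    junction_artifact_check(cl$chrom[i], cl$strand[i], cl$exons[[i]], genome,
                            known_junctions = known,
                            canonical = config$canonical,
                            repeat_k = config$repeat_k)
  })
  cl$noncanonical_novel_junction <-
    vapply(flags, `[[`, TRUE, "noncanonical_novel_junction")
  cl$rt_switch <- vapply(flags, `[[`, TRUE, "rt_switch")
  cage <- read_bed(paths$cage)
  polya <- read_bed(paths$polya)
  cl <- end_support_filter(cl, cage, polya, window = config$window,
                           categories_filtered = config$categories_filtered)
  cl[cl$category %in% config$excluded_categories, "retained"] <- FALSE
  kept <- cl[cl$retained == TRUE, ]

  ## per-cell assignments over retained isoforms
  assign_all <- merge(col$read_map,
                      molecules[, .(read_id, barcode, umi)], by = "read_id")
  assignments <- assign_all[assign_all$isoform_id %in% kept$isoform_id, ]
  mat <- build_cell_matrix(assignments, clusters,
                           min_cells = config$min_cells,
                           min_features = config$min_features)
  spec <- specificity_sets(mat$raw, mat$cell_clusters,
                           detect_min = config$detect_min)

  ## AS events on reference + retained novel isoforms
  novel_cat <- c("NIC", "NNC")
  disc <- kept[kept$category %in% novel_cat & !is.na(kept$gene_id), ]
  disc_tx <- lapply(seq_len(nrow(disc)), function(i)
    transcript_model(disc$isoform_id[i], disc$gene_id[i], disc$chrom[i],
                     disc$strand[i], disc$exons[[i]]))
  combined <- c(ann$transcripts, disc_tx)
  gene_of <- vapply(combined, `[[`, "", "gene_id")
  events <- data.table::rbindlist(lapply(unique(gene_of), function(g)
    detect_events(combined[gene_of == g], gene_id = g)))
  novelty <- c(
    stats::setNames(rep("known", length(ann$transcripts)),
                    names(ann$transcripts)),
    stats::setNames(rep("novel", nrow(disc)), disc$isoform_id))
  event_summary <- summarize_events(events, novelty)

  ## ORFs + peptides over retained isoforms
  seqs <- vapply(seq_len(nrow(kept)), function(i)
    transcript_seq(genome, kept$chrom[i], kept$strand[i],
                   kept$exons[[i]]), "")
  names(seqs) <- kept$isoform_id
  orfs <- predict_orfs(seqs, min_codons = config$min_codons)
  cds <- unique_cds(orfs)
  proteome_set <- Biostrings::readAAStringSet(paths$proteome)
  proteome <- stats::setNames(as.character(proteome_set),
                              sub("\\s.*$", "", names(proteome_set)))
  orf_gene <- kept$gene_id[match(orfs$isoform_id, kept$isoform_id)]
  orfs <- classify_orfs(orfs, proteome, orf_gene)
  pep_list <- readLines(paths$peptides)
  peptides <- map_peptides(pep_list, orfs, proteome)

  ## junction validation
  validation <- validate_junctions(kept, read_junction_counts(paths$junction_counts),
                                   min_unique = config$min_unique)
  ## per-cluster novel validation rate
  vmap <- stats::setNames(validation$isoforms$validated,
                          validation$isoforms$isoform_id)
  cl_names <- sort(unique(mat$cell_clusters))
  cluster_validation <- lapply(cl_names, function(cn) {
    det <- spec$cluster_sums[, cn] >= config$detect_min
    ids <- rownames(spec$cluster_sums)[det]
    nov <- ids[ids %in% disc$isoform_id]
    if (!length(nov)) return(NA_real_)
    mean(vmap[nov], na.rm = TRUE)
  })
  names(cluster_validation) <- cl_names

  stages <- list(demux = demux, chain_rejects = ch$rejects,
                 molecules = molecules, isoforms = col$isoforms,
                 read_map = col$read_map, classified = cl,
                 events = events, event_summary = event_summary,
                 orfs = orfs, cds = cds, peptides = peptides,
                 validation = validation,
                 cluster_validation = cluster_validation,
                 matrix = mat, specificity = spec)
  report <- pipeline_report(stages, config)
  stages$report <- report

  ## write outputs
  w <- function(dt, f) data.table::fwrite(dt, file.path(out_dir, f), sep = "\t")
  w(demux$flnc[, .(read_id, barcode, umi, orientation, polyA_len)], "flnc.tsv")
  w(demux$rejects, "flnc_rejects.tsv")
  w(molecules[, .(read_id, barcode, umi, chain, n_dups)], "molecules.tsv")
  iso_out <- data.table::as.data.table(cl)[, .(
    isoform_id, chrom, strand, start, end, tss, tes, chain, n_exons, n_reads,
    category, gene_id, evidence, noncanonical_novel_junction, rt_switch,
    cage_supported, polya_supported, retained)]
  w(iso_out, "isoforms.tsv")
  w(col$read_map, "read_map.tsv")
  w(events, "events.tsv")
  w(event_summary, "events_summary.tsv")
  w(orfs, "orfs.tsv")
  w(cds$groups[, .(cds_group, n_isoforms)], "cds_groups.tsv")
  w(peptides$matches, "peptide_matches.tsv")
  w(peptides$support, "peptide_support.tsv")
  w(validation$junctions, "junction_validation.tsv")
  w(validation$isoforms, "isoform_validation.tsv")
  w(spec$isoforms, "specificity.tsv")
  w(spec$upset, "upset.tsv")
  write_cell_matrix(mat$raw, file.path(out_dir, "matrix"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stages)
}
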