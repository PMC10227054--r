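# Shared fixtures. Simulations are generated once per test session and
# cached in tempdir(); every fixture is built in code (no stored data).

.fix <- new.env(parent = emptyenv())

# the stated default world, noise-free (exact truth recovery is expected)
sim_noise_free <- function() {
  if (is.null(.fix$nf)) {
    dir <- file.path(tempdir(), "scisokit-sim-nf")
    cfg <- simulation_config(seed = 11L, truncation_prob = 0,
                             barcode_error_rate = 0)
    .fix$nf <- list(cfg = cfg, sim = simulate_cochlea(cfg, dir), dir = dir)
  }
  .fix$nf
}

# one pipeline run over the noise-free world
run_noise_free <- function() {
  if (is.null(.fix$nf_run)) {
    nf <- sim_noise_free()
    out <- file.path(tempdir(), "scisokit-out-nf")
    .fix$nf_run <- list(
      stages = run_pipeline(nf$sim$paths, pipeline_config(), out), out = out)
  }
  .fix$nf_run
}

# a small noisy world (truncation, barcode errors, duplicates)
sim_noisy <- function() {
  if (is.null(.fix$noisy)) {
    dir <- file.path(tempdir(), "scisokit-sim-noisy")
    cfg <- simulation_config(seed = 7L, n_genes = 6L, cells_per_cluster = 12L,
                             reads_per_cell = 40, truncation_prob = 0.1,
                             barcode_error_rate = 0.1, duplicate_rate = 0.1)
    .fix$noisy <- list(cfg = cfg, sim = simulate_cochlea(cfg, dir), dir = dir)
  }
  .fix$noisy
}

# a 50-gene annotation for classifier stress tests
big_annotation <- function() {
  if (is.null(.fix$big_ann)) {
    cfg <- simulation_config(seed = 23L, n_genes = 50L,
                             transcripts_per_gene = c(1L, 3L))
    .fix$big_ann <- simulate_reference(cfg)
  }
  .fix$big_ann
}

# toy transcripts used across files -------------------------------------------

toy_tx <- function(id, exons, gene = "G", chrom = "chr1", strand = "+") {
  transcript_model(id, gene, chrom, strand, exons)
}

# the spec-style two-junction reference: exons (100,200),(300,400)
toy_reference <- function(strand = "+") {
  annotation(list(
    toy_tx("T1", rbind(c(100L, 200L), c(300L, 400L)), strand = strand)))
}

# assemble a synthetic raw read from its parts
make_read <- function(insert, barcode, umi, primer5, primer3,
                      polyA = 30L, rc = FALSE) {
  s <- paste0(primer5, insert, strrep("A", polyA), umi, barcode, primer3)
  if (rc) revcomp(s) else s
}
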