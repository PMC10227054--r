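---
title: "scisokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scisokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the models and procedures behind scisokit, the
parameters that matter, what the bundled synthetic-data generator does and
does not emulate, and the design decisions taken where the workflow it
re-implements left the details open.

## The problem

Single-cell isoform sequencing (ScISOr-Seq-style designs) combines two
measurements of the same cells: short reads, which are deep enough to
define cells, clusters and junction-level support, and full-length long
reads, which capture complete transcript structures but at far lower
depth. The two are linked by shared cell barcodes. The analysis question
is: which full-length isoforms exist, which are novel relative to the
annotation, which survive artifact filtering, how do they distribute
across cell types, and do they plausibly produce distinct proteins?

## Coordinates and the junction-chain model

All internal coordinates are 0-based half-open genomic intervals; GTF I/O
converts to and from the 1-based inclusive GTF convention at the boundary,
which confines every off-by-one decision to one file. Exon lists are kept
in genomic order regardless of strand; biological order is derived on
demand.

The central object is the *junction chain*: the ordered list of
(donor, acceptor) genomic coordinates of a multi-exon transcript, where
"donor" is the genomic-left coordinate (upstream exon end). Biological
donor/acceptor labels — needed for NIC/NNC site checks and for A5/A3
event typing — are assigned per strand (the biological donor of a
minus-strand junction is the genomic-right coordinate). Junction-chain
identity (exact equality) is the merge key everywhere: collapse, UMI
deduplication and FSM testing. Transcript ends never distinguish
multi-exon isoforms at collapse time; end handling is deferred to the
CAGE/polyA filter, where it belongs scientifically.

## Classification

Multi-exon queries are classified against the annotation in a fixed
order: FSM (chain equals a reference chain), ISM (consecutive *proper*
subchain — suffixes and prefixes of a reference chain, as produced by 5'
truncation), then NIC if every donor and acceptor of the assigned gene is
annotated, else NNC. Gene assignment is the same-strand gene with maximal
exonic overlap (≥ 1 nt). When no same-strand exonic overlap exists:
antisense (opposite-strand exonic overlap), fusion (the query span covers
two or more disjoint annotated loci), genic_intron (wholly inside one
intron), genic (locus overlap otherwise), intergenic. Mono-exon queries:
FSM against a mono-exon reference within 100 nt at both ends (the same
fuzz used in collapse), ISM when contained in a reference exon, genic
otherwise.

Two details are deliberate choices. First, the fusion test sits in the
no-exonic-overlap branch and is evaluated at locus level, strand-agnostic
together with genic/genic_intron; antisense takes precedence and requires
opposite-strand *exonic* overlap. Second, the classifier never mutates
gene models: gene membership of a discovered isoform is decided here, not
at collapse.

## Artifact filters

Novel junctions (absent from the assigned gene's annotated junction set)
are checked for two artifact signatures on the transcribed strand:

* **Non-canonical motif** — intron boundary dinucleotides outside
  {GT–AG, GC–AG, AT–AC}.
* **RT template switching** — a direct repeat of `repeat_k` = 8 nt ending
  at the donor (exonic side) and at the acceptor's intronic boundary.
  The workflow we re-implement names this filter but never defines it;
  the 8-nt direct-repeat operationalization is the classic signature of
  template switching during reverse transcription, and `repeat_k` is
  configurable.

End support: an ISM/NIC/NNC isoform is retained only when its TSS lies
within 50 bp (inclusive) of a CAGE peak **and** its TES within 50 bp of a
polyA peak, and neither artifact flag is set. The 50-bp rule as stated in
the source workflow is ambiguous between AND and OR across the two ends;
we require each end to be supported by its own peak type, because a CAGE
peak says nothing about a 3' end. FSM isoforms are exempt: the filter
exists to remove genomic contamination and PCR artifacts, which cannot
produce exact annotation matches. Both the category list subject to
filtering and the window are configurable, and the report records the
values used.

## AS events

Events are defined pairwise between transcripts of one gene and
deduplicated by (type, coordinates), following local-event semantics:
ES (a junction in one transcript vs ≥ 1 complete exon between the same
flanking sites in another), A5/A3 (two junctions sharing one boundary,
differing at the donor/acceptor, strand-aware), RI (an exon spanning
another transcript's junction with both outer edges matching), MX (two
non-overlapping single-exon paths between a shared donor and acceptor
that never co-occur in one chain), AF/AL (distinct, non-overlapping
terminal exons splicing to/from a shared site).

The A5-versus-AF boundary is resolved by exon overlap: when the
alternative flanking exons overlap each other the event is an A5/A3
(alternative site on one exon); when they are disjoint and both terminal
it is an AF/AL. On the minus strand the biological first exon is the
genomic *last* one, so the AF/AL label attaches to the genomic-upstream
alternatives for AL and genomic-downstream ones for AF — the planted
perturbations in the generator exercise both strands.

## ORFs and peptide support

The statistical ORF caller used in the original toolchain is replaced by
a deterministic rule: the longest ATG-initiated ORF that terminates at an
in-frame stop *within* the sequence, ties broken 5'-most, rejected below
100 codons (the threshold we preserve). This makes the prediction exactly
reproducible and testable against an exhaustive ATG-scan oracle. ORF
typing uses strict full-protein equality for "annotated"; softer
similarity tiers are out of scope. Peptide matching is exact substring
(no I/L folding, no PTMs); an isoform-specific peptide matches exactly
one predicted protein and is absent from the reference proteome. The
in-silico digest is tryptic: cleave after K/R, not before P, no missed
cleavages, length 7–40.

## Validation, matrix, specificity

A junction is validated when supported by **more than 5** unique short
reads (strict inequality: 6 passes, 5 does not); an isoform is validated
when every junction is; mono-exon isoforms are reported as not
applicable. The isoform × cell matrix counts deduplicated UMIs; the
min.cells = 3 / min.features = 50 filter is applied only to an auxiliary
view (mirroring matrix-loading defaults of clustering tools) and never
trims the catalog. An isoform is detected in a cluster when its summed
count reaches `detect_min` = 1 — the source workflow states no detection
threshold, so the weakest one is the default and the report records it —
and is cell-type specific when detected in exactly one cluster.

## The synthetic world

The generator's defaults state one fixed world: 20 genes on two
chromosomes, 1–3 reference transcripts per gene, masters of 4–8 exons
(120–240 nt, multiples of 3) separated by 300–600-nt introns; 4 clusters
× 50 cells at ~100 reads/cell (≈ 20k reads); a 1:1 novel:reference ratio
(the tissue studied by the source workflow was ~54% novel); novel
isoforms cluster-exclusive with probability 0.8 (~79% of novel transcripts
were cell-type specific there); truncation probability 0.1, barcode error
rate 0.02 (single substitutions, matching the Hamming-1 correction
contract), PCR duplicate rate 0.05, 30-nt polyA tails, 16-nt barcodes and
12-nt UMIs (10x V3 chemistry), and a short-read depth factor of 3 for
junction support.

Several constructions make ground truth exactly recoverable:

* Exonic sequence is built from stop-free codons in frame 0 with ATG at
  the transcript start and a stop-codon tail (stops in all three frames)
  at the end of the last exon, so every reference transcript carries an
  ORF and frame-preserving perturbations behave predictably — skipping a
  3k-nt exon deletes exactly k amino acids.
* Every annotated intron is canonical GT–AG on the transcribed strand.
  In addition, each intron carries a fixed menu of *cryptic* canonical
  sites — an alternative donor and acceptor 9 nt into the intron, and
  one 72-nt cryptic exon at offset 100 — pre-planted and screened
  against 8-nt direct repeats. Novel isoforms draw only from this menu,
  which is why `simulate_novel_isoforms(annotation, cfg)` never edits the
  genome: the coordinates travel in the annotation's `sim_info` table.
* Barcodes are generated pairwise Hamming ≥ 3 apart, so every single
  substitution error has a unique Hamming-1 neighbour and is always
  correctable; truncations keep at least 30 nt of the entry exon
  (fragments shorter than that would not survive size selection).
* ES and RI reuse annotated sites (intended NIC); site shifts and
  cryptic-exon events introduce novel sites (intended NNC). RI retains
  only internal introns and ES skips only internal exons so that no
  perturbed chain degenerates into a consecutive subchain (which would
  classify ISM). The generator verifies every intended label with its own
  site-membership check and resamples on collision.

What the generator does **not** emulate: sequencing errors within reads
(indels, substitutions outside the barcode), chimeric reads, doublets,
ambient RNA, internal polyA priming, expression-dependent length biases,
and realistic ONT error profiles. A green end-to-end test therefore
establishes the correctness of the pipeline's logic on structurally
realistic data, not robustness to raw-signal noise; the demultiplexer's
fuzzy primer search (≤ 2 mismatches) and the mapq gate exist for real
data but are exercised only lightly here.

## Numerical and degenerate-input choices

* Collapse ties: isoforms within a locus are numbered by descending read
  support, then start, end and chain string; UMI-duplicate
  representatives are the longest insert, ties to the smallest read id.
  Both make outputs byte-deterministic under input permutation.
* Mono-exon collapse merges reads that overlap with both end differences
  ≤ 100 nt (transitive closure).
* Peak distances are 0 inside a peak and measured to the nearer edge
  otherwise; "within 50 bp" is inclusive at exactly 50.
* Empty inputs (no reads, no junctions, mono-exon-only isoforms) yield
  typed empty tables, not errors; a read whose insert is consumed by the
  polyA run is rejected as `empty-insert`.
* The UMI deduplication key includes the junction chain rather than the
  full sequence — robust to 3' length jitter; the source workflow does
  not state its key, so this is a documented package decision.
* The mapping-quality cutoff (20) is a default, not a stated value; it is
  surfaced as a flag, as are all thresholds above.

## Known limitations

Classification assigns one gene per isoform (maximal exonic overlap), so
genuinely read-through transcripts inside overlapping loci are reported
as NNC of the dominant gene rather than fusions when they share exonic
sequence with it. Event detection reports local events only — no
transcript-level "complex" events and no PSI quantification. Peptide
support is substring-based and carries no FDR model. The per-stage CLI
commands named in the module interfaces are fulfilled by the exported R
functions; the installed `scisokit` script wraps only the composite
`simulate` and `run-all` commands.
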