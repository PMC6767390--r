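# pairtcr

Well-based paired TCRα/TCRβ repertoire sequencing, expression cloning and
reactivity analysis — implemented end to end in R, with a synthetic-data
generator that makes every stage testable without any external download.

## What it does

Single T cells sorted into 384-well plates have both TCR chains amplified
per well; a two-dimensional primer matrix tags each amplicon with a
column-specific forward and a row-specific reverse barcode, so pooled
amplicons from many plates sequence together and every read traces back to
its well — and therefore to one cell and its index-sort phenotype. The
package covers:

* **Reference** — germline V/J/C/signal-sequence segments with junction
  anchors (conserved V cysteine, J FGxG phenylalanine), FASTA + tab-delimited
  metadata, plus a length-calibrated synthetic locus (`synthetic_locus()`).
* **Barcode matrix** — seeded barcode design (`generate_barcodes()`),
  multi-plate layouts (`build_layout()`), error-correcting tag decoding
  (`decode_tags()`), JSON serialization.
* **Simulation** — per-well ground-truth clonotypes, chain dropout,
  substitution errors with a two-state quality model, 2×300 nt paired-end
  FASTQ output (`simulate_run()`).
* **Preprocessing** — overlap merging (`merge_pairs()`), the strict
  quality (> 0.8) / inclusive length (480–560 nt) filter
  (`filter_reads()`), per-plate subsampling, well demultiplexing with chain
  inference (`demux()`).
* **Annotation** — best-local-alignment V/J assignment
  (`assign_segment()`), CDR3 extraction with productivity calls
  (`extract_cdr3()`), per-well consensus with doublet flagging
  (`annotate_wells()`).
* **Repertoire** — αβ pairing per sorted well (`pair_wells()`),
  amplification/annotation efficiency against sorted-cell denominators
  (`efficiency_table()`), V-usage tables (`v_usage()`), phenotype joins.
* **Constructs** — in-silico Gibson assembly of single-vector
  SSα–Vα–Cα–2A–SSβ–Vβ–Cβ retroviral constructs from a 13-vector SSα
  library, with seam verification, ORF validation and colony-screen PCR
  prediction using the control primers `TCGATCCTCCCTTTATCCAG` /
  `CCATGGAACTGCACTTG` (expected product 1600–1700 bp).
* **Reactivity** — trapezoidal AUC of IL-2 dose–response curves and the
  threshold rule: reactive ⇔ AUC > 0.5, i.e. 50× the negative-control mean
  of 0.01 ± 0.003.

## Worked example

```r
library(pairtcr)

ref    <- synthetic_locus()                       # packaged germline locus
layout <- build_layout(1, generate_barcodes(24, seed = 11),
                          generate_barcodes(16, seed = 22))
cfg    <- sim_config(n_plates = 1, n_wells = 10, reads_per_well = 5,
                     chain_dropout_alpha = 0, chain_dropout_beta = 0,
                     error_rate = 0, seed = 3)
run    <- simulate_run(ref, layout, cfg)
res    <- run_pipeline(run$reads, layout, ref, run$ground_truth,
                       fcfg = filter_config(subsample_per_plate = NULL))
res$efficiency
#> # A tibble: 6 × 5
#>   population_label n_cells pct_alpha pct_beta pct_paired
#>   <chr>              <int>     <dbl>    <dbl>      <dbl>
#> ...
#> 6 all                   10       100      100        100
```

With no errors and no dropout, all 10 wells recover both chains (100/100/100
per cent of sorted cells) and every (V, J, CDR3) matches the simulator's
ground truth. Cloning one recovered pair:

```r
pair <- res$pairs[res$pairs$paired, ][1, ]
cl   <- clone_pair(pair, ref)
cl$validation$in_frame   #> TRUE
cl$screen_bp             #> 1639   (inside the 1600-1700 bp screen window)
```

`cl$construct$features` lists the cassette spans
(backbone–SSα–Vα–Cα–P2A–SSβ–Vβ–Cβ–backbone, 0-based half-open), and
`cl$validation$protein` is the single continuous ORF translation in which
both observed CDR3 peptide strings appear verbatim.

Reactivity calls on a simulated 30-clone panel:

```r
curves <- simulate_reactivity_panel(n_total = 30, n_reactive = 12, seed = 4)
rep    <- batch_report(curves)
rep$summary$n_reactive   #> 12      (12/30, 40% of clones reactive)
```

A thin command-line front end (`inst/scripts/pairtcr`) wraps simulation,
demultiplexing and reactivity scoring for shell use.

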