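#' Run the full preprocessing + annotation pipeline
#'
#' Mates are merged, subsampled per plate pool, filtered on quality and
#' length, demultiplexed to wells, annotated into per-well chain records
#' and paired against the sort manifest.
#'
#' @param pairs read-pair tibble (from [simulate_run()] `$reads` or
#'   [read_fastq_pairs()]).
#' @param layout a `plate_layout`.
#' @param ref a `tcr_reference`.
#' @param manifest sorted-well manifest (plate, row, col,
#'   population_label), e.g. the index-sort table.
#' @param schema an [amplicon_schema()].
#' @param fcfg a [filter_config()].
#' @param scoring an [align_scoring()].
#' @param max_mismatch tag mismatch tolerance.
#' @return list: merged, filtered, demux (wells + stats), records, pairs,
#'   efficiency.
#' @export
run_pipeline <- function(pairs, layout, ref, manifest,
                         schema = amplicon_schema(ref),
                         fcfg = filter_config(),
                         scoring = align_scoring(),
                         max_mismatch = 1L) {
  merged <- merge_pairs(pairs)
  if (!is.null(fcfg$subsample_per_plate))
    merged <- subsample_plate(merged, fcfg$subsample_per_plate,
                              fcfg$subsample_seed)
  flt <- filter_reads(merged, fcfg)
  dm <- demux(flt$kept, layout, schema, max_mismatch)
  records <- annotate_wells(dm$wells, ref, scoring)
  paired <- pair_wells(records, manifest)
  list(merged = merged, filtered = flt, demux = dm, records = records,
       pairs = paired, efficiency = efficiency_table(paired))
}
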