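#' Germline gene-segment references
#'
#' A `tcr_reference` holds germline V, J, C, signal-sequence (SS), 2A-linker
#' and vector-backbone segments for the TCR alpha and beta loci, with the
#' anchor coordinates needed for junction arithmetic: every V segment stores
#' the start of its conserved junction cysteine codon and every J segment the
#' start of its FGxG-motif phenylalanine codon (both 0-based; the codon
#' occupies `[start, start + 3)`).
#'
#' V segments are stored on the 5'->3' coding strand from framework region 1
#' through the end of the conserved cysteine codon.
#'
#' @name tcr_reference
NULL

SEG_CLASSES <- c("V", "J", "C", "SS", "linker2A", "vector_backbone")
CHAINS <- c("alpha", "beta")

new_reference <- function(segments) {
  segments <- as_tibble(segments)
  validate_segments(segments)
  structure(list(segments = segments), class = "tcr_reference")
}

validate_segments <- function(seg) {
  required <- c("id", "chain", "class", "family", "functional",
                "cys_codon_start", "phe_codon_start", "sequence")
  missing <- setdiff(required, names(seg))
  if (length(missing))
    stop("reference metadata lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(seg$id))
    stop("duplicate segment ids: ",
         paste(unique(seg$id[duplicated(seg$id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(seg$sequence)))
    stop("empty sequence for: ", paste(seg$id[!nzchar(seg$sequence)],
                                       collapse = ", "), call. = FALSE)
  assert_dna(seg$sequence, "reference sequence")
  bad_class <- !seg$class %in% SEG_CLASSES
  if (any(bad_class))
    stop("unknown segment class for: ", paste(seg$id[bad_class], collapse = ", "),
         call. = FALSE)
  bad_chain <- !(seg$chain %in% CHAINS | is.na(seg$chain))
  if (any(bad_chain))
    stop("unknown chain for: ", paste(seg$id[bad_chain], collapse = ", "),
         call. = FALSE)
  v <- seg$class == "V"
  bad_v <- v & (is.na(seg$cys_codon_start) |
                  seg$cys_codon_start < 0 |
                  seg$cys_codon_start + 3 > nchar(seg$sequence))
  if (any(bad_v))
    stop("V segment without valid cysteine-codon anchor: ",
         paste(seg$id[bad_v], collapse = ", "), call. = FALSE)
  j <- seg$class == "J"
  bad_j <- j & (is.na(seg$phe_codon_start) |
                  seg$phe_codon_start < 0 |
                  seg$phe_codon_start + 3 > nchar(seg$sequence))
  if (any(bad_j))
    stop("J segment without valid phenylalanine-codon anchor: ",
         paste(seg$id[bad_j], collapse = ", "), call. = FALSE)
  invisible(seg)
}

#' Load a germline reference from FASTA plus a metadata sidecar
#'
#' The metadata is a tab-delimited table with header
#' `id, chain, class, family, functional, cys_codon_start, phe_codon_start`;
#' one row per FASTA record (IMGT-style description-line dialects vary, so
#' annotation never rides on FASTA headers). Anchor columns are 0-based codon
#' start coordinates and may be `NA` where not applicable.
#'
#' @param fasta_path path to a FASTA file of segment sequences.
#' @param metadata_path path to the tab-delimited metadata table.
#' @return a `tcr_reference`.
#' @export
load_reference <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
  no_meta <- setdiff(ids, meta$id)
  if (length(no_meta))
    stop("FASTA records missing from metadata: ",
         paste(no_meta, collapse = ", "), call. = FALSE)
  no_seq <- setdiff(meta$id, ids)
  if (length(no_seq))
    stop("metadata rows without FASTA record: ",
         paste(no_seq, collapse = ", "), call. = FALSE)
  meta <- meta[match(ids, meta$id), ]
  meta$sequence <- toupper(as.character(seqs))
  meta$functional <- as.logical(meta$functional)
  meta$cys_codon_start <- as.integer(meta$cys_codon_start)
  meta$phe_codon_start <- as.integer(meta$phe_codon_start)
  new_reference(meta)
}

#' Write a reference back to FASTA + metadata
#'
#' Inverse of [load_reference()]; the round trip reproduces the reference
#' field by field.
#'
#' @param ref a `tcr_reference`.
#' @param fasta_path,metadata_path output paths.
#' @return `ref`, invisibly.
#' @export
write_reference <- function(ref, fasta_path, metadata_path) {
  seg <- ref$segments
  seqs <- Biostrings::DNAStringSet(seg$sequence)
  names(seqs) <- seg$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  utils::write.table(
    seg[, c("id", "chain", "class", "family", "functional",
            "cys_codon_start", "phe_codon_start")],
    metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ref)
}

#' Functional segments of one chain and class
#'
#' @param ref a `tcr_reference`.
#' @param chain `"alpha"` or `"beta"`.
#' @param seg_class one of `"V"`, `"J"`, `"C"`, `"SS"`, `"linker2A"`,
#'   `"vector_backbone"`.
#' @return tibble of matching functional segments, ordered by id.
#' @export
functional_segments <- function(ref, chain, seg_class) {
  stopifnot(inherits(ref, "tcr_reference"))
  if (!chain %in% CHAINS) stop("unknown chain: ", chain, call. = FALSE)
  if (!seg_class %in% SEG_CLASSES) stop("unknown class: ", seg_class,
                                        call. = FALSE)
  seg <- ref$segments
  out <- seg[!is.na(seg$chain) & seg$chain == chain &
               seg$class == seg_class & seg$functional, , drop = FALSE]
  out[order(out$id), ]
}

#' Per-locus counts of functional segments
#'
#' @param ref a `tcr_reference`.
#' @return tibble with columns `chain`, `class`, `n_functional`.
#' @export
locus_counts <- function(ref) {
  stopifnot(inherits(ref, "tcr_reference"))
  seg <- ref$segments
  seg <- seg[seg$functional & !is.na(seg$chain), ]
  out <- seg %>%
    group_by(.data$chain, .data$class) %>%
    summarise(n_functional = dplyr::n(), .groups = "drop") %>%
    arrange(.data$chain, .data$class)
  names(out)[1:2] <- c("chain", "class")
  out
}

#' Fetch one segment by id
#'
#' @param ref a `tcr_reference`.
#' @param id segment id.
#' @return single-row tibble.
#' @export
get_segment <- function(ref, id) {
  hit <- ref$segments[ref$segments$id == id, , drop = FALSE]
  if (nrow(hit) != 1L) stop("unknown segment id: ", id, call. = FALSE)
  hit
}

segment_seq <- function(ref, id) get_segment(ref, id)$sequence

#' @export
print.tcr_reference <- function(x, ...) {
  cat("<tcr_reference>", nrow(x$segments), "segments\n")
  print(locus_counts(x), n = Inf)
  invisible(x)
}
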