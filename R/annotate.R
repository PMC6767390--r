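#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_ext local-alignment scores; a gap of
#'   length L costs `gap_open + L * gap_ext`.
#' @param floor minimum best score below which a read is called no-hit
#'   (default 50, about 25 matched bases).
#' @return a `scoring` list.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                          gap_ext = 2, floor = 50) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, floor = floor), class = "align_scoring")
}

sub_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = TRUE)
}

#' Assign the best-matching gene segment to reads
#'
#' Aligns every candidate segment locally against every read
#' (match +2, mismatch -3, gap open -5, gap extend -2 by default) and
#' returns the arg-max hit per read; exact score ties break lexicographically
#' by segment id. Reads whose best score is below `scoring$floor` get an
#' `NA` hit.
#'
#' Reads containing a maximal-length candidate verbatim resolve without
#' dynamic programming: an exact full-length match scores `2 * length`,
#' which no other candidate of equal or shorter length can exceed, so the
#' shortcut returns exactly the arg-max the full sweep would.
#'
#' @param seqs character vector of read sequences.
#' @param candidates tibble of candidate segments (id, sequence, anchors), as
#'   from [functional_segments()].
#' @param scoring an [align_scoring()].
#' @return tibble, one row per read: segment_id, score, identity,
#'   read_start/read_end and seg_start/seg_end (1-based inclusive spans).
#' @export
assign_segment <- function(seqs, candidates, scoring = align_scoring()) {
  stopifnot(nrow(candidates) >= 1L)
  n <- length(seqs)
  ord <- order(candidates$id)           # lexicographic tie-break via which.max
  candidates <- candidates[ord, ]
  mat <- sub_matrix(scoring)
  reads_set <- Biostrings::DNAStringSet(seqs)
  out <- tibble(segment_id = rep(NA_character_, n), score = NA_real_,
                identity = NA_real_, read_start = NA_integer_,
                read_end = NA_integer_, seg_start = NA_integer_,
                seg_end = NA_integer_)

  ## exact-match shortcut for maximal-length candidates
  max_len <- max(nchar(candidates$sequence))
  resolved <- rep(FALSE, n)
  for (k in which(nchar(candidates$sequence) == max_len)) {
    pat <- candidates$sequence[k]
    if (2 * max_len < scoring$floor) break
    cnt <- Biostrings::vcountPattern(pat, reads_set)
    idx <- which(!resolved & cnt > 0L)
    if (!length(idx)) next
    pos <- vapply(idx, function(i)
      IRanges::start(Biostrings::matchPattern(pat, reads_set[[i]]))[1],
      integer(1))
    out$segment_id[idx] <- candidates$id[k]
    out$score[idx] <- 2 * max_len
    out$identity[idx] <- 1
    out$read_start[idx] <- pos
    out$read_end[idx] <- pos + max_len - 1L
    out$seg_start[idx] <- 1L
    out$seg_end[idx] <- max_len
    resolved[idx] <- TRUE
  }

  ## full score sweep over every candidate for the remaining reads, then
  ## traceback alignments only for each read's arg-max candidate
  todo <- which(!resolved)
  if (length(todo)) {
    sub_set <- reads_set[todo]
    score_m <- matrix(-Inf, length(todo), nrow(candidates))
    for (k in seq_len(nrow(candidates))) {
      score_m[, k] <- Biostrings::pairwiseAlignment(
        sub_set, Biostrings::DNAString(candidates$sequence[k]),
        type = "local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
        scoreOnly = TRUE)
    }
    best <- apply(score_m, 1L, which.max)   # first max = smallest id
    out$score[todo] <- score_m[cbind(seq_along(todo), best)]
    hit <- out$score >= scoring$floor
    for (k in unique(best[hit[todo]])) {
      sel <- best == k & hit[todo]
      idx <- todo[sel]
      aln <- Biostrings::pairwiseAlignment(
        reads_set[idx], Biostrings::DNAString(candidates$sequence[k]),
        type = "local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
      out$segment_id[idx] <- candidates$id[k]
      out$identity[idx] <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
      out$read_start[idx] <- IRanges::start(Biostrings::pattern(aln))
      out$read_end[idx] <- IRanges::end(Biostrings::pattern(aln))
      out$seg_start[idx] <- IRanges::start(Biostrings::subject(aln))
      out$seg_end[idx] <- IRanges::end(Biostrings::subject(aln))
    }
  }
  out
}

#' Extract the CDR3 junction between the V and J anchors
#'
#' The junction runs from the conserved V cysteine codon through the J FGxG
#' phenylalanine codon, both codons included. Productivity requires junction
#' length divisible by 3, intact anchors, and no stop codon in the junction
#' frame. Anchors falling outside the aligned spans flag the junction as
#' unresolved.
#'
#' @param seq read sequence (trimmed insert).
#' @param v_hit,j_hit single-row hit tibbles from [assign_segment()].
#' @param ref a `tcr_reference`.
#' @return list: cdr3_nt, cdr3_aa, productive, junction_unresolved.
#' @export
extract_cdr3 <- function(seq, v_hit, j_hit, ref) {
  unresolved <- list(cdr3_nt = NA_character_, cdr3_aa = NA_character_,
                     productive = FALSE, junction_unresolved = TRUE)
  if (is.na(v_hit$segment_id) || is.na(j_hit$segment_id)) return(unresolved)
  vseg <- get_segment(ref, v_hit$segment_id)
  jseg <- get_segment(ref, j_hit$segment_id)
  cys1 <- vseg$cys_codon_start + 1L               # 1-based codon start
  phe3 <- jseg$phe_codon_start + 3L               # 1-based codon end
  ## anchors must sit inside the aligned germline spans (no-gap mapping)
  if (cys1 < v_hit$seg_start || cys1 + 2L > v_hit$seg_end) return(unresolved)
  if (jseg$phe_codon_start + 1L < j_hit$seg_start ||
      phe3 > j_hit$seg_end) return(unresolved)
  start <- v_hit$read_start + (cys1 - v_hit$seg_start)
  end <- j_hit$read_start + (phe3 - j_hit$seg_start)
  if (end <= start || end > nchar(seq)) return(unresolved)
  cdr3 <- substr(seq, start, end)
  in_frame <- nchar(cdr3) %% 3L == 0L
  aa <- if (in_frame) translate_dna(cdr3) else NA_character_
  productive <- in_frame && !grepl("\\*", aa)
  list(cdr3_nt = cdr3, cdr3_aa = if (productive) aa else aa,
       productive = productive, junction_unresolved = FALSE)
}

## Per-column majority consensus over equal-length sequences; base ties
## break in A < C < G < T order.
majority_consensus <- function(seqs) {
  if (length(seqs) == 1L || length(unique(seqs)) == 1L) return(seqs[1])
  len <- as.integer(names(sort(table(nchar(seqs)), decreasing = TRUE))[1])
  seqs <- seqs[nchar(seqs) == len]
  m <- t(vapply(seqs, function(s) as.integer(charToRaw(s)), integer(len),
                USE.NAMES = FALSE))
  counts <- vapply(utf8ToInt("ACGT"), function(b) colSums(m == b),
                   numeric(len))
  paste(c("A", "C", "G", "T")[max.col(counts, ties.method = "first")],
        collapse = "")
}

#' Annotate demultiplexed wells into per-well chain records
#'
#' Every distinct read sequence is assigned a V and a J segment and a CDR3;
#' reads in a well are grouped by (V, J, CDR3), the dominant group defines
#' the record (ties break lexicographically), and its consensus sequence is
#' the per-column majority base call. Wells where the runner-up group holds
#' at least `doublet_frac` of reads and at least `doublet_min` reads are
#' flagged as potential doublets.
#'
#' @param wells demultiplexed well tibble from [demux()].
#' @param ref a `tcr_reference`.
#' @param scoring an [align_scoring()].
#' @param doublet_frac,doublet_min doublet-flag thresholds (0.2 / 2 reads).
#' @return chain-record tibble, one row per (well, chain): plate, row,
#'   row_label, col, chain, v_id, j_id, v_score, j_score, v_identity,
#'   j_identity, cdr3_nt, cdr3_aa, productive, junction_unresolved,
#'   n_reads_support, n_reads_total, doublet_flag, sequence (consensus).
#' @export
annotate_wells <- function(wells, ref, scoring = align_scoring(),
                           doublet_frac = 0.2, doublet_min = 2L) {
  if (nrow(wells) == 0L) return(empty_chain_records())
  recs <- lapply(CHAINS, function(ch) {
    sub <- wells[wells$chain == ch, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    uniq <- unique(sub$sequence)
    vh <- assign_segment(uniq, functional_segments(ref, ch, "V"), scoring)
    jh <- assign_segment(uniq, functional_segments(ref, ch, "J"), scoring)
    cd <- lapply(seq_along(uniq), function(i)
      extract_cdr3(uniq[i], vh[i, ], jh[i, ], ref))
    per_read <- tibble(
      u = match(sub$sequence, uniq),
      plate = sub$plate, row = sub$row, row_label = sub$row_label,
      col = sub$col)
    ann <- tibble(
      v_id = vh$segment_id, j_id = jh$segment_id,
      cdr3_nt = vapply(cd, `[[`, character(1), "cdr3_nt"))
    split_idx <- split(seq_len(nrow(per_read)),
                       paste(per_read$plate, per_read$row, per_read$col))
    out <- lapply(split_idx, function(ix) {
      u <- per_read$u[ix]
      a <- ann[u, ]
      valid <- !is.na(a$v_id) & !is.na(a$j_id) & !is.na(a$cdr3_nt)
      if (!any(valid)) return(NULL)
      u <- u[valid]; ix <- ix[valid]; a <- a[valid, ]
      key <- paste(a$v_id, a$j_id, a$cdr3_nt, sep = "|")
      cnt <- sort(table(key), decreasing = TRUE)
      dominant <- names(cnt)[1]
      total <- length(key)
      doublet <- length(cnt) > 1L &&
        cnt[2] >= doublet_frac * total && cnt[2] >= doublet_min
      sel <- key == dominant
      u_dom <- u[sel][1]
      cons <- majority_consensus(sub$sequence[ix[sel]])
      first <- which(sel)[1]
      cd1 <- cd[[u[first]]]
      tibble(
        plate = per_read$plate[ix[1]], row = per_read$row[ix[1]],
        row_label = per_read$row_label[ix[1]], col = per_read$col[ix[1]],
        chain = ch,
        v_id = a$v_id[first], j_id = a$j_id[first],
        v_score = vh$score[u_dom], j_score = jh$score[u_dom],
        v_identity = vh$identity[u_dom], j_identity = jh$identity[u_dom],
        cdr3_nt = a$cdr3_nt[first],
        cdr3_aa = cd1$cdr3_aa, productive = cd1$productive,
        junction_unresolved = cd1$junction_unresolved,
        n_reads_support = as.integer(cnt[1]),
        n_reads_total = as.integer(total),
        doublet_flag = doublet,
        sequence = cons)
    })
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out)) bind_rows(out) else NULL
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(empty_chain_records())
  arrange(bind_rows(recs), .data$plate, .data$row, .data$col, .data$chain)
}

empty_chain_records <- function() {
  tibble(plate = integer(), row = integer(), row_label = character(),
         col = integer(), chain = character(), v_id = character(),
         j_id = character(), v_score = numeric(), j_score = numeric(),
         v_identity = numeric(), j_identity = numeric(),
         cdr3_nt = character(), cdr3_aa = character(),
         productive = logical(), junction_unresolved = logical(),
         n_reads_support = integer(), n_reads_total = integer(),
         doublet_flag = logical(), sequence = character())
}
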