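#' Read-filtering configuration
#'
#' Defaults follow the platform's processing rule: keep assembled
#' reads with read-level quality strictly greater than 0.8 and assembled
#' length of 480-560 nt inclusive, after subsampling 50,000-100,000 reads
#' per 384-well plate.
#'
#' @param q_min quality threshold (strict `>`), in \[0, 1\].
#' @param len_min,len_max inclusive assembled-length window in nt.
#' @param subsample_per_plate reads retained per plate pool (NULL = all).
#' @param subsample_seed seed for the per-plate subsample.
#' @return a `filter_config` list.
#' @export
filter_config <- function(q_min = 0.8, len_min = 480L, len_max = 560L,
                          subsample_per_plate = 75000L,
                          subsample_seed = 1L) {
  stopifnot(q_min >= 0, q_min <= 1, len_min <= len_max)
  structure(list(q_min = q_min, len_min = as.integer(len_min),
                 len_max = as.integer(len_max),
                 subsample_per_plate = subsample_per_plate,
                 subsample_seed = subsample_seed), class = "filter_config")
}

## Best ungapped overlap merge of one read pair. Returns NULL on reject.
merge_one_pair <- function(s1, q1, s2, q2, min_overlap, min_identity) {
  s2rc <- revcomp(s2)
  q2r <- rev(string_to_phred(q2))
  q1v <- string_to_phred(q1)
  r1 <- charToRaw(s1); r2 <- charToRaw(s2rc)
  n1 <- length(r1); n2 <- length(r2)
  best_o <- 0L; best_score <- -Inf; best_match <- 0L
  for (o in seq.int(min_overlap, min(n1, n2))) {
    m <- sum(r1[(n1 - o + 1L):n1] == r2[1:o])
    score <- 2L * m - o                     # matches - mismatches
    if (score > best_score) { best_score <- score; best_o <- o; best_match <- m }
  }
  if (best_o == 0L || best_match / best_o < min_identity) return(NULL)
  o <- best_o
  i1 <- (n1 - o + 1L):n1
  a <- r1[i1]; b <- r2[1:o]
  qa <- q1v[i1]; qb <- q2r[1:o]
  agree <- a == b
  merged <- a
  take_b <- !agree & qb > qa
  merged[take_b] <- b[take_b]
  mq <- ifelse(agree, pmin(qa + qb, 60L), abs(qa - qb))
  seq <- paste0(substr(s1, 1L, n1 - o), rawToChar(as.raw(merged)),
                substr(s2rc, o + 1L, n2))
  qual <- c(q1v[seq_len(n1 - o)], mq, q2r[seq.int(o + 1L, length.out = n2 - o)])
  p_err <- 10^(-qual / 10)
  list(seq = seq, qual = qual,
       assembly_quality = exp(mean(log(1 - p_err))))
}

#' Merge paired-end mates by maximal ungapped overlap
#'
#' Finds the maximal-score ungapped overlap (score = matches - mismatches) of
#' at least `min_overlap` nt between mate 1 and the reverse complement of
#' mate 2. Disagreements in the overlap resolve to the higher-quality base;
#' agreeing bases get the capped sum of both qualities, disagreeing bases the
#' absolute quality difference. The read-level `assembly_quality` is the
#' geometric mean over bases of (1 - error probability), a PandaSeq-like
#' score in \[0, 1\]. Pairs whose best overlap identity falls below
#' `min_identity` are rejected.
#'
#' @param pairs tibble with seq1, qual1, seq2, qual2 (and optionally id).
#' @param min_overlap minimum overlap length in nt (default 30).
#' @param min_identity minimum fraction of matching bases in the overlap.
#' @return tibble of assembled reads: id, sequence, qual (Phred string),
#'   length, assembly_quality; rejected pairs are dropped and counted in the
#'   `n_rejected` attribute.
#' @export
merge_pairs <- function(pairs, min_overlap = 30L, min_identity = 0.8) {
  ids <- pairs$id %||% as.character(seq_len(nrow(pairs)))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    m <- merge_one_pair(pairs$seq1[i], pairs$qual1[i],
                        pairs$seq2[i], pairs$qual2[i],
                        min_overlap, min_identity)
    if (!is.null(m)) {
      out[[i]] <- tibble(id = ids[i], sequence = m$seq,
                         qual = phred_to_string(m$qual),
                         length = nchar(m$seq),
                         assembly_quality = m$assembly_quality)
    }
  }
  keep <- !vapply(out, is.null, logical(1))
  res <- if (any(keep)) bind_rows(out[keep]) else
    tibble(id = character(), sequence = character(), qual = character(),
           length = integer(), assembly_quality = numeric())
  attr(res, "n_rejected") <- sum(!keep)
  res
}

#' Apply the quality/length filter
#'
#' A read is kept iff `assembly_quality > q_min` (strict) and
#' `len_min <= length <= len_max` (inclusive). Idempotent.
#'
#' @param reads assembled-read tibble from [merge_pairs()].
#' @param cfg a [filter_config()].
#' @return list with `kept` and `dropped` tibbles; `dropped` carries a
#'   `reason` column (`quality`, `length`).
#' @export
filter_reads <- function(reads, cfg = filter_config()) {
  ok_q <- reads$assembly_quality > cfg$q_min
  ok_l <- reads$length >= cfg$len_min & reads$length <= cfg$len_max
  reason <- ifelse(!ok_l, "length", ifelse(!ok_q, "quality", NA_character_))
  list(kept = reads[ok_q & ok_l, , drop = FALSE],
       dropped = mutate(reads[!(ok_q & ok_l), , drop = FALSE],
                        reason = reason[!(ok_q & ok_l)]))
}

#' Uniform per-plate subsample without replacement
#'
#' @param reads assembled-read tibble.
#' @param n reads to retain; if `n >= nrow(reads)` all are returned.
#' @param seed integer seed.
#' @return subset tibble, input order preserved.
#' @export
subsample_plate <- function(reads, n, seed = 1L) {
  stopifnot(n >= 0)
  if (n >= nrow(reads)) return(reads)
  with_seed(seed, {
    keep <- sort(sample.int(nrow(reads), n))
    reads[keep, , drop = FALSE]
  })
}

## Chain call by local alignment against the constant-region stubs.
## Vectorized: two pairwiseAlignment calls over all reads.
call_chain <- function(seqs, schema, min_margin = 5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  sc <- function(stub) Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(stub),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  sa <- sc(schema$c_stub$alpha)
  sb <- sc(schema$c_stub$beta)
  ifelse(abs(sa - sb) < min_margin, "ambiguous_chain",
         ifelse(sa > sb, "alpha", "beta"))
}

#' Demultiplex assembled reads to wells
#'
#' Reads the forward (column) tag from the 5' end and the reverse (row) tag
#' from the reverse complement of the 3' end, decodes the pair through the
#' layout with up to `max_mismatch` substitutions per tag, trims tags and
#' universal linker, and infers the chain from the best-scoring
#' constant-region stub (minimum score margin 5; ties rejected as
#' `ambiguous_chain`).
#'
#' @param reads assembled-read tibble (id, sequence, qual, ...).
#' @param layout a `plate_layout`.
#' @param schema an [amplicon_schema()].
#' @param max_mismatch substitutions tolerated per tag (default 1).
#' @return list with `wells` (tibble: id, plate, row, row_label, col, chain,
#'   sequence trimmed of tags/linker, assembly_quality) and `stats` (tibble
#'   of per-category counts; categories sum to the input count).
#' @export
demux <- function(reads, layout, schema, max_mismatch = 1L) {
  n <- nrow(reads)
  tl <- schema$tag_length
  lk <- nchar(schema$universal_linker)
  status <- character(n)
  plate <- integer(n); row <- integer(n); col <- integer(n)
  row_label <- character(n)
  ## vectorized tag matching: byte matrices of the layout tags, one
  ## mismatch-count sweep per read (same semantics as decode_tags)
  tag_mat <- function(tags) t(vapply(tags, function(t)
    as.integer(charToRaw(t)), integer(tl)))
  fm <- tag_mat(layout$fwd_tags$tags[seq_len(layout$n_fwd_used)])
  rm_ <- tag_mat(layout$rev_tags$tags[seq_len(layout$n_rev_used)])
  m <- layout$well_map
  well_lookup <- matrix(NA_integer_, nrow(rm_), nrow(fm))
  well_lookup[cbind(m$rev_idx, m$fwd_idx)] <- seq_len(nrow(m))
  match_axis <- function(obs, tm) {
    d <- rowSums(tm != matrix(as.integer(charToRaw(obs)), nrow(tm), tl,
                              byrow = TRUE))
    which(d <= max_mismatch)
  }
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    if (nchar(s) < 2L * tl + lk + 1L) { status[i] <- "unknown_fwd"; next }
    fi <- match_axis(substr(s, 1L, tl), fm)
    ri <- match_axis(revcomp(substr(s, nchar(s) - tl + 1L, nchar(s))), rm_)
    if (length(fi) > 1L || length(ri) > 1L) { status[i] <- "ambiguous"; next }
    if (length(fi) == 0L) { status[i] <- "unknown_fwd"; next }
    if (length(ri) == 0L) { status[i] <- "unknown_rev"; next }
    wi <- well_lookup[ri, fi]
    if (is.na(wi)) { status[i] <- "unknown_fwd"; next }
    status[i] <- "assigned"
    plate[i] <- m$plate[wi]; row[i] <- m$row[wi]; col[i] <- m$col[wi]
    row_label[i] <- m$row_label[wi]
  }
  assigned <- status == "assigned"
  trimmed <- substr(reads$sequence[assigned], tl + lk + 1L,
                    nchar(reads$sequence[assigned]) - tl)
  chain <- if (any(assigned)) call_chain(trimmed, schema) else character(0)
  wells <- tibble(
    id = reads$id[assigned], plate = plate[assigned], row = row[assigned],
    row_label = row_label[assigned], col = col[assigned],
    chain = chain, sequence = trimmed,
    assembly_quality = reads$assembly_quality[assigned])
  bad_chain <- wells$chain == "ambiguous_chain"
  stats <- tibble(
    category = c("assigned", "unknown_fwd", "unknown_rev", "ambiguous",
                 "ambiguous_chain"),
    n = c(sum(assigned) - sum(bad_chain),
          sum(status == "unknown_fwd"), sum(status == "unknown_rev"),
          sum(status == "ambiguous"), sum(bad_chain)))
  list(wells = wells[!bad_chain, , drop = FALSE], stats = stats)
}
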