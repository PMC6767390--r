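make_pair <- function(insert, read_len = 300L, q = 37L) {
  L <- nchar(insert)
  tibble::tibble(
    id = "p1",
    seq1 = substr(insert, 1, read_len),
    qual1 = pairtcr:::phred_to_string(rep(q, read_len)),
    seq2 = revcomp(substr(insert, L - read_len + 1, L)),
    qual2 = pairtcr:::phred_to_string(rep(q, read_len)))
}

test_that("error-free mates reconstruct the insert exactly", {
  set.seed(1)
  insert <- random_seq(500)
  m <- merge_pairs(make_pair(insert))
  expect_equal(nrow(m), 1L)
  expect_equal(m$sequence, insert)
  expect_equal(m$length, 500L)
  expect_gt(m$assembly_quality, 0.999)
})

test_that("overlap disagreements resolve to the higher-quality base", {
  set.seed(2)
  insert <- random_seq(500)
  p <- make_pair(insert)
  ## put a Q10 error in mate 1 inside the overlap (positions 201-300 of r1)
  pos <- 250L
  truth <- substr(p$seq1, pos, pos)
  substr(p$seq1, pos, pos) <- setdiff(c("A", "C", "G", "T"), truth)[1]
  q1 <- pairtcr:::string_to_phred(p$qual1); q1[pos] <- 10L
  p$qual1 <- pairtcr:::phred_to_string(q1)
  ## mate 2 keeps Q37 at that base -> its (correct) base must win
  m <- merge_pairs(p)
  expect_equal(m$sequence, insert)

  ## and symmetrically: degrade mate 2 instead, mate 1 base wins
  p2 <- make_pair(insert)
  pos2 <- nchar(insert) - pos + 1L          # same column, mate-2 coordinates
  truth2 <- substr(p2$seq2, pos2, pos2)
  substr(p2$seq2, pos2, pos2) <- setdiff(c("A", "C", "G", "T"), truth2)[1]
  q2 <- pairtcr:::string_to_phred(p2$qual2); q2[pos2] <- 10L
  p2$qual2 <- pairtcr:::phred_to_string(q2)
  m2 <- merge_pairs(p2)
  expect_equal(m2$sequence, insert)
})

test_that("unrelated mates are rejected by exhaustive overlap scan", {
  set.seed(3)
  p <- tibble::tibble(id = "x",
                      seq1 = random_seq(300),
                      qual1 = pairtcr:::phred_to_string(rep(37L, 300)),
                      seq2 = random_seq(300),
                      qual2 = pairtcr:::phred_to_string(rep(37L, 300)))
  m <- merge_pairs(p)
  expect_equal(nrow(m), 0L)
  expect_equal(attr(m, "n_rejected"), 1L)
})

test_that("filtering is idempotent and records drop reasons", {
  reads <- tibble::tibble(
    id = as.character(1:4),
    sequence = strrep("A", c(500, 470, 500, 570)),
    qual = "", length = c(500L, 470L, 500L, 570L),
    assembly_quality = c(0.95, 0.95, 0.5, 0.95))
  f1 <- filter_reads(reads)
  expect_equal(f1$kept$id, "1")
  expect_equal(f1$dropped$reason[f1$dropped$id == "2"], "length")
  expect_equal(f1$dropped$reason[f1$dropped$id == "3"], "quality")
  f2 <- filter_reads(f1$kept)
  expect_identical(f2$kept, f1$kept)
  expect_equal(nrow(f2$dropped), 0L)
})

test_that("per-plate subsampling is uniform, deterministic and boundary-safe", {
  reads <- tibble::tibble(id = as.character(1:200), sequence = "A",
                          qual = "", length = 1L, assembly_quality = 1)
  s <- subsample_plate(reads, 50, seed = 42)
  expect_equal(nrow(s), 50L)
  expect_equal(anyDuplicated(s$id), 0L)
  expect_identical(s, subsample_plate(reads, 50, seed = 42))
  expect_equal(nrow(subsample_plate(reads, 0, seed = 1)), 0L)
  expect_identical(subsample_plate(reads, 500, seed = 1), reads)

  ## retention frequency of one read across seeds is binomial around n/N
  hits <- vapply(1:40, function(s)
    "7" %in% subsample_plate(reads, 150, seed = s)$id, logical(1))
  p <- 150 / 200
  expect_lt(abs(mean(hits) - p), 3 * sqrt(p * (1 - p) / 40))
})

test_that("demultiplexing conserves counts and survives single-base tag errors", {
  ref <- small_ref()
  layout <- one_plate_layout()
  schema <- amplicon_schema(ref)
  cfg <- sim_config(n_plates = 1, n_wells = 12, reads_per_well = 3,
                    chain_dropout_alpha = 0, chain_dropout_beta = 0,
                    error_rate = 0, seed = 13)
  run <- simulate_run(ref, layout, cfg)
  merged <- merge_pairs(run$reads)

  ## inject one substitution into every forward tag
  corrupted <- merged
  for (i in seq_len(nrow(corrupted))) {
    b <- substr(corrupted$sequence[i], 3, 3)
    substr(corrupted$sequence[i], 3, 3) <-
      setdiff(c("A", "C", "G", "T"), b)[1]
  }
  dm <- demux(corrupted, layout, schema, max_mismatch = 1)
  expect_equal(sum(dm$stats$n), nrow(corrupted))
  expect_equal(dm$stats$n[dm$stats$category == "assigned"], nrow(corrupted))

  ## scrambled tags are all rejected and counts still conserve
  scrambled <- merged
  scrambled$sequence <- paste0(strrep("A", 8),
                               substr(scrambled$sequence, 9,
                                      nchar(scrambled$sequence)))
  dm2 <- demux(scrambled, layout, schema, max_mismatch = 1)
  expect_equal(sum(dm2$stats$n), nrow(scrambled))
  expect_equal(dm2$stats$n[dm2$stats$category == "assigned"], 0L)

  ## chain inference agrees with the simulator's chain labels
  dm3 <- demux(merged, layout, schema)
  truth_chain <- ifelse(grepl(":alpha:", dm3$wells$id), "alpha", "beta")
  expect_equal(dm3$wells$chain, truth_chain)
})
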