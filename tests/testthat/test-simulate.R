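test_that("clonotype sampling is seeded, uniform over segments, and honours anchors", {
  ref <- small_ref()
  set.seed(7); c1 <- sample_clonotype(ref)
  set.seed(7); c2 <- sample_clonotype(ref)
  expect_identical(c1, c2)

  ## junction starts at the V cysteine codon and ends at the J FGxG codon
  v <- get_segment(ref, c1$v_alpha); j <- get_segment(ref, c1$j_alpha)
  expect_equal(substr(c1$junction_alpha, 1, 3),
               substr(v$sequence, v$cys_codon_start + 1, v$cys_codon_start + 3))
  jl <- nchar(c1$junction_alpha)
  expect_equal(substr(c1$junction_alpha, jl - 2, jl),
               substr(j$sequence, j$phe_codon_start + 1, j$phe_codon_start + 3))

  ## restricting the locus forces the segment choice
  tiny <- synthetic_locus(seed = 3, n_v_alpha = 1, n_j_alpha = 1,
                          n_v_beta = 1, n_j_beta = 1, n_families = 1)
  set.seed(1)
  cs <- replicate(20, sample_clonotype(tiny), simplify = FALSE)
  expect_true(all(vapply(cs, `[[`, character(1), "v_alpha") == "TRAV01"))
  expect_true(all(vapply(cs, `[[`, character(1), "j_alpha") == "TRAJ01"))
})

test_that("force_productive clonotypes all pass an independent productivity scan", {
  ref <- small_ref()
  set.seed(11)
  for (k in 1:1000) {
    cl <- sample_clonotype(ref, force_productive = TRUE)
    for (ch in c("alpha", "beta")) {
      junc <- if (ch == "alpha") cl$junction_alpha else cl$junction_beta
      chain <- if (ch == "alpha") cl$chain_alpha else cl$chain_beta
      expect_equal(nchar(junc) %% 3, 0)
      ## independent translate-and-scan of the full chain frame
      expect_false(grepl("\\*", as.character(Biostrings::translate(
        Biostrings::DNAString(substr(chain, 1, nchar(chain) - nchar(chain) %% 3))))))
    }
  }
})

test_that("an error-free dropout-free run emits the exact read count and decodes to truth", {
  ref <- small_ref()
  layout <- one_plate_layout()
  cfg <- sim_config(n_plates = 1, n_wells = 10, reads_per_well = 5,
                    chain_dropout_alpha = 0, chain_dropout_beta = 0,
                    error_rate = 0, seed = 3)
  run <- simulate_run(ref, layout, cfg)
  expect_equal(nrow(run$reads), 10 * 2 * 5)

  schema <- amplicon_schema(ref)
  merged <- merge_pairs(run$reads)
  expect_equal(attr(merged, "n_rejected"), 0L)
  dm <- demux(merged, layout, schema)
  expect_equal(dm$stats$n[dm$stats$category == "assigned"], 100L)
  ## every read decodes to its ground-truth well (well id is in the read id)
  got <- sprintf("sim:p%02d%s%02d", dm$wells$plate, dm$wells$row_label,
                 dm$wells$col)
  expect_true(all(startsWith(dm$wells$id, got)))
})

test_that("degenerate dropout removes exactly the affected chain", {
  ref <- small_ref()
  layout <- one_plate_layout()
  cfg <- sim_config(n_plates = 1, n_wells = 8, reads_per_well = 3,
                    chain_dropout_alpha = 1, chain_dropout_beta = 0,
                    error_rate = 0, seed = 5)
  run <- simulate_run(ref, layout, cfg)
  expect_false(any(grepl(":alpha:", run$reads$id)))
  expect_equal(sum(grepl(":beta:", run$reads$id)), 8 * 3)
})

test_that("the same seed reproduces byte-identical FASTQ output", {
  ref <- small_ref()
  layout <- one_plate_layout()
  cfg <- sim_config(n_plates = 1, n_wells = 5, reads_per_well = 2, seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_run(ref, layout, cfg, dir = d1)
  simulate_run(ref, layout, cfg, dir = d2)
  for (f in c("reads_R1.fastq", "reads_R2.fastq")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("empirical substitution rate matches the configured rate within 3 sigma", {
  ref <- small_ref()
  layout <- one_plate_layout()
  rate <- 0.005
  cfg <- sim_config(n_plates = 1, n_wells = 30, reads_per_well = 6,
                    chain_dropout_alpha = 0, chain_dropout_beta = 0,
                    error_rate = rate, seed = 17)
  run <- simulate_run(ref, layout, cfg)
  schema <- amplicon_schema(ref)
  gt <- run$ground_truth
  mism <- 0L; total <- 0L
  for (i in seq_len(nrow(gt))) {
    for (ch in c("alpha", "beta")) {
      amp <- truth_amplicon(gt[i, ], ch, ref, layout, schema)
      ids <- sprintf("sim:p%02d%s%02d:%s", gt$plate[i], gt$row_label[i],
                     gt$col[i], ch)
      rr <- run$reads[startsWith(run$reads$id, ids), ]
      if (nrow(rr) == 0) next
      truth1 <- substr(amp, 1, nchar(rr$seq1[1]))
      truth2 <- revcomp(substr(amp, nchar(amp) - nchar(rr$seq2[1]) + 1,
                               nchar(amp)))
      for (k in seq_len(nrow(rr))) {
        mism <- mism + hamming(rr$seq1[k], truth1) + hamming(rr$seq2[k], truth2)
        total <- total + nchar(truth1) + nchar(truth2)
      }
    }
  }
  expect_gt(total, 1e5)
  sigma <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(mism / total - rate), 3 * sigma)
})

test_that("assembled amplicon lengths fall inside the accepted filter window", {
  ref <- full_ref()
  layout <- one_plate_layout()
  cfg <- sim_config(n_plates = 1, n_wells = 20, reads_per_well = 1,
                    chain_dropout_alpha = 0, chain_dropout_beta = 0,
                    error_rate = 0, seed = 21)
  run <- simulate_run(ref, layout, cfg)
  merged <- merge_pairs(run$reads)
  schema <- amplicon_schema(ref)
  expect_true(all(merged$length >= schema$insert_range[1]))
  expect_true(all(merged$length <= schema$insert_range[2]))
  expect_true(all(merged$length >= 480 & merged$length <= 560))
})
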