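productive_pair <- function(ref, seed = 30) {
  set.seed(seed)
  pair_from_clonotype(sample_clonotype(ref, force_productive = TRUE))
}

test_that("fragment design reverts to germline outside the observed junction", {
  ref <- full_ref()
  pair <- productive_pair(ref)
  cfg <- construct_config()
  frags <- design_fragments(pair, ref, cfg)

  ## all four homology tails have the configured length
  expect_equal(nchar(frags$valpha$left_homology), 20L)
  expect_equal(nchar(frags$valpha$right_homology), 20L)
  expect_equal(nchar(frags$vbeta$left_homology), 20L)
  expect_equal(nchar(frags$vbeta$right_homology), 20L)
  ## homology regions are prefix/suffix of the fragment sequence
  expect_true(startsWith(frags$valpha$sequence, frags$valpha$left_homology))
  expect_true(endsWith(frags$valpha$sequence, frags$valpha$right_homology))

  ## the fragment core equals germline V + observed junction + germline J,
  ## composed independently from the reference
  v <- get_segment(ref, pair$alpha_v_id)
  j <- get_segment(ref, pair$alpha_j_id)
  expected <- paste0(substr(v$sequence, 1, v$cys_codon_start),
                     pair$alpha_cdr3_nt,
                     substr(j$sequence, j$phe_codon_start + 4,
                            nchar(j$sequence)))
  core <- substr(frags$valpha$sequence, 21, nchar(frags$valpha$sequence) - 20)
  expect_equal(core, expected)

  ## primer-region substitutions in the observed consensus leave the
  ## fragment 5' end germline: the designed core never depends on bases
  ## outside the junction, so corrupt consensus V bases cannot leak in
  expect_equal(substr(core, 1, 21), substr(v$sequence, 1, 21))

  ## chain-completeness and productivity preconditions
  aonly <- pair; aonly$beta_v_id <- NA_character_
  expect_error(design_fragments(aonly, ref, cfg), "beta")
  improd <- pair; improd$alpha_productive <- FALSE
  expect_error(design_fragments(improd, ref, cfg), "productive")
})

test_that("vector selection is a keyed bijection over the 13-vector library", {
  ref <- full_ref()
  lib <- vector_library(ref)
  expect_length(lib, 13L)
  expect_equal(anyDuplicated(vapply(lib, `[[`, character(1), "sequence")), 0L)
  v <- functional_segments(ref, "alpha", "V")
  for (i in seq_len(nrow(v))) {
    vec <- select_vector(v$id[i], lib, ref)
    expect_equal(vec$family, v$family[i])
  }
  expect_error(select_vector("TRAV01", lib["TRAVF02"], ref), "covers")
})

test_that("assembly is seamless, ordered, and deterministic", {
  ref <- full_ref()
  pair <- productive_pair(ref, seed = 31)
  cfg <- construct_config()
  frags <- design_fragments(pair, ref, cfg)
  vec <- select_vector(pair$alpha_v_id, vector_library(ref), ref)
  con <- assemble(frags, vec, cfg)

  ## total length = vector + sum(fragments) - 4 * homology (exact)
  expect_equal(nchar(con$sequence),
               nchar(vec$sequence) +
                 sum(vapply(frags, function(f) nchar(f$sequence),
                            numeric(1))) - 4L * cfg$homology)

  ## feature-order scan: spans tile the circle in the stated cassette order
  feats <- refine_features(con, ref)
  expect_equal(
    feats$feature,
    c("backbone5", "SSalpha", "Valpha", "Calpha", "P2A", "SSbeta",
      "Vbeta", "Cbeta", "backbone3"))
  expect_true(all(feats$start[-1] == utils::head(feats$end, -1)))
  ## each feature substring matches its source component
  ssa <- substr(con$sequence, feats$start[2] + 1, feats$end[2])
  expect_equal(ssa, vec$ssa_seq)
  p2a <- substr(con$sequence, feats$start[5] + 1, feats$end[5])
  expect_equal(p2a, get_segment(ref, "P2A")$sequence)

  ## determinism
  expect_identical(assemble(frags, vec, cfg)$sequence, con$sequence)

  ## corrupted left tail of the beta fragment names the failing junction
  broken <- frags
  s <- broken$vbeta$sequence
  substr(s, 1, 1) <- if (substr(s, 1, 1) == "A") "C" else "A"
  broken$vbeta$sequence <- s
  expect_error(assemble(broken, vec, cfg), "SSbeta-Vbeta")
})

test_that("assembled constructs translate in frame with the CDR3s intact", {
  ref <- full_ref()
  pair <- productive_pair(ref, seed = 32)
  res <- clone_pair(pair, ref)
  val <- res$validation
  expect_true(val$in_frame)
  expect_length(val$premature_stops, 0L)
  expect_true(val$p2a_in_frame)
  ## observed CDR3 amino-acid strings appear verbatim in the translation
  expect_true(grepl(pair$alpha_cdr3_aa, val$protein, fixed = TRUE))
  expect_true(grepl(pair$beta_cdr3_aa, val$protein, fixed = TRUE))
  ## independent oracle: translate the ORF substring directly
  f <- res$construct$features
  orf <- substr(res$construct$sequence,
                f$start[f$feature == "SSalpha"] + 1,
                f$end[f$feature == "Cbeta"])
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(orf)))
  expect_equal(val$protein, prot)
  expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
  expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
})

test_that("screen product arithmetic is exact on a toy template", {
  cfg <- construct_config()
  ## place primers at hand-counted offsets on a 200 bp toy template:
  ## fw starts at position 11, rc(rev) occupies positions 151-167
  set.seed(33)
  toy <- paste0(random_seq(10), cfg$primer_fw, random_seq(120),
                revcomp(cfg$primer_rev), random_seq(33))
  expect_equal(predict_screen_amplicon(list(sequence = toy), cfg),
               167L - 11L + 1L)
  ## absent or duplicated sites are errors with the site count
  expect_error(predict_screen_amplicon(list(sequence = random_seq(200)), cfg),
               "count 0")
  dup <- paste0(toy, cfg$primer_fw)
  expect_error(predict_screen_amplicon(list(sequence = dup), cfg), "count 2")
})
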