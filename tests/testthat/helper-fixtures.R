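## Shared fixtures and independent oracles. Fixtures are built in code, once
## per test run, and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_env)) assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

## Small locus for unit tests (fast alignment), full locus for end-to-end.
small_ref <- function() cached("small_ref", synthetic_locus(
  seed = 101L, n_v_alpha = 4L, n_j_alpha = 3L, n_v_beta = 4L, n_j_beta = 3L,
  n_families = 4L))

full_ref <- function() cached("full_ref", synthetic_locus())

one_plate_layout <- function() cached("one_plate_layout", build_layout(
  1L, generate_barcodes(24, seed = 11), generate_barcodes(16, seed = 22)))

## --- independent oracles ---------------------------------------------------

## Affine-gap Smith-Waterman best local score, plain dynamic programming.
## A gap of length L costs open + ext * L.
sw_oracle <- function(p, s, match = 2, mismatch = -3, open = 5, ext = 2) {
  P <- strsplit(p, "")[[1]]; S <- strsplit(s, "")[[1]]
  np <- length(P); ns <- length(S)
  H <- matrix(0, np + 1, ns + 1)
  E <- matrix(-Inf, np + 1, ns + 1)
  F <- matrix(-Inf, np + 1, ns + 1)
  best <- 0
  for (i in 2:(np + 1)) for (j in 2:(ns + 1)) {
    sc <- if (P[i - 1] == S[j - 1]) match else mismatch
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
    if (H[i, j] > best) best <- H[i, j]
  }
  best
}

## Fine-grid midpoint-rule integration of the piecewise-linear mean curve.
## Midpoint error is O(h^2) and concentrated at the curve's kinks, so 1e6
## cells put it well below 1e-9 on these scales.
riemann_auc <- function(conc, resp, n_grid = 1e6) {
  m <- aggregate(resp, list(conc = conc), mean)
  m <- m[order(m$conc), ]
  y <- pmax(m$x, 0)
  f <- approxfun(m$conc, y)
  brk <- seq(min(m$conc), max(m$conc), length.out = n_grid + 1)
  h <- diff(brk)
  sum(f((head(brk, -1) + tail(brk, -1)) / 2) * h)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

## Sense-strand amplicon rebuilt from ground truth, independent of the
## simulator's internals.
truth_amplicon <- function(gt_row, chain, ref, layout, schema) {
  v <- if (chain == "alpha") gt_row$v_alpha else gt_row$v_beta
  j <- if (chain == "alpha") gt_row$j_alpha else gt_row$j_beta
  junc <- if (chain == "alpha") gt_row$junction_alpha else gt_row$junction_beta
  vseg <- get_segment(ref, v); jseg <- get_segment(ref, j)
  chain_seq <- paste0(substr(vseg$sequence, 1, vseg$cys_codon_start), junc,
                      substr(jseg$sequence, jseg$phe_codon_start + 4,
                             nchar(jseg$sequence)))
  tags <- well_tags(layout, gt_row$plate, gt_row$row, gt_row$col)
  paste0(tags$fwd, schema$universal_linker, chain_seq,
         schema$c_stub[[chain]], revcomp(tags$rev))
}

## Minimal chain-record rows for repertoire tests.
fake_record <- function(plate, row, col, chain, v = "TRAV01", j = "TRAJ01",
                        cdr3 = "TGTGCTTTTGGCTCTGGC") {
  tibble::tibble(plate = plate, row = row, row_label = LETTERS[row],
                 col = col, chain = chain, v_id = v, j_id = j,
                 v_score = 600, j_score = 114, v_identity = 1,
                 j_identity = 1, cdr3_nt = cdr3,
                 cdr3_aa = translate_dna(cdr3), productive = TRUE,
                 junction_unresolved = FALSE, n_reads_support = 5L,
                 n_reads_total = 5L, doublet_flag = FALSE,
                 sequence = cdr3)
}
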