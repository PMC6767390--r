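#' Simulation configuration
#'
#' Defaults emulate one pooled MiSeq run of sorted 384-well plates: most
#' wells receive a cell, each well-chain amplicon is sequenced by a fixed
#' number of 2x300 nt read pairs, and per-chain dropout reproduces the
#' observed per-chain recovery of well-based paired TCR sequencing (alpha
#' ~65%, beta ~75%, paired ~49% of sorted cells).
#'
#' @param n_plates number of plates.
#' @param n_wells number of filled wells per plate (default 346, ~90%).
#' @param reads_per_well read pairs emitted per well and chain.
#' @param chain_dropout_alpha,chain_dropout_beta probability that a well
#'   yields no reads for that chain (RT/PCR failure collapsed into one knob).
#' @param error_rate i.i.d. per-base substitution probability.
#' @param read_length mate length in nt.
#' @param doublet_rate probability a well received two cells.
#' @param force_productive resample clonotypes until both chains are
#'   productive (sorted cells express a surface TCR, so default TRUE).
#' @param populations phenotype class labels sampled per well.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_plates = 1L, n_wells = 346L, reads_per_well = 80L,
                       chain_dropout_alpha = 0.35, chain_dropout_beta = 0.25,
                       error_rate = 0.003, read_length = 300L,
                       doublet_rate = 0, force_productive = TRUE,
                       populations = c("CD4", "ActCD4", "Tfh", "Treg",
                                       "ActCD8"),
                       seed = 1L) {
  stopifnot(chain_dropout_alpha >= 0, chain_dropout_alpha <= 1,
            chain_dropout_beta >= 0, chain_dropout_beta <= 1,
            error_rate >= 0, error_rate <= 1, doublet_rate >= 0,
            doublet_rate <= 1, reads_per_well >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Sample one clonotype from a reference
#'
#' V and J segments are drawn uniformly from the functional segments of each
#' chain; the junction is the V end (from the conserved cysteine codon)
#' plus 0-10 random non-templated nucleotides plus the J start (through the
#' FGxG phenylalanine codon). Productivity requires junction length divisible
#' by 3 and no stop codon in the chain reading frame.
#'
#' @param ref a `tcr_reference`.
#' @param force_productive resample until both chains are productive.
#' @param population_label phenotype label to attach.
#' @return a `clonotype` list (segment ids, junctions, full V..J chain
#'   sequences, productivity flags).
#' @export
sample_clonotype <- function(ref, force_productive = FALSE,
                             population_label = NA_character_) {
  draw_chain <- function(chain) {
    v <- functional_segments(ref, chain, "V")
    j <- functional_segments(ref, chain, "J")
    stopifnot(nrow(v) > 0, nrow(j) > 0)
    vi <- v[sample.int(nrow(v), 1L), ]
    ji <- j[sample.int(nrow(j), 1L), ]
    n_len <- sample(0:10, 1L)
    n_seq <- if (n_len > 0) random_dna(n_len) else ""
    chain_seq <- paste0(vi$sequence, n_seq, ji$sequence)
    junc_start <- vi$cys_codon_start + 1L          # 1-based
    junc_end <- nchar(vi$sequence) + n_len + ji$phe_codon_start + 3L
    junction <- substr(chain_seq, junc_start, junc_end)
    productive <- nchar(junction) %% 3L == 0L &&
      !grepl("\\*", translate_dna(chain_seq))
    list(v = vi$id, j = ji$id, junction = junction,
         chain_seq = chain_seq, productive = productive)
  }
  repeat {
    a <- draw_chain("alpha")
    b <- draw_chain("beta")
    if (!force_productive || (a$productive && b$productive)) break
  }
  structure(list(
    v_alpha = a$v, j_alpha = a$j, junction_alpha = a$junction,
    chain_alpha = a$chain_seq, productive_alpha = a$productive,
    v_beta = b$v, j_beta = b$j, junction_beta = b$junction,
    chain_beta = b$chain_seq, productive_beta = b$productive,
    population_label = population_label
  ), class = "clonotype")
}

## Full sense-strand amplicon for one chain of a clonotype.
build_amplicon <- function(clono, chain, schema, fwd_tag, rev_tag) {
  chain_seq <- if (chain == "alpha") clono$chain_alpha else clono$chain_beta
  paste0(fwd_tag, schema$universal_linker, chain_seq,
         schema$c_stub[[chain]], revcomp(rev_tag))
}

## Apply i.i.d. substitution errors and draw two-state Phred qualities.
## Low state ~ Q12 (error 0.063), high state ~ Q37 (error 2e-4); the state
## mix is solved so the marginal substitution rate equals `rate`.
mutate_read <- function(seq, rate) {
  n <- nchar(seq)
  e_low <- 10^(-1.2); e_high <- 10^(-3.7)
  if (rate <= e_high) {
    state_low <- rep(FALSE, n)
  } else {
    p_low <- min(1, (rate - e_high) / (e_low - e_high))
    state_low <- stats::runif(n) < p_low
  }
  per_base_err <- ifelse(state_low, e_low, e_high)
  if (rate <= e_high) per_base_err[] <- rate
  hit <- stats::runif(n) < per_base_err
  chars <- strsplit(seq, "")[[1]]
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(DNA_BASES4, b), 1L), character(1))
  }
  qual <- ifelse(state_low, 12L, 37L)
  list(seq = paste(chars, collapse = ""), qual = phred_to_string(qual))
}

#' Simulate a matrix-barcoded paired-end sequencing run
#'
#' For every filled well a clonotype is drawn; for every non-dropped chain,
#' `reads_per_well` read pairs are emitted whose error-free assembly equals
#' the schema amplicon (mate 1 = 5' end, mate 2 = reverse complement of the
#' 3' end). Output is deterministic for a given config seed.
#'
#' @param ref a `tcr_reference`.
#' @param layout a `plate_layout`.
#' @param config a [sim_config()].
#' @param schema an [amplicon_schema()]; default built from `ref`.
#' @param dir if non-NULL, write `reads_R1.fastq`, `reads_R2.fastq`,
#'   `index_sort.tsv`, `ground_truth.tsv` there.
#' @return list with `reads` (tibble: id, seq1, qual1, seq2, qual2),
#'   `ground_truth`, `index_sort` tibbles and the file paths when written.
#' @export
simulate_run <- function(ref, layout, config = sim_config(),
                         schema = amplicon_schema(ref), dir = NULL) {
  if (config$n_wells > 384L)
    stop("n_wells per plate cannot exceed 384", call. = FALSE)
  if (config$n_plates > layout$n_plates)
    stop("config asks for more plates than the layout holds", call. = FALSE)
  with_seed(config$seed, {
    wells <- do.call(rbind, lapply(seq_len(config$n_plates), function(p) {
      idx <- sort(sample.int(384L, config$n_wells))
      data.frame(plate = p, row = (idx - 1L) %% 16L + 1L,
                 col = (idx - 1L) %/% 16L + 1L)
    }))
    n <- nrow(wells)
    truth <- vector("list", n)
    reads <- vector("list", n)
    sort_rows <- vector("list", n)
    for (i in seq_len(n)) {
      w <- wells[i, ]
      pop <- sample(config$populations, 1L)
      clono <- sample_clonotype(ref, config$force_productive, pop)
      doublet <- stats::runif(1) < config$doublet_rate
      clono2 <- if (doublet)
        sample_clonotype(ref, config$force_productive, pop) else NULL
      tags <- well_tags(layout, w$plate, w$row, w$col)
      alpha_present <- stats::runif(1) >= config$chain_dropout_alpha
      beta_present <- stats::runif(1) >= config$chain_dropout_beta
      well_reads <- list()
      for (chain in c("alpha", "beta")) {
        present <- if (chain == "alpha") alpha_present else beta_present
        if (!present || config$reads_per_well == 0L) next
        n_reads <- config$reads_per_well
        n2 <- if (doublet) floor(0.3 * n_reads) else 0L
        sources <- c(rep(list(clono), n_reads - n2),
                     rep(list(clono2), n2))
        amps <- vapply(sources, build_amplicon, character(1),
                       chain = chain, schema = schema,
                       fwd_tag = tags$fwd, rev_tag = tags$rev)
        nk <- length(amps)
        s1 <- q1 <- s2 <- q2 <- character(nk)
        for (k in seq_len(nk)) {
          amp <- amps[k]
          L <- nchar(amp)
          rl <- min(config$read_length, L)
          m1 <- mutate_read(substr(amp, 1L, rl), config$error_rate)
          m2raw <- revcomp(substr(amp, L - rl + 1L, L))
          m2 <- mutate_read(m2raw, config$error_rate)
          s1[k] <- m1$seq; q1[k] <- m1$qual
          s2[k] <- m2$seq; q2[k] <- m2$qual
        }
        well_reads[[length(well_reads) + 1L]] <- tibble(
          id = sprintf("sim:p%02d%s%02d:%s:%d", w$plate,
                       well_row_labels()[w$row], w$col, chain,
                       seq_len(nk)),
          seq1 = s1, qual1 = q1, seq2 = s2, qual2 = q2)
      }
      reads[[i]] <- if (length(well_reads)) bind_rows(well_reads) else NULL
      truth[[i]] <- tibble(
        plate = w$plate, row = w$row, row_label = well_row_labels()[w$row],
        col = w$col, population_label = pop,
        v_alpha = clono$v_alpha, j_alpha = clono$j_alpha,
        junction_alpha = clono$junction_alpha,
        productive_alpha = clono$productive_alpha,
        v_beta = clono$v_beta, j_beta = clono$j_beta,
        junction_beta = clono$junction_beta,
        productive_beta = clono$productive_beta,
        alpha_present = alpha_present, beta_present = beta_present,
        doublet = doublet)
      fl <- stats::rlnorm(6, meanlog = 6 + match(pop, config$populations) / 2,
                          sdlog = 0.4)
      sort_rows[[i]] <- tibble(
        plate = w$plate, row = w$row, row_label = well_row_labels()[w$row],
        col = w$col, population_label = pop,
        FSC_A = fl[1], SSC_A = fl[2], CD4_FITC = fl[3], CD44_BV785 = fl[4],
        CXCR5_PE = fl[5], PD1_BV605 = fl[6])
    }
    out <- list(reads = bind_rows(reads[!vapply(reads, is.null, logical(1))]),
                ground_truth = bind_rows(truth),
                index_sort = bind_rows(sort_rows),
                config = config)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      out$files <- write_run(out, dir)
    }
    out
  })
}

## Write a simulated run to FASTQ + TSV files.
write_run <- function(run, dir) {
  fq <- function(seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(quals))
    names(x) <- run$reads$id
    Biostrings::writeQualityScaledXStringSet(x, path)
    path
  }
  r1 <- file.path(dir, "reads_R1.fastq")
  r2 <- file.path(dir, "reads_R2.fastq")
  fq(run$reads$seq1, run$reads$qual1, r1)
  fq(run$reads$seq2, run$reads$qual2, r2)
  gt <- file.path(dir, "ground_truth.tsv")
  ix <- file.path(dir, "index_sort.tsv")
  utils::write.table(run$ground_truth, gt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(run$index_sort, ix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(r1 = r1, r2 = r2, ground_truth = gt, index_sort = ix)
}

#' Read paired FASTQ files into the read-pair table
#'
#' @param r1,r2 FASTQ paths (mate 1, mate 2).
#' @return tibble with id, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pairs <- function(r1, r2) {
  rd <- function(p) {
    x <- Biostrings::readQualityScaledDNAStringSet(p)
    list(id = sub("\\s.*$", "", names(x)),
         seq = as.character(x),
         qual = as.character(Biostrings::quality(x)))
  }
  a <- rd(r1); b <- rd(r2)
  stopifnot(identical(a$id, b$id))
  tibble(id = a$id, seq1 = unname(a$seq), qual1 = unname(a$qual),
         seq2 = unname(b$seq), qual2 = unname(b$qual))
}
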