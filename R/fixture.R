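#' Length-calibrated synthetic germline locus
#'
#' Builds the packaged synthetic reference used by the simulator, the
#' annotation tests and the construct designer. All sequences are synthetic
#' stand-ins (random stop-free open reading frames), but their lengths are
#' calibrated so that:
#'
#' * tagged second-PCR amplicons fall inside the 480-560 nt accepted length
#'   window (alpha 483-493 nt, beta 501-511 nt, with the beta amplicon the
#'   larger of the two as on amplification gels),
#' * the colony-screen PCR product of an assembled expression construct falls
#'   inside the expected 1600-1700 bp window (1627 + Na + Nb bp for junction
#'   insertions Na, Nb of 0-10 nt each).
#'
#' Fixed structural choices (0-based coordinates):
#'
#' * V segments: 300 nt ending with a TGT cysteine codon
#'   (`cys_codon_start = 297`); the first 21 nt stand for the degenerate
#'   framework-region-1 primer footprint.
#' * J segments: 57 nt with a `TTT GGC TCT GGC` (FGSG) motif at nt 21-32
#'   (`phe_codon_start = 21`).
#' * Constant regions: Calpha 330 nt (stop-free; read through into the 2A
#'   linker), Cbeta 300 nt ending in TAA. The second-PCR amplicons carry the
#'   first 90 (alpha) / 108 (beta) nt as the constant-region stub.
#' * Signal sequences: one 60 nt ATG-initiated SSalpha per V-alpha family
#'   (13 families -> the 13-vector library), one 57 nt SSbeta.
#' * 2A linker: 66 nt encoding GSG-P2A (GSGATNFSLLKQAGDVEENPGP).
#' * Vector backbone: non-coding filler carrying the forward control-primer
#'   site 40 nt upstream of the SSalpha start and the reverse control-primer
#'   site ending 60 nt downstream of the Cbeta end.
#'
#' @param seed integer seed fixing the fixture; the default is the packaged
#'   fixture.
#' @param n_v_alpha,n_j_alpha,n_v_beta,n_j_beta locus sizes (defaults
#'   20/10/26/12 functional segments).
#' @param n_families number of V-alpha families / SSalpha vectors (default 13).
#' @param n_pseudo_v_alpha extra non-functional V-alpha segments (default 0).
#' @return a `tcr_reference`.
#' @export
synthetic_locus <- function(seed = 20190502L,
                            n_v_alpha = 20L, n_j_alpha = 10L,
                            n_v_beta = 26L, n_j_beta = 12L,
                            n_families = 13L, n_pseudo_v_alpha = 0L) {
  with_seed(seed, {
    make_v <- function(prefix, n, families, functional) {
      tibble(
        id = sprintf("%s%02d", prefix, seq_len(n)),
        family = families,
        functional = functional,
        sequence = vapply(seq_len(n), function(i)
          paste0(random_orf(99L), "TGT"), character(1)),
        cys_codon_start = 297L, phe_codon_start = NA_integer_)
    }
    make_j <- function(prefix, n) {
      tibble(
        id = sprintf("%s%02d", prefix, seq_len(n)),
        family = NA_character_, functional = TRUE,
        sequence = vapply(seq_len(n), function(i)
          paste0(random_orf(7L), "TTTGGCTCTGGC", random_orf(8L)),
          character(1)),
        cys_codon_start = NA_integer_, phe_codon_start = 21L)
    }
    fam_alpha <- sprintf("TRAVF%02d",
                         rep_len(seq_len(n_families), n_v_alpha))
    fam_beta <- sprintf("TRBVF%02d",
                        rep_len(seq_len(max(1L, n_v_beta %/% 2L)), n_v_beta))

    va <- make_v("TRAV", n_v_alpha, fam_alpha, TRUE)
    if (n_pseudo_v_alpha > 0L) {
      ps <- make_v("TRAVP", n_pseudo_v_alpha,
                   rep("TRAVF01", n_pseudo_v_alpha), FALSE)
      va <- bind_rows(va, ps)
    }
    vb <- make_v("TRBV", n_v_beta, fam_beta, TRUE)
    ja <- make_j("TRAJ", n_j_alpha)
    jb <- make_j("TRBJ", n_j_beta)

    ca <- tibble(id = "TRAC", family = NA_character_, functional = TRUE,
                 sequence = random_orf(110L),
                 cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)
    cb <- tibble(id = "TRBC", family = NA_character_, functional = TRUE,
                 sequence = paste0(random_orf(99L), "TAA"),
                 cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)

    ssa <- tibble(
      id = sprintf("SSA-F%02d", seq_len(n_families)),
      family = sprintf("TRAVF%02d", seq_len(n_families)),
      functional = TRUE,
      sequence = vapply(seq_len(n_families), function(i)
        paste0("ATG", random_orf(19L)), character(1)),
      cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)
    ssb <- tibble(id = "SSB", family = NA_character_, functional = TRUE,
                  sequence = random_orf(19L),
                  cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)

    p2a_aa <- "GSGATNFSLLKQAGDVEENPGP"
    p2a <- tibble(id = "P2A", family = NA_character_, functional = TRUE,
                  sequence = encode_peptide(p2a_aa),
                  cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)

    cfg <- construct_config()
    backbone5 <- paste0(random_dna(180L), cfg$primer_fw, random_dna(20L))
    backbone3 <- paste0(random_dna(43L), revcomp(cfg$primer_rev),
                        random_dna(140L))
    bb <- tibble(
      id = c("BACKBONE5-SYN", "BACKBONE3-SYN"),
      family = NA_character_, functional = TRUE,
      sequence = c(backbone5, backbone3),
      cys_codon_start = NA_integer_, phe_codon_start = NA_integer_)

    seg <- bind_rows(
      mutate(va, chain = "alpha", class = "V"),
      mutate(ja, chain = "alpha", class = "J"),
      mutate(ca, chain = "alpha", class = "C"),
      mutate(ssa, chain = "alpha", class = "SS"),
      mutate(vb, chain = "beta", class = "V"),
      mutate(jb, chain = "beta", class = "J"),
      mutate(cb, chain = "beta", class = "C"),
      mutate(ssb, chain = "beta", class = "SS"),
      mutate(p2a, chain = NA_character_, class = "linker2A"),
      mutate(bb, chain = NA_character_, class = "vector_backbone"))
    seg <- seg[, c("id", "chain", "class", "family", "functional",
                   "cys_codon_start", "phe_codon_start", "sequence")]
    new_reference(seg)
  })
}

## Deterministic codon encoding of a peptide (first codon in a fixed table).
encode_peptide <- function(aa) {
  tab <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT", G = "GGA",
           H = "CAT", I = "ATT", K = "AAA", L = "CTT", M = "ATG", N = "AAT",
           P = "CCT", Q = "CAA", R = "CGT", S = "TCT", T = "ACT", V = "GTT",
           W = "TGG", Y = "TAT")
  paste(tab[strsplit(aa, "")[[1]]], collapse = "")
}

#' Amplicon structure shared by simulator and demultiplexer
#'
#' Second-PCR amplicons are, on the sense strand,
#' `fwd_tag + universal_linker + V + junction-N + J + C-stub +
#' revcomp(rev_tag)`; the forward (column) tag is read from the mate-1 5' end
#' and the reverse (row) tag from the mate-2 5' end.
#'
#' @param ref a `tcr_reference` (used to size the constant-region stubs).
#' @param tag_length barcode length in nt.
#' @param c_stub_alpha,c_stub_beta length of the constant-region stub carried
#'   by the amplicon, per chain.
#' @param insert_range accepted assembled-length window in nt.
#' @return an `amplicon_schema` list.
#' @export
amplicon_schema <- function(ref, tag_length = 8L,
                            c_stub_alpha = 90L, c_stub_beta = 108L,
                            insert_range = c(480L, 560L)) {
  ca <- segment_seq(ref, functional_segments(ref, "alpha", "C")$id[1])
  cb <- segment_seq(ref, functional_segments(ref, "beta", "C")$id[1])
  structure(list(
    universal_linker = "GTACGGGTTCAGGACCACGC",
    tag_length = as.integer(tag_length),
    c_stub = list(alpha = substr(ca, 1L, c_stub_alpha),
                  beta = substr(cb, 1L, c_stub_beta)),
    insert_range = as.integer(insert_range)
  ), class = "amplicon_schema")
}

#' Vector library for expression cloning
#'
#' One circular retroviral backbone per V-alpha family, each carrying that
#' family's SSalpha cassette and the Cbeta cassette with the single
#' linearization site at the SSalpha/Cbeta boundary (where the insert goes).
#' The serialized circular sequence starts at the backbone origin, so the
#' cassette order on the sense strand is
#' `backbone5' - SSalpha - [cut] - Cbeta - backbone3'`.
#'
#' @param ref a `tcr_reference` containing SS, C and vector_backbone segments.
#' @return named list of `vector_entry` objects keyed by V-alpha family.
#' @export
vector_library <- function(ref) {
  seg <- ref$segments
  ssa <- seg[seg$class == "SS" & seg$chain == "alpha", ]
  cb <- segment_seq(ref, seg$id[seg$class == "C" & seg$chain == "beta"][1])
  b5 <- segment_seq(ref, "BACKBONE5-SYN")
  b3 <- segment_seq(ref, "BACKBONE3-SYN")
  entries <- lapply(seq_len(nrow(ssa)), function(i) {
    s <- ssa$sequence[i]
    structure(list(
      family = ssa$family[i],
      ssa_id = ssa$id[i],
      ssa_seq = s,
      cbeta_seq = cb,
      sequence = paste0(b5, s, cb, b3),
      ## 0-based position of the single cut, at the SSalpha/Cbeta boundary
      lin_site = nchar(b5) + nchar(s)
    ), class = "vector_entry")
  })
  names(entries) <- ssa$family
  entries
}
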