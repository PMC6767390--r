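#' Construct-design configuration
#'
#' @param homology Gibson homology-tail length in nt (default 20).
#' @param primer_region length of the degenerate framework-region-1 primer
#'   footprint at the V 5' end that is reverted to germline (default 21 nt).
#' @param screen_window expected colony-PCR product size window in bp.
#' @param primer_fw,primer_rev colony-screen control primer sequences
#'   (forward on the sense strand, reverse annealing on the antisense
#'   strand).
#' @return a `construct_config` list.
#' @export
construct_config <- function(homology = 20L, primer_region = 21L,
                             screen_window = c(1600L, 1700L),
                             primer_fw = "TCGATCCTCCCTTTATCCAG",
                             primer_rev = "CCATGGAACTGCACTTG") {
  stopifnot(screen_window[1] <= screen_window[2], homology >= 10L)
  structure(list(homology = as.integer(homology),
                 primer_region = as.integer(primer_region),
                 screen_window = as.integer(screen_window),
                 primer_fw = primer_fw, primer_rev = primer_rev),
            class = "construct_config")
}

gibson_fragment <- function(name, core, left, right) {
  structure(list(name = name, sequence = paste0(left, core, right),
                 left_homology = left, right_homology = right),
            class = "gibson_fragment")
}

## Germline-corrected V..J chain sequence: germline V up to the junction,
## the observed CDR3 junction, germline J after the phenylalanine codon.
## Everything outside the observed junction is germline by construction,
## which models the error-reverting gene-specific second PCR.
vdj_from_record <- function(v_id, j_id, cdr3_nt, ref) {
  v <- get_segment(ref, v_id)
  j <- get_segment(ref, j_id)
  paste0(substr(v$sequence, 1L, v$cys_codon_start),
         cdr3_nt,
         substr(j$sequence, j$phe_codon_start + 4L, nchar(j$sequence)))
}

#' Design the three Gibson fragments for a paired TCR
#'
#' Produces the TCRalpha fragment (homology tails to the SSalpha of the
#' assigned V-alpha family and to the Calpha head), the Calpha-2A-SSbeta
#' linker fragment, and the TCRbeta fragment (tails to the SSbeta end and
#' the Cbeta head). Degenerate first-PCR primer positions are reverted to
#' the germline of the assigned V segment.
#'
#' @param pair single paired-well row from [pair_wells()] (needs
#'   `alpha_v_id`, `alpha_j_id`, `alpha_cdr3_nt`, `alpha_productive` and the
#'   beta equivalents).
#' @param ref a `tcr_reference`.
#' @param cfg a [construct_config()].
#' @return named list of `gibson_fragment`s: valpha, linker, vbeta.
#' @export
design_fragments <- function(pair, ref, cfg = construct_config()) {
  need <- function(ch) {
    v <- pair[[paste0(ch, "_v_id")]]
    if (is.null(v) || is.na(v))
      stop("missing ", ch, " chain record", call. = FALSE)
    if (!isTRUE(pair[[paste0(ch, "_productive")]]))
      stop(ch, " chain is not productive", call. = FALSE)
  }
  need("alpha"); need("beta")
  h <- cfg$homology
  ssa_fam <- get_segment(ref, pair$alpha_v_id)$family
  seg <- ref$segments
  ssa <- seg[seg$class == "SS" & seg$chain == "alpha" &
               seg$family == ssa_fam, ]
  if (nrow(ssa) != 1L)
    stop("no SSalpha cassette for V-alpha family ", ssa_fam, call. = FALSE)
  ssb <- seg[seg$class == "SS" & seg$chain == "beta", ]
  ca <- segment_seq(ref, seg$id[seg$class == "C" & seg$chain == "alpha"][1])
  cb <- segment_seq(ref, seg$id[seg$class == "C" & seg$chain == "beta"][1])
  p2a <- segment_seq(ref, seg$id[seg$class == "linker2A"][1])

  tail_of <- function(s) substr(s, nchar(s) - h + 1L, nchar(s))
  head_of <- function(s) substr(s, 1L, h)

  vdj_a <- vdj_from_record(pair$alpha_v_id, pair$alpha_j_id,
                           pair$alpha_cdr3_nt, ref)
  vdj_b <- vdj_from_record(pair$beta_v_id, pair$beta_j_id,
                           pair$beta_cdr3_nt, ref)
  linker_core <- paste0(ca, p2a, ssb$sequence)
  list(
    valpha = gibson_fragment("TCRa", vdj_a, tail_of(ssa$sequence),
                             head_of(ca)),
    linker = gibson_fragment(
      "Ca-2A-SSb",
      substr(linker_core, h + 1L, nchar(linker_core) - h),
      head_of(ca), tail_of(ssb$sequence)),
    vbeta = gibson_fragment("TCRb", vdj_b, tail_of(ssb$sequence),
                            head_of(cb)))
}

#' Select the expression vector serving a V-alpha gene
#'
#' @param v_alpha_id assigned V-alpha segment id.
#' @param library vector library from [vector_library()].
#' @param ref a `tcr_reference` (maps the gene to its family).
#' @return the matching `vector_entry`.
#' @export
select_vector <- function(v_alpha_id, library, ref) {
  fam <- get_segment(ref, v_alpha_id)$family
  if (!fam %in% names(library))
    stop("no vector for V-alpha family ", fam, "; library covers: ",
         paste(names(library), collapse = ", "), call. = FALSE)
  library[[fam]]
}

## Linearize a circular vector at its single cut site: the linear molecule
## starts just downstream of the cut and ends just upstream of it.
linearize_vector <- function(vec) {
  s <- vec$sequence
  paste0(substr(s, vec$lin_site + 1L, nchar(s)),
         substr(s, 1L, vec$lin_site))
}

#' Assemble fragments and vector into a circular expression construct
#'
#' Overlap-merges the linearized vector and the three fragments in order
#' (vector - TCRalpha - linker - TCRbeta - back to vector). Each seam
#' requires the upstream suffix and downstream prefix of `cfg$homology` nt
#' to match exactly and the shared homology region to occur exactly once in
#' the final circle. The circular sequence is serialized from the vector
#' backbone origin, so features run
#' SSalpha-Valpha-Calpha-2A-SSbeta-Vbeta-Cbeta on the sense strand.
#'
#' @param fragments fragment list from [design_fragments()].
#' @param vector a `vector_entry`.
#' @param cfg a [construct_config()].
#' @return an `expression_construct`: `sequence` (circular, serialized from
#'   the backbone origin), `features` tibble (0-based half-open spans) and
#'   `seams` tibble.
#' @export
assemble <- function(fragments, vector, cfg = construct_config()) {
  h <- cfg$homology
  pieces <- list(vector = linearize_vector(vector),
                 valpha = fragments$valpha$sequence,
                 linker = fragments$linker$sequence,
                 vbeta = fragments$vbeta$sequence)
  junctions <- c("SSalpha-Valpha", "Valpha-Calpha", "SSbeta-Vbeta",
                 "Vbeta-Cbeta")
  seq <- pieces[[1]]
  seams <- character(4)
  for (k in 2:4) {
    nxt <- pieces[[k]]
    seam <- substr(seq, nchar(seq) - h + 1L, nchar(seq))
    if (seam != substr(nxt, 1L, h))
      stop("assembly_error: no homology match at junction ",
           junctions[k - 1L], call. = FALSE)
    seams[k - 1L] <- seam
    seq <- paste0(seq, substr(nxt, h + 1L, nchar(nxt)))
  }
  ## close the circle: the TCRbeta right tail must equal the vector start
  seam <- substr(seq, nchar(seq) - h + 1L, nchar(seq))
  if (seam != substr(seq, 1L, h))
    stop("assembly_error: no homology match at junction ", junctions[4],
         call. = FALSE)
  seams[4] <- seam
  circ <- substr(seq, 1L, nchar(seq) - h)

  ## verify every seam occurs exactly once on the circle (append h-1 bases
  ## so origin-straddling matches count once and origin matches are not
  ## duplicated)
  doubled <- paste0(circ, substr(circ, 1L, h - 1L))
  n_occ <- vapply(seams, function(s)
    length(Biostrings::matchPattern(s, Biostrings::DNAString(doubled))),
    integer(1))
  if (any(n_occ != 1L))
    stop("assembly_error: homology region duplicated at junction ",
         junctions[which(n_occ != 1L)[1]], call. = FALSE)

  ## rotate so the sequence starts at the vector backbone origin
  b5_len <- vec_component_lengths(vector)
  rot <- nchar(vector$cbeta_seq) + b5_len["b3"]
  circ <- paste0(substr(circ, rot + 1L, nchar(circ)),
                 substr(circ, 1L, rot))
  feats <- construct_features(fragments, vector, cfg, b5_len)
  stopifnot(sum(feats$end - feats$start) == nchar(circ))
  structure(list(sequence = circ, features = feats,
                 seams = tibble(junction = junctions, homology = seams),
                 config = cfg),
            class = "expression_construct")
}

vec_component_lengths <- function(vector) {
  total <- nchar(vector$sequence)
  ssa <- nchar(vector$ssa_seq); cb <- nchar(vector$cbeta_seq)
  b5 <- vector$lin_site - ssa
  c(b5 = b5, ssa = ssa, cb = cb, b3 = total - b5 - ssa - cb)
}

## Feature spans (0-based half-open) on the origin-rotated circle.
construct_features <- function(fragments, vector, cfg, lens) {
  h <- cfg$homology
  core <- function(f) nchar(f$sequence) - 2L * h
  widths <- c(
    backbone5 = unname(lens["b5"]),
    SSalpha = unname(lens["ssa"]),
    Valpha = core(fragments$valpha),
    CA2ASSB = core(fragments$linker) + 2L * h,
    Vbeta = core(fragments$vbeta),
    Cbeta = unname(lens["cb"]),
    backbone3 = unname(lens["b3"]))
  ends <- cumsum(widths)
  tibble(feature = names(widths), start = ends - widths, end = ends)
}

#' Split the linker feature into Calpha / 2A / SSbeta spans
#'
#' @param construct an `expression_construct`.
#' @param ref the `tcr_reference` whose Calpha/2A/SSbeta lengths were used.
#' @return feature tibble with the combined linker span replaced by the
#'   three component spans.
#' @export
refine_features <- function(construct, ref) {
  seg <- ref$segments
  ca <- nchar(segment_seq(ref, seg$id[seg$class == "C" &
                                        seg$chain == "alpha"][1]))
  p2a <- nchar(segment_seq(ref, seg$id[seg$class == "linker2A"][1]))
  f <- construct$features
  lk <- f[f$feature == "CA2ASSB", ]
  parts <- tibble(feature = c("Calpha", "P2A", "SSbeta"),
                  start = lk$start + c(0L, ca, ca + p2a),
                  end = c(lk$start + ca, lk$start + ca + p2a, lk$end))
  out <- bind_rows(f[f$feature != "CA2ASSB", ], parts)
  arrange(out, .data$start)
}

#' Validate the open reading frame of an assembled construct
#'
#' Translates from the SSalpha start codon through the Cbeta stop and
#' reports frame continuity, premature stops, and in-frame presence of the
#' 2A peptide. Requires `in_frame` to mean: a single continuous reading
#' frame from the SSalpha ATG to the Cbeta terminal stop with no internal
#' stop codon.
#'
#' @param construct an `expression_construct`.
#' @param p2a_aa amino-acid sequence of the 2A linker expected in frame.
#' @return list: in_frame, premature_stops (0-based aa positions),
#'   has_start, has_terminal_stop, p2a_in_frame, protein.
#' @export
validate_orf <- function(construct,
                         p2a_aa = "GSGATNFSLLKQAGDVEENPGP") {
  f <- construct$features
  orf_start <- f$start[f$feature == "SSalpha"] + 1L      # 1-based
  orf_end <- f$end[f$feature == "Cbeta"]
  orf <- substr(construct$sequence, orf_start, orf_end)
  has_start <- startsWith(orf, "ATG")
  in_frame_len <- nchar(orf) %% 3L == 0L
  protein <- translate_dna(orf)
  stops <- which(strsplit(protein, "")[[1]] == "*") - 1L
  has_terminal_stop <- in_frame_len && length(stops) > 0L &&
    max(stops) == nchar(protein) - 1L
  premature <- stops[stops < nchar(protein) - 1L]
  p2a_in_frame <- grepl(p2a_aa, protein, fixed = TRUE)
  list(in_frame = has_start && in_frame_len && length(premature) == 0L &&
         has_terminal_stop && p2a_in_frame,
       premature_stops = premature,
       has_start = has_start, has_terminal_stop = has_terminal_stop,
       p2a_in_frame = p2a_in_frame, protein = protein)
}

#' Predict the colony-screen PCR product length
#'
#' Locates the forward control primer on the sense strand and the reverse
#' control primer on the antisense strand (each must occur exactly once,
#' reverse site downstream of the forward site) and returns the product
#' length including both primer footprints.
#'
#' @param construct an `expression_construct` (or any object with a
#'   `sequence` string).
#' @param cfg a [construct_config()].
#' @return product length in bp.
#' @export
predict_screen_amplicon <- function(construct, cfg = construct_config()) {
  s <- Biostrings::DNAString(construct$sequence)
  fw <- Biostrings::matchPattern(cfg$primer_fw, s)
  rv <- Biostrings::matchPattern(revcomp(cfg$primer_rev), s)
  if (length(fw) != 1L)
    stop(sprintf("forward control primer site count %d (expected 1)",
                 length(fw)), call. = FALSE)
  if (length(rv) != 1L)
    stop(sprintf("reverse control primer site count %d (expected 1)",
                 length(rv)), call. = FALSE)
  if (IRanges::start(rv) <= IRanges::end(fw))
    stop("reverse control primer site is not downstream of the forward site",
         call. = FALSE)
  IRanges::end(rv) - IRanges::start(fw) + 1L
}

#' Clone one paired TCR end to end
#'
#' Convenience wrapper: design fragments, pick the vector, assemble, refine
#' the feature map, validate the reading frame and predict the screening
#' product.
#'
#' @param pair single paired-well row ([pair_wells()]).
#' @param ref a `tcr_reference`.
#' @param library vector library ([vector_library()]); built from `ref` by
#'   default.
#' @param cfg a [construct_config()].
#' @return list: construct, validation, screen_bp.
#' @export
clone_pair <- function(pair, ref, library = vector_library(ref),
                       cfg = construct_config()) {
  frags <- design_fragments(pair, ref, cfg)
  vec <- select_vector(pair$alpha_v_id, library, ref)
  construct <- assemble(frags, vec, cfg)
  construct$features <- refine_features(construct, ref)
  list(construct = construct,
       validation = validate_orf(construct),
       screen_bp = predict_screen_amplicon(construct, cfg))
}

#' Build a paired-well row directly from a simulated clonotype
#'
#' Used to drive construct design from ground truth (e.g. when exercising
#' the cloning stage without a sequencing run).
#'
#' @param clono a `clonotype` from [sample_clonotype()].
#' @param plate,row,col well address to attach.
#' @return single-row tibble in the [pair_wells()] layout.
#' @export
pair_from_clonotype <- function(clono, plate = 1L, row = 1L, col = 1L) {
  tibble(
    plate = plate, row = row, col = col,
    population_label = clono$population_label,
    alpha_v_id = clono$v_alpha, alpha_j_id = clono$j_alpha,
    alpha_cdr3_nt = clono$junction_alpha,
    alpha_cdr3_aa = translate_dna(clono$junction_alpha),
    alpha_productive = clono$productive_alpha,
    beta_v_id = clono$v_beta, beta_j_id = clono$j_beta,
    beta_cdr3_nt = clono$junction_beta,
    beta_cdr3_aa = translate_dna(clono$junction_beta),
    beta_productive = clono$productive_beta,
    has_alpha = TRUE, has_beta = TRUE, paired = TRUE)
}
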