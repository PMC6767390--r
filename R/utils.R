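#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% group_by summarise mutate arrange filter left_join
#'   count ungroup select n bind_rows
#' @importFrom rlang .data
#' @import Biostrings
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

DNA_BASES4 <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(chartr("ACGT", "TGCA", s)))),
         character(1), USE.NAMES = FALSE)
}

#' Translate a DNA string in frame 1
#'
#' Codon-table lookup against the standard genetic code. Trailing partial
#' codons are dropped; stops are reported as `*`, unknown codons as `X`.
#'
#' @param x character scalar, DNA.
#' @return character scalar, amino-acid sequence.
#' @export
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n, 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(x, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal length.
#' @return integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

random_dna <- function(n_char) {
  paste(sample(DNA_BASES4, n_char, replace = TRUE), collapse = "")
}

## All 61 stop-free codons.
stopfree_codons <- function() {
  cods <- apply(expand.grid(DNA_BASES4, DNA_BASES4, DNA_BASES4), 1, paste,
                collapse = "")
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

## Random open-reading-frame fragment of n_codons codons with no stop codon.
random_orf <- function(n_codons) {
  paste(sample(stopfree_codons(), n_codons, replace = TRUE), collapse = "")
}

## Phred integer vector <-> Sanger-offset (33) quality string.
phred_to_string <- function(q) {
  rawToChar(as.raw(pmin(q, 93L) + 33L))
}
string_to_phred <- function(s) {
  as.integer(charToRaw(s)) - 33L
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

well_row_labels <- function() LETTERS[1:16]
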