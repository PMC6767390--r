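#' Barcode sets and the two-dimensional plate matrix
#'
#' Matrix PCR barcoding tags each well's amplicon with one column-specific
#' forward and one row-specific reverse barcode, so a pool of many 384-well
#' plates can be sequenced together and every read traced back to its well
#' from the tag pair alone.
#'
#' @name plate_layout
NULL

#' Generate a barcode set by seeded random search
#'
#' Draws random tags and keeps those at pairwise Hamming distance at least
#' `min_dist` from every kept tag, excluding tags equal to a kept tag's
#' reverse complement (or their own). With `min_dist >= 2*max_mismatch + 1`,
#' decoding with up to `max_mismatch` substitutions is provably unique.
#'
#' @param n number of tags.
#' @param length tag length in nt (default 8).
#' @param min_dist minimum pairwise Hamming distance (default 3).
#' @param seed integer seed fixing the search.
#' @param max_tries attempt budget before giving up.
#' @return a `barcode_set`: list with `tags`, `tag_length`,
#'   `min_pairwise_hamming`.
#' @export
generate_barcodes <- function(n, length = 8L, min_dist = 3L, seed = 1L,
                              max_tries = 2000L * n) {
  if (n > 4^length)
    stop(sprintf("only %d tags of length %d exist; %d requested",
                 4^length, length, n), call. = FALSE)
  with_seed(seed, {
    tags <- character(0)
    tries <- 0L
    while (length(tags) < n && tries < max_tries) {
      tries <- tries + 1L
      cand <- random_dna(length)
      rc <- revcomp(cand)
      if (cand == rc) next
      ok <- TRUE
      for (t in tags) {
        if (hamming(cand, t) < min_dist || rc == t) { ok <- FALSE; break }
      }
      if (ok) tags <- c(tags, cand)
    }
    if (length(tags) < n)
      stop(sprintf(
        "could not find %d tags (length %d, min Hamming %d); largest set found: %d",
        n, length, min_dist, length(tags)), call. = FALSE)
    structure(list(tags = tags, tag_length = as.integer(length),
                   min_pairwise_hamming = as.integer(min_dist)),
              class = "barcode_set")
  })
}

#' Build a multi-plate well map from forward and reverse tag sets
#'
#' Plates are tiled into a virtual super-grid (default 3 rows x 4 columns of
#' plates for 12 plates); super-grid columns consume forward (column) tags
#' and super-grid rows consume reverse (row) tags, so every one of the
#' `n_plates * 384` wells receives a unique (forward, reverse) tag pair.
#'
#' @param n_plates number of 384-well plates.
#' @param fwd_tags,rev_tags `barcode_set`s for the column and row axes.
#' @param tiling integer c(grid_rows, grid_cols) of the plate super-grid;
#'   default the most square tiling with grid_cols >= grid_rows.
#' @return a `plate_layout` with a bijective `well_map` tibble
#'   (plate, row 1-16, row_label A-P, col 1-24, fwd_idx, rev_idx).
#' @export
build_layout <- function(n_plates, fwd_tags, rev_tags, tiling = NULL) {
  if (is.null(tiling)) {
    gr <- floor(sqrt(n_plates))
    while (n_plates %% gr != 0L) gr <- gr - 1L
    tiling <- c(gr, n_plates %/% gr)
  }
  tiling <- as.integer(tiling)
  gr <- tiling[1]; gc <- tiling[2]
  if (gr * gc < n_plates)
    stop("tiling holds fewer plates than requested", call. = FALSE)
  need_fwd <- gc * 24L; need_rev <- gr * 16L
  if (length(fwd_tags$tags) < need_fwd || length(rev_tags$tags) < need_rev)
    stop(sprintf(
      "insufficient tags: need %d fwd x %d rev for %d plates (%d wells), have %d x %d (%d combinations)",
      need_fwd, need_rev, n_plates, n_plates * 384L,
      length(fwd_tags$tags), length(rev_tags$tags),
      length(fwd_tags$tags) * length(rev_tags$tags)), call. = FALSE)
  grid <- expand.grid(row = 1:16, col = 1:24, plate = seq_len(n_plates))
  pr <- (grid$plate - 1L) %/% gc      # plate position in super-grid
  pc <- (grid$plate - 1L) %% gc
  map <- tibble(
    plate = grid$plate,
    row = grid$row,
    row_label = well_row_labels()[grid$row],
    col = grid$col,
    fwd_idx = as.integer(pc * 24L + grid$col),
    rev_idx = as.integer(pr * 16L + grid$row))
  stopifnot(!anyDuplicated(map[, c("fwd_idx", "rev_idx")]))
  structure(list(
    n_plates = as.integer(n_plates),
    tiling = as.integer(tiling),
    fwd_tags = fwd_tags, rev_tags = rev_tags,
    n_fwd_used = need_fwd, n_rev_used = need_rev,
    well_map = map
  ), class = "plate_layout")
}

#' Tags of one well
#'
#' @param layout a `plate_layout`.
#' @param plate,row,col well address (row may be 1-16 or "A"-"P").
#' @return list with `fwd` and `rev` tag sequences.
#' @export
well_tags <- function(layout, plate, row, col) {
  if (is.character(row)) row <- match(row, well_row_labels())
  m <- layout$well_map
  hit <- m[m$plate == plate & m$row == row & m$col == col, ]
  if (nrow(hit) != 1L) stop("no such well", call. = FALSE)
  list(fwd = layout$fwd_tags$tags[hit$fwd_idx],
       rev = layout$rev_tags$tags[hit$rev_idx])
}

## Hamming distances of one observed tag against a tag panel.
tag_distances <- function(observed, tags) {
  obs <- charToRaw(observed)
  vapply(tags, function(t) sum(charToRaw(t) != obs), integer(1),
         USE.NAMES = FALSE)
}

#' Decode an observed tag pair to a well address
#'
#' Each observed tag must lie within `max_mismatch` substitutions of exactly
#' one layout tag; otherwise the read is rejected with a reason
#' (`unknown_fwd`, `unknown_rev`, `ambiguous`).
#'
#' @param fwd_obs,rev_obs observed tag sequences (sense orientation).
#' @param layout a `plate_layout`.
#' @param max_mismatch maximum substitutions tolerated per tag (default 1).
#' @return list with `status` ("assigned" or a reject reason) and, when
#'   assigned, `plate`, `row`, `row_label`, `col`.
#' @export
decode_tags <- function(fwd_obs, rev_obs, layout, max_mismatch = 1L) {
  fd <- tag_distances(fwd_obs, layout$fwd_tags$tags[seq_len(layout$n_fwd_used)])
  rd <- tag_distances(rev_obs, layout$rev_tags$tags[seq_len(layout$n_rev_used)])
  fi <- which(fd <= max_mismatch)
  ri <- which(rd <= max_mismatch)
  if (length(fi) > 1L || length(ri) > 1L) return(list(status = "ambiguous"))
  if (length(fi) == 0L) return(list(status = "unknown_fwd"))
  if (length(ri) == 0L) return(list(status = "unknown_rev"))
  m <- layout$well_map
  hit <- m[m$fwd_idx == fi & m$rev_idx == ri, ]
  if (nrow(hit) != 1L) return(list(status = "unknown_fwd"))
  list(status = "assigned", plate = hit$plate, row = hit$row,
       row_label = hit$row_label, col = hit$col)
}

#' Serialize / restore a layout as versioned JSON
#'
#' @param layout a `plate_layout`.
#' @param path output (input) path.
#' @return `write_layout` returns `layout` invisibly; `read_layout` returns a
#'   `plate_layout`.
#' @export
write_layout <- function(layout, path) {
  doc <- list(
    format = "pairtcr-layout", version = 1L,
    n_plates = layout$n_plates, tiling = layout$tiling,
    fwd_tags = layout$fwd_tags[c("tags", "tag_length", "min_pairwise_hamming")],
    rev_tags = layout$rev_tags[c("tags", "tag_length", "min_pairwise_hamming")])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(layout)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pairtcr-layout"))
    stop("not a pairtcr layout document", call. = FALSE)
  bs <- function(x) structure(list(tags = x$tags,
                                   tag_length = as.integer(x$tag_length),
                                   min_pairwise_hamming =
                                     as.integer(x$min_pairwise_hamming)),
                              class = "barcode_set")
  build_layout(doc$n_plates, bs(doc$fwd_tags), bs(doc$rev_tags),
               tiling = doc$tiling)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d plates (%dx%d tiling), %d fwd x %d rev tags\n",
              x$n_plates, x$tiling[1], x$tiling[2],
              x$n_fwd_used, x$n_rev_used))
  invisible(x)
}
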