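#' Pair alpha and beta chain records per sorted well
#'
#' One row per well of the sort manifest; chain records attach where present.
#' Records for wells absent from the manifest are reported as orphans with a
#' warning.
#'
#' @param records chain-record tibble from [annotate_wells()] (both chains).
#' @param manifest tibble of sorted wells: plate, row, col,
#'   population_label (e.g. the ground-truth or index-sort table).
#' @return tibble, one row per sorted well: well address, population_label,
#'   has_alpha/has_beta, paired, and the alpha_*/beta_* record fields.
#' @export
pair_wells <- function(records, manifest) {
  key <- function(d) paste(d$plate, d$row, d$col, sep = ":")
  manifest <- as_tibble(manifest)
  mkey <- key(manifest)
  if (anyDuplicated(mkey))
    stop("duplicate wells in manifest", call. = FALSE)
  orphans <- records[!key(records) %in% mkey, , drop = FALSE]
  if (nrow(orphans) > 0L)
    warning(sprintf("%d chain records fall outside the sort manifest",
                    nrow(orphans)), call. = FALSE)
  pick <- function(ch) {
    r <- records[records$chain == ch & key(records) %in% mkey, , drop = FALSE]
    cols <- c("v_id", "j_id", "cdr3_nt", "cdr3_aa", "productive",
              "n_reads_support", "doublet_flag", "sequence")
    out <- r[, c("plate", "row", "col", cols)]
    names(out)[-(1:3)] <- paste0(ch, "_", cols)
    out
  }
  pairs <- manifest[, intersect(c("plate", "row", "row_label", "col",
                                  "population_label"), names(manifest))]
  pairs <- left_join(pairs, pick("alpha"), by = c("plate", "row", "col"))
  pairs <- left_join(pairs, pick("beta"), by = c("plate", "row", "col"))
  mutate(pairs,
         has_alpha = !is.na(.data$alpha_v_id),
         has_beta = !is.na(.data$beta_v_id),
         paired = .data$has_alpha & .data$has_beta)
}

#' Chain-recovery efficiency per population
#'
#' Percentages are computed against sorted input cells (the manifest), not
#' against sequenced reads; `pct_paired <= min(pct_alpha, pct_beta)` always.
#'
#' @param pairs paired-well tibble from [pair_wells()].
#' @return tibble per population: n_cells, pct_alpha, pct_beta, pct_paired,
#'   plus a pooled `"all"` row.
#' @export
efficiency_table <- function(pairs) {
  eff <- function(d, label) {
    tibble(population_label = label, n_cells = nrow(d),
           pct_alpha = 100 * mean(d$has_alpha),
           pct_beta = 100 * mean(d$has_beta),
           pct_paired = 100 * mean(d$paired))
  }
  pops <- split(pairs, pairs$population_label %||% "all")
  pops <- pops[vapply(pops, nrow, integer(1)) > 0L]
  bind_rows(c(lapply(names(pops), function(p) eff(pops[[p]], p)),
              list(eff(pairs, "all"))))
}

#' V gene / family usage frequencies
#'
#' @param records chain-record tibble (or paired table with `alpha_v_id` /
#'   `beta_v_id` columns via [pair_wells()]; chain records are simpler).
#' @param ref a `tcr_reference` (for the family of each V gene).
#' @param group_by optional extra grouping column of `records`
#'   (e.g. `"population_label"`).
#' @return tibble per (group, chain, v_id): count, frequency (sums to 1 per
#'   group and chain) and the gene family.
#' @export
v_usage <- function(records, ref, group_by = NULL) {
  stopifnot(nrow(records) > 0L)
  fam <- ref$segments[, c("id", "family")]
  d <- records[!is.na(records$v_id), ]
  grp <- c(group_by, "chain", "v_id")
  out <- d %>%
    group_by(dplyr::across(dplyr::all_of(grp))) %>%
    summarise(count = dplyr::n(), .groups = "drop_last") %>%
    mutate(frequency = .data$count / sum(.data$count)) %>%
    ungroup()
  out$family <- fam$family[match(out$v_id, fam$id)]
  arrange(out, dplyr::across(dplyr::all_of(grp)))
}

#' Attach index-sort phenotypes to paired wells
#'
#' Left join on (plate, row, col); duplicate phenotype rows for one well are
#' an error and unmatched wells are flagged.
#'
#' @param pairs paired-well tibble.
#' @param index_sort index-sort tibble keyed by plate, row, col.
#' @return `pairs` with phenotype columns and a `phenotype_matched` flag.
#' @export
link_phenotype <- function(pairs, index_sort) {
  keyix <- paste(index_sort$plate, index_sort$row, index_sort$col)
  if (anyDuplicated(keyix))
    stop("duplicate index-sort rows for a well", call. = FALSE)
  drop <- intersect(c("row_label", "population_label"), names(index_sort))
  ix <- index_sort[, setdiff(names(index_sort), drop)]
  out <- left_join(pairs, ix, by = c("plate", "row", "col"))
  pheno_cols <- setdiff(names(ix), c("plate", "row", "col"))
  out$phenotype_matched <- stats::complete.cases(out[, pheno_cols])
  out
}
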