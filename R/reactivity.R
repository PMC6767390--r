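#' Reactivity-classification configuration
#'
#' The default threshold follows the platform's rule: a clone is
#' antigen-reactive when the area under its IL-2 concentration-response
#' curve exceeds 0.5, i.e. 50-fold above the negative-control AUC of
#' 0.01 +/- 0.003.
#'
#' @param auc_threshold reactivity threshold (strict `>`), in
#'   (ng/mL)x(mg/mL).
#' @param neg_control_mean,neg_control_sd negative-control AUC summary.
#' @param log_axis integrate over log10 concentration instead of the linear
#'   axis (zero-concentration points are dropped in log mode).
#' @return a `reactivity_config` list.
#' @export
reactivity_config <- function(auc_threshold = 0.5, neg_control_mean = 0.01,
                              neg_control_sd = 0.003, log_axis = FALSE) {
  stopifnot(auc_threshold > 0)
  structure(list(auc_threshold = auc_threshold,
                 neg_control_mean = neg_control_mean,
                 neg_control_sd = neg_control_sd,
                 log_axis = log_axis), class = "reactivity_config")
}

#' Area under an IL-2 dose-response curve
#'
#' Trapezoidal area of the mean replicate response over antigen
#' concentration on the linear concentration axis, baseline 0; negative
#' responses are clamped to 0 before integration. Input point order is
#' irrelevant.
#'
#' @param curve tibble with `concentration` (mg/mL) and `response` (ng/mL;
#'   replicate rows allowed per concentration).
#' @param log_axis integrate over log10(concentration) (drops
#'   zero-concentration points).
#' @return AUC in (ng/mL)x(mg/mL) (or ng/mL x log10 mg/mL in log mode).
#' @export
compute_auc <- function(curve, log_axis = FALSE) {
  stopifnot(all(curve$concentration >= 0))
  m <- curve %>%
    group_by(.data$concentration) %>%
    summarise(response = mean(.data$response), .groups = "drop") %>%
    arrange(.data$concentration)
  if (log_axis) m <- m[m$concentration > 0, ]
  if (nrow(m) < 2L)
    stop("AUC requires at least 2 distinct concentrations", call. = FALSE)
  x <- if (log_axis) log10(m$concentration) else m$concentration
  y <- pmax(m$response, 0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Classify one clone's reactivity
#'
#' @param curve dose-response tibble ([compute_auc()]) or NULL if `auc`
#'   given.
#' @param cfg a [reactivity_config()].
#' @param auc precomputed AUC (skips integration).
#' @return tibble: auc, fold_over_negative, reactive (strictly above
#'   threshold).
#' @export
classify_reactivity <- function(curve = NULL, cfg = reactivity_config(),
                                auc = NULL) {
  if (is.null(auc)) auc <- compute_auc(curve, cfg$log_axis)
  tibble(auc = auc,
         fold_over_negative = auc / cfg$neg_control_mean,
         reactive = auc > cfg$auc_threshold)
}

#' Batch reactivity report
#'
#' @param curves tibble with `clone_id`, `concentration`, `response` (and
#'   optionally `antigen`); one curve per clone id. Replicates are rows
#'   sharing a concentration; if a `curve_id` column is present, two curves
#'   claiming one clone id are rejected.
#' @param cfg a [reactivity_config()].
#' @return list with `calls` (one row per clone: clone_id, auc,
#'   fold_over_negative, reactive) and `summary` (n_reactive, n_total,
#'   pct_reactive, and min/max response per concentration).
#' @export
batch_report <- function(curves, cfg = reactivity_config()) {
  ids <- unique(curves$clone_id)
  if (length(ids) == 0L) stop("no curves", call. = FALSE)
  if ("curve_id" %in% names(curves)) {
    per_clone <- tapply(curves$curve_id, curves$clone_id,
                        function(x) length(unique(x)))
    if (any(per_clone > 1L)) stop("duplicate clone ids", call. = FALSE)
  }
  per_conc <- curves %>%
    group_by(.data$clone_id, .data$concentration) %>%
    summarise(response = mean(.data$response), .groups = "drop")
  calls <- bind_rows(lapply(ids, function(id) {
    cl <- classify_reactivity(curves[curves$clone_id == id, ], cfg)
    mutate(cl, clone_id = id)
  }))[, c("clone_id", "auc", "fold_over_negative", "reactive")]
  range_tbl <- per_conc %>%
    group_by(.data$concentration) %>%
    summarise(min_response = min(.data$response),
              max_response = max(.data$response), .groups = "drop")
  list(calls = calls,
       summary = list(n_reactive = sum(calls$reactive),
                      n_total = nrow(calls),
                      pct_reactive = 100 * mean(calls$reactive),
                      response_range = range_tbl))
}

#' Simulate a panel of IL-2 dose-response curves
#'
#' Generates `n_reactive` saturating responders (Hill-type curves with
#' peak secretion spanning the observed 0.5-80 ng/mL range at the top
#' antigen dose) and `n_total - n_reactive` negative-control-like flat
#' curves, with log-normal replicate noise.
#'
#' @param n_total,n_reactive panel size and planted responders.
#' @param concentrations antigen doses in mg/mL.
#' @param n_replicates technical replicates per dose.
#' @param seed integer seed.
#' @return curve tibble for [batch_report()] with a `truth_reactive` flag.
#' @export
simulate_reactivity_panel <- function(n_total = 30L, n_reactive = 12L,
                                      concentrations = c(0, 0.031, 0.125,
                                                         0.5, 2),
                                      n_replicates = 2L, seed = 1L) {
  stopifnot(n_reactive <= n_total)
  with_seed(seed, {
    rows <- lapply(seq_len(n_total), function(i) {
      reactive <- i <= n_reactive
      repeat {
        top <- if (reactive) exp(stats::runif(1, log(0.5), log(80))) else 0
        ec50 <- if (reactive) exp(stats::runif(1, log(0.05), log(0.5))) else 1
        mu <- top * concentrations / (concentrations + ec50)
        curve <- do.call(rbind, lapply(seq_along(concentrations), function(k) {
          resp <- mu[k] * stats::rlnorm(n_replicates, 0, 0.15) +
            stats::rnorm(n_replicates, 0.01, 0.003)
          data.frame(clone_id = sprintf("TCR%02d", i),
                     truth_reactive = reactive,
                     concentration = concentrations[k],
                     response = resp)
        }))
        ## planted labels must hold under the AUC rule: redraw borderline
        ## curves so positives land above and negatives below threshold
        auc <- compute_auc(curve)
        if (reactive == (auc > 0.5)) break
      }
      curve
    })
    as_tibble(do.call(rbind, rows))
  })
}
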