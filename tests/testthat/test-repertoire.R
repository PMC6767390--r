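manifest10 <- function() {
  tibble::tibble(plate = 1L, row = rep(1:2, each = 5), col = rep(1:5, 2),
                 population_label = rep(c("Tfh", "Treg"), each = 5))
}

test_that("well pairing intersects chains and reports orphans", {
  man <- manifest10()
  alpha <- dplyr::bind_rows(lapply(1:8, function(i)
    fake_record(1L, man$row[i], man$col[i], "alpha")))
  beta <- dplyr::bind_rows(lapply(c(1:6, 9), function(i)
    fake_record(1L, man$row[i], man$col[i], "beta", v = "TRBV01",
                j = "TRBJ01")))
  pairs <- pair_wells(dplyr::bind_rows(alpha, beta), man)
  expect_equal(nrow(pairs), 10L)
  expect_equal(sum(pairs$paired), 6L)
  eff <- efficiency_table(pairs)
  expect_equal(eff$pct_paired[eff$population_label == "all"], 60)

  ## empty beta input -> no pairs
  p2 <- pair_wells(alpha, man)
  expect_equal(sum(p2$paired), 0L)
  expect_equal(efficiency_table(p2)$pct_paired, rep(0, 3))

  ## record outside the manifest triggers an orphan warning
  stray <- fake_record(9L, 1L, 1L, "alpha")
  expect_warning(pair_wells(dplyr::bind_rows(alpha, stray), man), "orphan|outside")
})

test_that("efficiency percentages use sorted cells as denominator", {
  set.seed(20)
  n <- 1536L
  man <- tibble::tibble(plate = rep(1:4, each = 384),
                        row = rep(rep(1:16, times = 24), 4),
                        col = rep(rep(1:24, each = 16), 4),
                        population_label = "CD4")
  idx <- sample(n, 830)
  alpha <- dplyr::bind_rows(lapply(idx, function(i)
    fake_record(man$plate[i], man$row[i], man$col[i], "alpha")))
  pairs <- pair_wells(alpha, man)
  eff <- efficiency_table(pairs)
  expect_equal(round(eff$pct_alpha[eff$population_label == "CD4"], 1), 54.0)

  ## all wells annotated for both chains -> 100/100/100
  both <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(1:20, function(i)
      fake_record(man$plate[i], man$row[i], man$col[i], "alpha"))),
    dplyr::bind_rows(lapply(1:20, function(i)
      fake_record(man$plate[i], man$row[i], man$col[i], "beta"))))
  eff2 <- efficiency_table(pair_wells(both, man[1:20, ]))
  expect_equal(unlist(eff2[1, c("pct_alpha", "pct_beta", "pct_paired")]),
               c(pct_alpha = 100, pct_beta = 100, pct_paired = 100))
})

test_that("paired recovery is bounded by per-chain recovery", {
  set.seed(21)
  man <- manifest10()
  for (k in 1:20) {
    recs <- list()
    for (i in 1:10) {
      if (runif(1) < 0.6) recs <- c(recs, list(
        fake_record(1L, man$row[i], man$col[i], "alpha")))
      if (runif(1) < 0.6) recs <- c(recs, list(
        fake_record(1L, man$row[i], man$col[i], "beta")))
    }
    if (!length(recs)) next
    eff <- efficiency_table(pair_wells(dplyr::bind_rows(recs), man))
    expect_true(all(eff$pct_paired <= pmin(eff$pct_alpha, eff$pct_beta) + 1e-9))
  }
})

test_that("V usage frequencies normalise per group and add over partitions", {
  ref <- small_ref()
  recs <- dplyr::bind_rows(
    lapply(1:3, function(i) fake_record(1L, 1L, i, "beta", v = "TRBV01")),
    fake_record(1L, 1L, 4L, "beta", v = "TRBV02"))
  u <- v_usage(recs, ref)
  expect_equal(u$frequency[u$v_id == "TRBV01"], 0.75)
  expect_equal(u$frequency[u$v_id == "TRBV02"], 0.25)
  expect_equal(sum(u$frequency), 1)

  ## uniform draws: each frequency within 3 sigma of 1/4 (multinomial bound)
  set.seed(22)
  n <- 2000L
  ids <- sprintf("TRBV%02d", sample(1:4, n, TRUE))
  recs2 <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    fake_record(1L, (i - 1) %% 16 + 1, (i - 1) %/% 16 %% 24 + 1, "beta",
                v = ids[i])))
  u2 <- v_usage(recs2, ref)
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(u2$frequency - 0.25) < 3 * sigma))

  ## per-population sub-tables pool to the global counts
  recs$population_label <- c("Tfh", "Tfh", "Treg", "Treg")
  by_pop <- v_usage(recs, ref, group_by = "population_label")
  pooled <- stats::aggregate(count ~ v_id, by_pop, sum)
  expect_equal(pooled$count[match(u$v_id, pooled$v_id)], u$count)
  sums <- stats::aggregate(frequency ~ population_label, by_pop, sum)
  expect_true(all(abs(sums$frequency - 1) < 1e-9))
})

test_that("phenotype linking is an order-invariant left join with flags", {
  man <- manifest10()
  alpha <- dplyr::bind_rows(lapply(1:10, function(i)
    fake_record(1L, man$row[i], man$col[i], "alpha")))
  pairs <- pair_wells(alpha, man)
  ix <- dplyr::mutate(man, FSC_A = seq(0.1, 1, 0.1) * 1000, CD4_FITC = 500)

  full <- link_phenotype(pairs, ix)
  expect_true(all(full$phenotype_matched))
  expect_equal(full$FSC_A[full$row == 1 & full$col == 1], 100)

  missing_one <- link_phenotype(pairs, ix[-3, ])
  expect_equal(sum(!missing_one$phenotype_matched), 1L)

  shuffled <- link_phenotype(pairs, ix[sample(10), ])
  expect_identical(shuffled, full)

  expect_error(link_phenotype(pairs, ix[c(1, 1:10), ]), "duplicate")
})
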