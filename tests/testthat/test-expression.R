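test_that("replicate averaging and log-ratios follow the stated conventions", {
  expr <- tibble::tibble(
    gene_id = c("g1", "g1", "g2"),
    sample = c("cer", "cer", "cer"),
    value = c(90, 110, 42))
  av <- average_replicates(expr)
  expect_equal(av$value[av$gene_id == "g1"], 100)
  expect_equal(av$value[av$gene_id == "g2"], 42)

  expect_equal(log2_ratio(200, 100), 1)
  expect_equal(log2_ratio(100, 100), 0)
  expect_true(is.na(log2_ratio(0, 50)))                       # excluded
  expect_equal(log2_ratio(0, 50, policy = "pseudocount", pseudocount = 0.5),
               log2(0.5 / 50.5))
})

test_that("expression divergence builds total and cis ratios from raw values", {
  raw <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    total_x = c(200, 100, 0), total_y = c(100, 100, 50),
    hyb_x_allele = c(80, 50, 10), hyb_y_allele = c(40, 50, 10))
  ed <- expression_divergence(raw)
  expect_equal(ed$total_log2, c(1, 0, NA))
  expect_equal(ed$cis_log2, c(1, 0, 0))

  pre <- tibble::tibble(gene_id = "g1", total_log2 = 0.3, cis_log2 = -0.2)
  expect_equal(expression_divergence(pre)$cis_log2, -0.2)
  expect_error(expression_divergence(tibble::tibble(gene_id = "g1")),
               "neither")
})

test_that("the cis test picks the observed direction, doubles, and caps", {
  px <- pool_fixture(n = 200, n_essential = 40, seed = 77)
  focal <- px$ids[1:10]
  ed <- tibble::tibble(gene_id = px$ids, cis_log2 = px$stats$value)

  # strong positive shift: direction greater, doubled p near 0
  ed_hi <- dplyr::mutate(ed, cis_log2 = ifelse(.data$gene_id %in% focal,
                                               cis_log2 + 5, cis_log2))
  hi <- cis_directionality_test(ed_hi, focal, px$ids, px$ann,
                                n_resamples = 1000, seed = 1)
  expect_equal(hi$direction, "greater")
  expect_equal(hi$side, "two-sided-doubled")
  expect_lt(hi$p_value, 0.01)

  # strong negative shift: direction flips to less, still significant
  ed_lo <- dplyr::mutate(ed, cis_log2 = ifelse(.data$gene_id %in% focal,
                                               cis_log2 - 5, cis_log2))
  lo <- cis_directionality_test(ed_lo, focal, px$ids, px$ann,
                                n_resamples = 1000, seed = 1)
  expect_equal(lo$direction, "less")
  expect_lt(lo$p_value, 0.01)

  # doubling invariant holds on arbitrary inputs
  mid <- cis_directionality_test(ed, focal, px$ids, px$ann,
                                 n_resamples = 500, seed = 2)
  expect_equal(mid$p_value, min(1, 2 * mid$p_one_sided))

  # constant statistic: one-sided p = 1, capped two-sided = 1
  edc <- dplyr::mutate(ed, cis_log2 = 1)
  cst <- cis_directionality_test(edc, focal, px$ids, px$ann,
                                 n_resamples = 200, seed = 3)
  expect_equal(cst$p_value, 1)
})

test_that("the total-expression test is one-sided for elevated species-X expression", {
  px <- pool_fixture(n = 200, n_essential = 40, seed = 78)
  focal <- px$ids[1:10]
  ed <- tibble::tibble(gene_id = px$ids, total_log2 = px$stats$value)

  up <- dplyr::mutate(ed, total_log2 = ifelse(.data$gene_id %in% focal,
                                              total_log2 + 3, total_log2))
  r_up <- total_elevation_test(up, focal, px$ids, px$ann,
                               n_resamples = 1000, seed = 4)
  expect_equal(r_up$side, "greater")
  expect_lt(r_up$p_value, 0.01)

  down <- dplyr::mutate(ed, total_log2 = ifelse(.data$gene_id %in% focal,
                                                total_log2 - 3, total_log2))
  r_down <- total_elevation_test(down, focal, px$ids, px$ann,
                                 n_resamples = 1000, seed = 4)
  expect_equal(r_down$p_value, 1)  # wrong direction under a one-sided test
})

test_that("cis and total tests share the resampling engine exactly", {
  px <- pool_fixture(n = 150, n_essential = 30, seed = 79)
  focal <- px$ids[5:14]
  vals <- abs(px$stats$value) + 0.1  # positive median: cis direction greater
  ed <- tibble::tibble(gene_id = px$ids, total_log2 = vals, cis_log2 = vals)
  cis <- cis_directionality_test(ed, focal, px$ids, px$ann,
                                 n_resamples = 800, seed = 11)
  tot <- total_elevation_test(ed, focal, px$ids, px$ann,
                              n_resamples = 800, seed = 11)
  expect_equal(cis$p_one_sided, tot$p_value)
  expect_identical(cis$resample_medians, tot$resample_medians)
})

test_that("null expression data yields calibrated p-values and shifted data is detected", {
  # null: focal drawn from the pool's own distribution
  n_data <- 200
  hits <- withr::with_seed(123, {
    sum(vapply(seq_len(n_data), function(i) {
      ids <- sprintf("e%04d", 1:400)
      ann <- tibble::tibble(gene_id = ids, essential = rep(c(TRUE, FALSE), 200))
      ed <- tibble::tibble(gene_id = ids, total_log2 = rnorm(400))
      total_elevation_test(ed, ids[1:20], ids, ann, n_resamples = 400,
                           seed = 1000 + i)$p_value <= 0.05
    }, logical(1)))
  })
  # exact binomial 99% band around 0.05 for 200 trials
  expect_gte(hits / n_data, 0.017)
  expect_lte(hits / n_data, 0.098)

  # power: focal cis shifted by one pool SD, g = 26, pool = 3500
  n_power <- 60
  wins <- withr::with_seed(321, {
    sum(vapply(seq_len(n_power), function(i) {
      ids <- sprintf("e%04d", 1:3500)
      ann <- tibble::tibble(gene_id = ids,
                            essential = rep(c(TRUE, rep(FALSE, 4)), 700))
      sd <- 0.5
      ed <- tibble::tibble(
        gene_id = ids,
        cis_log2 = rnorm(3500, mean = c(rep(sd, 26), rep(0, 3474)),
                         sd = sd))
      cis_directionality_test(ed, ids[1:26], ids, ann, n_resamples = 1000,
                              seed = 2000 + i)$p_value <= 0.05
    }, logical(1)))
  })
  expect_gte(wins / n_power, 0.8)
})
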