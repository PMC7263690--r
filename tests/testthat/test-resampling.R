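test_that("focal median uses the even-count convention and errors on disjoint sets", {
  stats <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                          value = c(1, 2, 3, 10))
  ann <- tibble::tibble(gene_id = c("a", "b", "c", "d"),
                        essential = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(focal_median(stats, c("a", "b", "c"))$m_true, 2)
  fm <- focal_median(stats, c("a", "b", "c", "d"), ann)
  expect_equal(fm$m_true, 2.5)
  expect_equal(fm$g, 4L)
  expect_equal(fm$e_focal, 2L)
  # genes absent from the table do not count toward g
  expect_equal(focal_median(stats, c("a", "zz"))$g, 1L)
  expect_error(focal_median(stats, c("zz")), "no focal gene")
})

test_that("matched cohorts hit the stratum counts exactly or fail loudly", {
  px <- pool_fixture(n = 110, n_essential = 10)
  withr::with_seed(1, {
    coh <- draw_matched_cohort(px$ids, px$ann, g = 4, e_focal = 1)
    expect_length(coh, 4)
    expect_equal(sum(px$ann$essential[match(coh, px$ann$gene_id)]), 1)
    coh0 <- draw_matched_cohort(px$ids, px$ann, g = 5, e_focal = 0)
    expect_equal(sum(px$ann$essential[match(coh0, px$ann$gene_id)]), 0)
  })
  expect_error(draw_matched_cohort(px$ids, px$ann, g = 20, e_focal = 15),
               "essential stratum")
  expect_error(draw_matched_cohort(px$ids[1:3], px$ann, g = 5, e_focal = 0),
               "non-essential stratum")
})

test_that("empirical p-values behave at the degenerate and enumerable limits", {
  ann3 <- tibble::tibble(gene_id = c("a", "b", "c"), essential = FALSE)
  stats3 <- tibble::tibble(gene_id = c("a", "b", "c"), value = c(1, 2, 3))

  # constant statistic: every resample median >= m_true
  const <- dplyr::mutate(stats3, value = 7)
  r <- enrichment_test(const, "a", c("a", "b", "c"), ann3,
                       n_resamples = 200, seed = 1, stratified = FALSE)
  expect_equal(r$p_value, 1)

  # g = 1 focal at the maximum of a 3-gene pool: p -> 1/3
  r2 <- enrichment_test(stats3, "c", c("a", "b", "c"), ann3,
                        n_resamples = 10000, seed = 2, stratified = FALSE)
  expect_lt(abs(r2$p_value - 1 / 3), 0.02)

  # m_true at the pool minimum: p = 1 for side greater
  r3 <- enrichment_test(stats3, "a", c("a", "b", "c"), ann3,
                        n_resamples = 500, seed = 3, stratified = FALSE)
  expect_equal(r3$p_value, 1)
})

test_that("stratified resampling p agrees with exhaustive enumeration", {
  px <- pool_fixture(n = 7, n_essential = 3, seed = 5)
  focal <- px$ids[c(1, 4)]  # one essential, one not
  fm <- focal_median(px$stats, focal, px$ann)
  exact <- oracle_enrichment_exact(px$stats$value, px$ann$essential,
                                   g = fm$g, e_focal = fm$e_focal,
                                   m_true = fm$m_true)
  r <- enrichment_test(px$stats, focal, px$ids, px$ann,
                       n_resamples = 20000, seed = 7)
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(r$p_value - exact), max(3 * se, 1e-9))
})

test_that("the engine is deterministic under seed and monotone in the focal statistic", {
  px <- pool_fixture(n = 60, n_essential = 15, seed = 31)
  focal <- px$ids[1:6]
  r1 <- enrichment_test(px$stats, focal, px$ids, px$ann,
                        n_resamples = 2000, seed = 42)
  r2 <- enrichment_test(px$stats, focal, px$ids, px$ann,
                        n_resamples = 2000, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$resample_medians, r2$resample_medians)
  expect_equal(r1$seed, 42L)

  # raising every focal value (pool held fixed via exclusion) cannot
  # increase the side = greater p-value
  shifts <- c(0, 0.2, 0.5, 1, 3)
  ps <- vapply(shifts, function(s) {
    st <- px$stats
    st$value[st$gene_id %in% focal] <- st$value[st$gene_id %in% focal] + s
    enrichment_test(st, focal, setdiff(px$ids, focal), px$ann,
                    n_resamples = 2000, seed = 42,
                    exclude_focal = TRUE)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("one-sided p-values double into capped two-sided ones", {
  expect_equal(two_sided_from_one_sided(0.25), 0.5)
  expect_equal(two_sided_from_one_sided(0.6), 1)
  expect_equal(two_sided_from_one_sided(0), 0)
  expect_equal(two_sided_from_one_sided(c(0.1, 0.5, 1)), c(0.2, 1, 1))
})

test_that("tidy, glance and autoplot expose the result fields", {
  px <- pool_fixture()
  r <- enrichment_test(px$stats, px$ids[1:4], px$ids, px$ann,
                       n_resamples = 100, seed = 9, focal_term = "GO:0005778")
  td <- tidy(r)
  expect_equal(td$focal_term, "GO:0005778")
  expect_equal(td$n_at_least / td$n_resamples, td$p_value)
  expect_s3_class(glance(r), "tbl_df")
  expect_s3_class(autoplot(r), "ggplot")
})
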