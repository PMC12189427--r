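test_that("spearman recovers monotone relationships and exact small-n p", {
  expect_equal(spearman(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman(1:4, c(40, 30, 20, 10))$rho, -1)
  sp <- spearman(1:3, c(2, 1, 3))
  expect_equal(sp$rho, 0.5)
  expect_equal(sp$method, "exact permutation")
  # exact permutation p for perfect monotone n=4: 2/4! two-sided
  expect_equal(spearman(1:4, 1:4)$p_value, 2 / 24)
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(c(1, 2, NA), 1:3), "non-finite")
})

test_that("constant input flags rho as undefined instead of a number", {
  sp <- spearman(rep(1, 5), 1:5)
  expect_true(is.na(sp$rho))
  expect_true(is.na(sp$p_value))
  expect_match(sp$method, "undefined")
})

test_that("rho is invariant under strictly increasing transforms", {
  set.seed(112)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r0 <- spearman(x, y)$rho
    expect_equal(spearman(exp(x), y)$rho, r0)
    expect_equal(spearman(x, y^3)$rho, r0)
    expect_equal(spearman(rank(x), 2 * y + 7)$rho, r0)
  }
})

test_that("t-approximation is close to cor.test for larger n", {
  set.seed(113)
  x <- rnorm(40); y <- x + rnorm(40)
  sp <- spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sp$rho, unname(ct$estimate))
  expect_equal(sp$p_value, ct$p.value, tolerance = 0.05)
})

test_that("zero-rate intervals are dropped without touching survivors", {
  r <- c(0, 1, 0, 2); f <- c(5, 6, 7, 8)
  flt <- exclude_zero_intervals(r, f)
  expect_equal(flt$rates, c(1, 2))
  expect_equal(flt$features, c(6, 8))
  expect_identical(flt$n_dropped, 2L)
  all_pos <- exclude_zero_intervals(1:4, f)
  expect_equal(all_pos$rates, 1:4)
  expect_identical(all_pos$n_dropped, 0L)
  expect_error(exclude_zero_intervals(c(0, 0), c(1, 2)),
               "no recombining intervals")
})

make_pair <- function(chrom_name, n, rate, gc = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- build_interval_grid(n * 1e5, 1e5)
  rec <- structure(
    data.frame(chrom = chrom_name, start = g$intervals$start,
               end = g$intervals$end, n_foci = 0L, cM = rate / 10,
               rate_cM_per_Mb = rate),
    class = c("recombination_track", "data.frame"), n_cells = 100L,
    interval_size = 1e5)
  feat <- toy_feature_track(g, chrom_name, gc = gc %||% rate)
  list(rec = rec, feat = feat)
}

test_that("correlate_tracks runs per chromosome and pooled", {
  set.seed(114)
  p1 <- make_pair("c1", 10, runif(10, 0.1, 5))
  p2 <- make_pair("c2", 10, runif(10, 0.1, 5))
  res <- correlate_tracks(list(p1$rec, p2$rec), list(p1$feat, p2$feat),
                          features = "gc", pooled = c("c1", "c2"))
  expect_s3_class(res, "association_result")
  # feature == rate gives rho = 1 in every scope
  expect_equal(res$rho, rep(1, 3))
  pooled <- res[res$scope == "pooled_c1_c2", ]
  expect_identical(pooled$n_pairs, 20L)
  expect_identical(sum(res$n_pairs[res$scope != "pooled_c1_c2"]),
                   pooled$n_pairs)
})

test_that("grid mismatch is rejected before statistics", {
  set.seed(115)
  p1 <- make_pair("c1", 10, runif(10, 0.1, 5))
  g2 <- build_interval_grid(10 * 1e5, 2e5)
  feat_bad <- toy_feature_track(g2, "c1")
  expect_error(correlate_tracks(list(p1$rec), list(feat_bad),
                                features = "gc"), "grid mismatch")
})

test_that("nonzero_only mode filters pairs exactly as the filter oracle", {
  set.seed(116)
  rate <- c(0, 0, 0, runif(12, 0.1, 4))
  gc <- runif(15, 0.35, 0.55)
  p <- make_pair("c1", 15, rate, gc = gc)
  res_all <- correlate_tracks(list(p$rec), list(p$feat), features = "gc")
  res_nz <- correlate_tracks(list(p$rec), list(p$feat), features = "gc",
                             mode = "nonzero_only")
  expect_identical(res_all$n_pairs, 15L)
  expect_identical(res_nz$n_pairs, 12L)
  expect_true(res_nz$zero_excluded)
  expect_false(res_all$zero_excluded)
  flt <- exclude_zero_intervals(rate, gc)
  expect_equal(res_nz$rho, spearman(flt$rates, flt$features)$rho)
})

test_that("missing feature values are excluded pairwise", {
  set.seed(117)
  rate <- runif(12, 0.1, 4)
  gc <- runif(12, 0.35, 0.55)
  gc[c(3, 7)] <- NA
  p <- make_pair("c1", 12, rate, gc = gc)
  res <- correlate_tracks(list(p$rec), list(p$feat), features = "gc")
  expect_identical(res$n_pairs, 10L)
  expect_equal(res$rho, spearman(rate[-c(3, 7)], gc[-c(3, 7)])$rho)
})

test_that("null features rarely reach significance", {
  set.seed(118)
  hits <- 0L
  for (i in 1:200) {
    x <- runif(100); y <- runif(100)
    sp <- spearman(x, y)
    if (sp$p_value <= 0.05) hits <- hits + 1L
    expect_lt(abs(sp$rho), 0.5)
  }
  expect_gte(200L - hits, 180L)  # p > 0.05 in >= 90% of replicates
})

test_that("format_matrix shows significant cells with stars, blanks the rest", {
  res <- structure(
    data.frame(scope = c("c1", "c1", "c2"),
               feature = c("gc", "cgi", "gc"),
               rho = c(0.65, 0.2, 0.4),
               p_value = c(0.004, 0.5, 0.3),
               n_pairs = 30L, zero_excluded = FALSE,
               significant = c(TRUE, FALSE, FALSE),
               stars = c("**", "", "")),
    class = c("association_result", "data.frame"))
  expect_warning(m <- format_matrix(res), "cgi")
  expect_identical(m["c1", "gc"], "0.65 **")
  expect_identical(m["c2", "gc"], "")
  expect_false("cgi" %in% colnames(m))
  expect_identical(significance_stars(c(0.04, 0.009, 0.0009, 0.2)),
                   c("*", "**", "***", ""))
})

test_that("arm masks restrict the correlated intervals", {
  set.seed(119)
  rate <- runif(20, 0.1, 4)
  p <- make_pair("c1", 20, rate)
  g <- build_interval_grid(20 * 1e5, 1e5)
  mask <- mask_intervals(g, 10e5, 20e5)  # long arm only
  res <- correlate_tracks(list(p$rec), list(p$feat), features = "gc",
                          masks = list(c1 = mask))
  expect_identical(res$n_pairs, 10L)
})
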