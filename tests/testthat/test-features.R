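test_that("GC content counts C+G over unambiguous bases", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATGCNN"), 0.5)
  expect_equal(gc_content("atgc"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("ATXGC"), "position 3")
})

test_that("obs/exp CpG follows N_CpG * L / (N_C * N_G)", {
  expect_equal(obs_exp_cpg("CCGG"), 1.0)
  expect_equal(obs_exp_cpg("AAAA"), 0)
  expect_equal(obs_exp_cpg(strrep("CG", 150)), 2.0)
  expect_error(obs_exp_cpg(""), "empty")
})

test_that("gc/oe agree with naive counting oracles on random sequences", {
  set.seed(107)
  for (i in 1:25) {
    s <- random_sequence(sample(50:500, 1), i)
    expect_equal(gc_content(s), oracle_gc(s))
    expect_equal(obs_exp_cpg(s), oracle_oe(s))
  }
})

test_that("island caller handles the canonical constructions", {
  # a 300 bp CpG-rich repeat is found as one island spanning the repeat
  s <- paste0(strrep("A", 300), strrep("CG", 150), strrep("A", 300))
  isl <- call_cpg_islands(s)
  expect_identical(nrow(isl), 1L)
  expect_lte(isl$start, 300)
  expect_gte(isl$end, 600)
  # every returned island re-satisfies the three criteria
  sub <- substr(s, isl$start + 1, isl$end)
  expect_gt(nchar(sub), 200)
  expect_gte(gc_content(sub), 0.5)
  expect_gte(obs_exp_cpg(sub), 0.6)

  # poly-A has no islands
  expect_identical(nrow(call_cpg_islands(strrep("A", 300))), 0L)

  # a CpG stretch too short to support any region longer than 200 bp
  # (100 bp repeat: maximal GC-0.5 extension tops out at exactly 200 bp)
  short <- paste0(strrep("A", 300), strrep("CG", 50), strrep("A", 300))
  expect_identical(nrow(call_cpg_islands(short)), 0L)
})

test_that("islands are disjoint, sorted, and re-satisfy the criteria", {
  set.seed(108)
  for (i in 1:10) {
    s <- random_sequence(sample(800:2000, 1), i)
    isl <- call_cpg_islands(s)
    if (nrow(isl) == 0) next
    expect_true(all(diff(isl$start) > 0))
    expect_true(all(utils::head(isl$end, -1) <= isl$start[-1]))
    for (j in seq_len(nrow(isl))) {
      sub <- substr(s, isl$start[j] + 1, isl$end[j])
      expect_gt(nchar(sub), 200)
      expect_gte(gc_content(sub), 0.5)
      expect_gte(obs_exp_cpg(sub), 0.6)
      expect_equal(gc_content(sub), isl$gc_fraction[j])
      expect_equal(obs_exp_cpg(sub), isl$obs_exp_cpg[j])
    }
  }
})

test_that("caller matches the brute-force search on a quick sample", {
  set.seed(109)
  for (i in 1:20) {
    s <- random_sequence(sample(300:1200, 1), i)
    a <- call_cpg_islands(s)
    b <- oracle_islands(s)
    expect_identical(nrow(a), nrow(b))
    expect_equal(a$start, b$start)
    expect_equal(a$end, b$end)
  }
})

test_that("GC is additive over partitions with N-exclusion respected", {
  set.seed(110)
  s <- random_sequence(3000, 2)  # includes Ns
  cuts <- sort(sample(100:2900, 4))
  parts <- substring(s, c(1, cuts + 1), c(cuts, 3000))
  counts <- vapply(parts, function(p) {
    ch <- strsplit(toupper(p), "")[[1]]
    sum(ch != "N")
  }, numeric(1))
  gcs <- vapply(parts, gc_content, numeric(1))
  expect_equal(gc_content(s), sum(gcs * counts) / sum(counts))
})

test_that("feature profiles compute per-interval GC, CGI and gene density", {
  ch <- chromosome_model("t1", 3000)
  g <- build_interval_grid(ch, 1000)
  set.seed(111)
  s <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  genes <- data.frame(chrom = "t1", start = c(100, 900, 1500, 2500))
  ft <- feature_profile(s, genes, g, ch)
  expect_equal(ft$gene_count, c(2L, 1L, 1L))
  expect_equal(ft$gene_pct, c(50, 25, 25))
  expect_equal(sum(ft$gene_pct), 100)
  expect_equal(ft$gc, vapply(1:3, function(i)
    oracle_gc(substr(s, (i - 1) * 1000 + 1, i * 1000)), numeric(1)))

  # all genes in one interval
  ft1 <- feature_profile(s, data.frame(chrom = "t1", start = c(10, 20, 30)),
                         g, ch)
  expect_equal(ft1$gene_pct, c(100, 0, 0))

  # an all-N interval: GC flagged missing, no islands
  s2 <- paste0(strrep("N", 1000), substr(s, 1001, 3000))
  ft2 <- feature_profile(s2, genes, g, ch)
  expect_true(is.na(ft2$gc[1]))
  expect_identical(ft2$cgi_count[1], 0L)

  # missing annotation flags gene_pct rather than fabricating zeros
  expect_warning(ftn <- feature_profile(s, NULL, g, ch), "gene_pct undefined")
  expect_true(all(is.na(ftn$gene_pct)))
  expect_error(
    feature_profile(s, data.frame(chrom = "t1", start = 5000), g, ch),
    "outside")
})

test_that("CGI counts assign islands to intervals by start position", {
  ch <- chromosome_model("t2", 2000)
  g <- build_interval_grid(ch, 1000)
  # island straddling the interval boundary: counted once, in interval 1
  s <- paste0(strrep("A", 700), strrep("CG", 300), strrep("A", 700))
  suppressWarnings(ft <- feature_profile(s, NULL, g, ch))
  expect_identical(sum(ft$cgi_count), 1L)
  expect_identical(ft$cgi_count[1], 1L)
})
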