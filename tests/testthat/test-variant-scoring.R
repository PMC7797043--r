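test_that("allele windows are centered with the variant at offset 500", {
  g <- random_genome(seed = 51, len = 5000)
  base_at <- function(pos) as.character(Biostrings::subseq(g[[1]], pos, pos))
  ref <- base_at(2500)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- data.frame(chrom = "chr1", pos = 2500L, id = "v1",
                  ref = ref, alt = alt)
  w <- extract_allele_windows(g, v)
  expect_equal(Biostrings::width(w$ref), 1000L)
  rs <- as.character(w$ref[[1]]); as <- as.character(w$alt[[1]])
  d <- which(strsplit(rs, "")[[1]] != strsplit(as, "")[[1]])
  expect_equal(d, 501L)                    # 0-based offset 500
  expect_equal(substr(rs, 501, 501), ref)

  # ref == alt gives identical windows
  v2 <- transform(v, alt = ref, id = "v2")
  w2 <- extract_allele_windows(g, v2)
  expect_identical(as.character(w2$ref), as.character(w2$alt))

  # a 3 bp deletion keeps the alt window at 1000 bp using downstream bases
  ref3 <- as.character(Biostrings::subseq(g[[1]], 2500, 2503))
  v3 <- data.frame(chrom = "chr1", pos = 2500L, id = "v3",
                   ref = ref3, alt = substr(ref3, 1, 1))
  w3 <- extract_allele_windows(g, v3)
  expect_equal(Biostrings::width(w3$alt), 1000L)
  expect_identical(substr(as.character(w3$alt[[1]]), 502, 1000),
                   as.character(Biostrings::subseq(g[[1]], 2504, 3002)))

  # ref mismatch and near-edge variants are skipped with warnings
  wrong_ref <- setdiff(c("A", "C", "G", "T"), base_at(2600))[1]
  vbad <- data.frame(chrom = c("chr1", "chr1"), pos = c(2600L, 100L),
                     id = c("bad", "edge"),
                     ref = c(wrong_ref, base_at(100)), alt = c("A", "C"))
  expect_warning(expect_warning(wb <- extract_allele_windows(g, vbad),
                                "does not match"), "chromosome end")
  expect_length(wb$kept, 0L)
  expect_equal(nrow(wb$skipped), 2L)
})

test_that("SAD records satisfy the Alt minus Ref definition", {
  g <- random_genome(seed = 52, len = 5000)
  m <- tiny_model(n_features = 2, input_length = 1000)
  base_at <- function(pos) as.character(Biostrings::subseq(g[[1]], pos, pos))
  v <- data.frame(chrom = "chr1", pos = c(1500L, 2500L),
                  id = c("v1", "v2"),
                  ref = c(base_at(1500), base_at(2500)),
                  alt = c("A", "C"), stringsAsFactors = FALSE)
  v$alt[1] <- setdiff(c("A", "C", "G", "T"), v$ref[1])[1]
  v$alt[2] <- v$ref[2]                       # ref == alt -> SAD 0
  sc <- sad_scores(m, v, g)
  expect_equal(nrow(sc$records), 4L)
  expect_equal(sc$records$sad, sc$records$alt_prob - sc$records$ref_prob,
               tolerance = 1e-12)
  expect_true(all(sc$records$sad[sc$records$id == "v2"] == 0))
  expect_equal(sc$summary$mean_abs_sad[2], 0)

  # antisymmetry under allele swap at the same site
  v_fwd <- v[1, ]
  g_swap <- g
  # write the alt allele into the genome so the swapped scoring is valid
  tmp <- as.character(g[[1]])
  substr(tmp, 1500, 1500) <- v$alt[1]
  g_swap <- Biostrings::DNAStringSet(c(chr1 = tmp))
  v_rev <- data.frame(chrom = "chr1", pos = 1500L, id = "r1",
                      ref = v$alt[1], alt = v$ref[1])
  s_fwd <- sad_scores(m, v_fwd, g)$records$sad
  s_rev <- sad_scores(m, v_rev, g_swap)$records$sad
  expect_equal(s_fwd, -s_rev, tolerance = 1e-12)
})

test_that("saturated mutagenesis agrees with per-variant scoring", {
  g <- random_genome(seed = 53, len = 4000)
  m <- tiny_model(n_features = 2, input_length = 1000)
  grid <- saturated_mutagenesis(m, g, "chr1", 1800, 1811)
  expect_equal(dim(grid), c(12L, 4L, 2L))
  # reference-base entries are exactly zero
  for (i in 1:12) {
    ref <- as.character(Biostrings::subseq(g[[1]], 1799 + i, 1799 + i))
    expect_true(all(grid[i, ref, ] == 0))
  }
  # random entries equal a direct single-variant scoring
  set.seed(54)
  for (k in 1:10) {
    i <- sample(12, 1)
    ref <- as.character(Biostrings::subseq(g[[1]], 1799 + i, 1799 + i))
    b <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- data.frame(chrom = "chr1", pos = 1799L + i, id = "m",
                    ref = ref, alt = b)
    sc <- sad_scores(m, v, g)$records
    for (f in 1:2)
      expect_equal(grid[i, b, f], sc$sad[f], tolerance = 1e-9)
  }
  expect_error(saturated_mutagenesis(m, g, "chr1", 1000, 2500, cap = 1000),
               "cap")
})

test_that("the rank-sum test matches exact enumeration and the base oracle", {
  # all of A above all of B with n = m = 5: p = 1 / choose(10, 5)
  r <- deepfun:::wilcoxon_rank_sum(6:10, 1:5, "greater")
  expect_equal(r$p.value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_true(r$exact)

  # identical groups: one-sided p near 0.5
  set.seed(55)
  x <- runif(6)
  ri <- deepfun:::wilcoxon_rank_sum(x, x, "greater")
  expect_gt(ri$p.value, 0.4)
  expect_lt(ri$p.value, 0.65)

  expect_warning(rt <- deepfun:::wilcoxon_rank_sum(rep(1, 5), rep(1, 4)),
                 "tied")
  expect_equal(rt$p.value, 1)

  # large-sample path against stats::wilcox.test
  for (i in 1:10) {
    a <- rnorm(30, mean = 0.3); b <- rnorm(25)
    mine <- deepfun:::wilcoxon_rank_sum(a, b, "greater")
    ref <- stats::wilcox.test(a, b, alternative = "greater",
                              exact = FALSE, correct = TRUE)
    expect_false(mine$exact)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-9)
  }
  # exact path against stats::wilcox.test where both are exact
  for (i in 1:10) {
    a <- runif(6); b <- runif(8)
    mine <- deepfun:::wilcoxon_rank_sum(a, b, "greater")
    ref <- stats::wilcox.test(a, b, alternative = "greater", exact = TRUE)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("group comparison reports the threshold proportion curve", {
  set.seed(56)
  a <- abs(rnorm(20, 0.3)); b <- abs(rnorm(20, 0.05, 0.02))
  res <- compare_sad_groups(a, b, thresholds = c(0, 0.1, 0.5))
  expect_equal(res$curve$prop_a[1], 1)
  expect_equal(res$curve$prop_b[1], 1)
  expect_equal(res$curve$prop_a[2], mean(a >= 0.1))
  expect_true(res$p.value < 0.05)
})
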