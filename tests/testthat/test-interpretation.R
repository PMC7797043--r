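test_that("information content matches its closed-form values", {
  uni <- matrix(0.25, 19, 4)
  expect_equal(info_content(uni), 0)
  onehot <- matrix(0, 19, 4); onehot[, 1] <- 1
  expect_equal(info_content(onehot), 38)
  half <- uni; half[1, ] <- c(0.5, 0.5, 0, 0)
  expect_equal(info_content(half), 1)
  expect_error(info_content(matrix(2, 19, 4)), "outside")

  # invariant under position permutation; increases toward one-hot
  set.seed(61)
  m <- matrix(rgamma(19 * 4, 1), 19, 4); m <- m / rowSums(m)
  expect_equal(info_content(m), info_content(m[sample(19), ]))
  # moving one position from uniform toward one-hot strictly raises IC
  flat <- matrix(0.25, 19, 4)
  prev <- info_content(flat)
  for (w in seq(0.2, 1, by = 0.2)) {
    sharper <- flat
    sharper[5, ] <- (1 - w) * rep(0.25, 4) + w * c(1, 0, 0, 0)
    cur <- info_content(sharper)
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("MEME files round-trip to 1e-9", {
  set.seed(62)
  mats <- list(m1 = matrix(rgamma(8 * 4, 1), 8, 4),
               m2 = matrix(rgamma(12 * 4, 1), 12, 4))
  mats <- lapply(mats, function(m) {
    m <- m / rowSums(m); colnames(m) <- c("A", "C", "G", "T"); m
  })
  path <- tempfile(fileext = ".meme")
  write_meme(mats, path)
  back <- read_meme(path)
  expect_equal(names(back), names(mats))
  expect_equal(back$m1, mats$m1, tolerance = 1e-9)
  expect_equal(back$m2, mats$m2, tolerance = 1e-9)
})

test_that("motif matching finds identical PWMs and rejects uniform noise", {
  set.seed(63)
  target <- deepfun:::consensus_to_pwm("TGACGTCA")
  fake_pwms <- structure(list(
    filter001 = list(pwm = rbind(matrix(0.25, 5, 4,
                                        dimnames = list(NULL, c("A","C","G","T"))),
                                 target,
                                 matrix(0.25, 6, 4,
                                        dimnames = list(NULL, c("A","C","G","T")))),
                     support = 10L, ic = 10)),
    class = "filter_pwms", background = rep(0.25, 4), width = 19L)
  db <- list(hit = target,
             other = deepfun:::consensus_to_pwm("ACAATTGT"))
  mm <- match_motifs(fake_pwms, db, n_null = 200, seed = 64)
  best <- mm[mm$best, ]
  expect_equal(best$motif, "hit")
  expect_equal(best$similarity, 1, tolerance = 1e-9)
  expect_equal(best$offset, 5L)
  expect_equal(best$orientation, "+")

  # database of unrelated uniform motifs: nothing passes q < 0.1
  uni_db <- lapply(1:4, function(i) matrix(0.25, 8, 4,
                                           dimnames = list(NULL, c("A","C","G","T"))))
  names(uni_db) <- paste0("u", 1:4)
  mm2 <- match_motifs(fake_pwms, uni_db, n_null = 200, seed = 65)
  expect_false(any(mm2$significant))
  expect_error(match_motifs(fake_pwms, list()), "empty")
})

test_that("filter PWMs stack half-max alignments into valid probabilities", {
  g <- random_genome(seed = 66, len = 30000)
  pl <- plant_motif_features(g, motifs = example_motifs()[1], n_features = 1,
                             peaks_per_feature = 20, seed = 67)
  sites <- build_active_sites(pl$peaks, pl$genome)
  lab <- build_label_matrix(sites, pl$peaks)
  seqs <- site_sequences(sites, pl$genome)
  X <- deepfun:::encode_batch(seqs)
  m <- tiny_model(n_features = 1, input_length = 1000)
  pw <- filter_to_pwm(m, X)
  expect_length(pw, 6L)
  for (f in pw) {
    expect_equal(rowSums(f$pwm), rep(1, 19), tolerance = 1e-9)
    expect_gte(f$ic, 0)
  }
  # a silenced filter returns the background PWM with zero support
  m0 <- tiny_model(n_features = 1, input_length = 1000,
                   conv_activation = "relu", batch_norm = FALSE)
  m0$params$conv_W[[1]][2, ] <- 0
  m0$params$conv_b[[1]][2] <- 0
  pw0 <- filter_to_pwm(m0, X)
  expect_equal(pw0[[2]]$support, 0L)
  expect_equal(pw0[[2]]$pwm, matrix(0.25, 19, 4,
                                    dimnames = list(NULL, c("A","C","G","T"))))
})

test_that("filter influence is zero for constant filters and sums squares", {
  m <- tiny_model(n_features = 2, input_length = 300)
  # silence one filter: its output map is constant, so mean-replacement is
  # the identity and its influence must vanish
  m$params$conv_W[[1]][3, ] <- 0
  X <- random_onehot_batch(12, 300, seed = 68)
  infl <- filter_influence(m, X, n_repeats = 1)
  expect_equal(unname(infl$global["filter003"]), 0, tolerance = 1e-12)
  expect_equal(infl$global, rowSums(infl$per_feature^2), tolerance = 1e-9)
  # deterministic when the whole set is used
  infl2 <- filter_influence(m, X, n_repeats = 1)
  expect_identical(infl$per_feature, infl2$per_feature)
  expect_error(filter_influence(m, X, n_repeats = 2, subsample = 2), "exceeds")
})

test_that("influence-expression correlation recovers designed relationships", {
  tissues <- paste0("t", 1:5)
  filters <- sprintf("filter%03d", 1:3)
  feats <- paste0("f", 1:10)
  feature_tissue <- stats::setNames(rep(tissues, 2), feats)
  set.seed(69)
  per_feature <- matrix(rnorm(30), 3, 10,
                        dimnames = list(filters, feats))
  # filter001's per-tissue influence exactly proportional to gene g1's
  # expression across tissues
  expr <- matrix(rlnorm(3 * 5), 3, 5, dimnames = list(paste0("g", 1:3),
                                                      tissues))
  per_t <- tapply(per_feature["filter001", ], feature_tissue[feats], mean)
  expr["g1", tissues] <- 2 * per_t[tissues] + 5
  influence <- list(per_feature = per_feature,
                    global = rowSums(per_feature^2))
  matches <- data.frame(filter = filters[1:2], motif = c("g1", "g2"),
                        similarity = c(0.95, 0.9), q = c(1e-6, 0.05),
                        best = TRUE)
  res <- influence_expression_correlation(influence, matches, expr,
                                          feature_tissue)
  expect_equal(res$pcc$pcc[res$pcc$filter == "filter001"], 1,
               tolerance = 1e-9)
  expect_equal(res$pcc$confidence,
               c("high", "low")[match(res$pcc$filter, filters[1:2])])

  # constant expression: filter skipped with a warning
  expr["g2", ] <- 3
  expect_warning(res2 <- influence_expression_correlation(
    influence, matches, expr, feature_tissue), "constant")
  expect_false("filter002" %in% res2$pcc$filter)

  # direct textbook PCC recomputation on a random instance
  iv <- tapply(per_feature["filter002", ], feature_tissue[feats], mean)
  ev <- rlnorm(5); expr["g2", ] <- ev
  res3 <- influence_expression_correlation(influence, matches, expr,
                                           feature_tissue)
  manual <- sum((iv - mean(iv)) * (ev - mean(ev))) /
    sqrt(sum((iv - mean(iv))^2) * sum((ev - mean(ev))^2))
  expect_equal(res3$pcc$pcc[res3$pcc$filter == "filter002"], manual,
               tolerance = 1e-9)
})
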