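# Shared fixtures. The trained planted-motif experiment is expensive
# (~3 min), so it is built lazily once per test run and reused by every
# test that needs a trained model.

.fixture_env <- new.env(parent = emptyenv())

get_experiment <- function() {
  if (is.null(.fixture_env$exp))
    .fixture_env$exp <- planted_motif_experiment(seed = 1)
  .fixture_env$exp
}

# small untrained model over short windows, for fast shape/score tests
tiny_model <- function(n_features = 2L, input_length = 120L, seed = 7L,
                       conv_activation = "exp", batch_norm = TRUE) {
  spec <- model_spec(conv_layers = list(c(6L, 19L, 3L, 18L)),
                     hidden = c(8L, 8L), dropout = 0,
                     input_length = input_length, global_pool = TRUE,
                     batch_norm = batch_norm,
                     conv_activation = conv_activation)
  build_model(spec, n_features, seed = seed)
}

random_genome <- function(seed = 3L, n_chrom = 1L, len = 5000L) {
  generate_toy_genome(seed, n_chrom = n_chrom, chrom_length = len)
}

random_onehot_batch <- function(n, L, seed = 1L) {
  set.seed(seed)
  X <- array(0, dim = c(4L, L, n))
  for (i in seq_len(n)) {
    idx <- sample.int(4L, L, replace = TRUE)
    X[cbind(idx, seq_len(L), i)] <- 1
  }
  X
}

# brute-force active-site merge oracle: iterate connected components of the
# ">200 bp window overlap" graph with recentering until stable; weights are
# the number of original peaks represented
merge_oracle <- function(midpoints, chrom = "chr1", max_overlap = 200,
                         half = 500) {
  items <- data.frame(center = as.numeric(midpoints), weight = 1)
  repeat {
    n <- nrow(items)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      ov <- min(items$center[i], items$center[j]) + half -
        (max(items$center[i], items$center[j]) - half)
      adj[i, j] <- i != j && ov > max_overlap
    }
    # connected components by repeated boolean multiplication
    reach <- adj | diag(n)
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp <- match(apply(reach, 1, paste, collapse = ""),
                  unique(apply(reach, 1, paste, collapse = "")))
    out <- do.call(rbind, lapply(unique(comp), function(k) {
      idx <- comp == k
      data.frame(center = floor(sum(items$center[idx] * items$weight[idx]) /
                                  sum(items$weight[idx]) + 0.5),
                 weight = sum(items$weight[idx]))
    }))
    changed <- nrow(out) < nrow(items)
    items <- out[order(out$center), , drop = FALSE]
    if (!changed) break
  }
  items
}

# peaks GRanges from 0-based start/end vectors
peaks_gr <- function(starts0, ends0, chrom = "chr1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts0 + 1L, ends0))
}

# one-sided (greater) Fisher p by direct hypergeometric tail
fisher_oracle_p <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# canonical correlations by the generalized-eigenvalue route
cca_eigen_oracle <- function(X, Y) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx, Sxy) %*% solve(Syy, t(Sxy))
  ev <- sort(Re(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmin(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0), 1))
}
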