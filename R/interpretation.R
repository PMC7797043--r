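# post-BN, post-activation first-layer output maps under running statistics
conv1_output_maps <- function(model, X) {
  p <- model$params
  cpp_conv1_output(p$conv_W[[1]], p$conv_b[[1]], spec_pads(model$spec)[1],
                   X, isTRUE(model$spec$batch_norm),
                   p$bn_gamma[[1]], p$bn_beta[[1]],
                   model$bn_mean[[1]], model$bn_var[[1]],
                   isTRUE(model$spec$rc_conv),
                   identical(model$spec$conv_activation, "exp"))
}

#' Convert first-layer filters into probabilistic PWMs
#'
#' For each filter, every window alignment whose raw activation exceeds half
#' of that filter's maximum activation over the sample is stacked; nucleotide
#' counts per position plus a pseudocount are normalized to probabilities
#' (the activation-counting convention of this family of sequence models).
#' Filters that never reach a positive half-max activation return the
#' background PWM with support 0.
#'
#' @param model Trained `deepfun_model`.
#' @param X 4 x L x N one-hot sample (>= 1000 windows recommended), e.g. the
#'   test split tensor.
#' @param pseudocount Added to every base count before normalization.
#' @param background Length-4 background probabilities.
#' @return Object of class `filter_pwms`: list of per-filter lists
#'   (`pwm` K x 4 matrix, `support`, `ic`), plus attributes.
#' @export
filter_to_pwm <- function(model, X, pseudocount = 0.5,
                          background = rep(0.25, 4)) {
  if (length(dim(X)) != 3L || dim(X)[3] < 1L) stop("empty sample")
  p <- model$params
  K <- ncol(p$conv_W[[1]]) %/% 4L
  pad <- spec_pads(model$spec)[1]
  left <- pad %/% 2L
  rc <- isTRUE(model$spec$rc_conv)
  act_l <- conv1_output_maps(model, X)
  acts <- act_l$A; orients <- act_l$orient
  nf <- dim(acts)[1]; Lout <- dim(acts)[2]; N <- dim(acts)[3]
  L <- dim(X)[2]
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    a <- acts[f, , ]                      # Lout x N
    amax <- max(a)
    if (amax <= 0) {
      pwm <- matrix(background, nrow = K, ncol = 4L, byrow = TRUE,
                    dimnames = list(NULL, bases))
      out[[f]] <- list(pwm = pwm, support = 0L,
                       ic = info_content(pwm, background))
      next
    }
    hits <- which(a > amax / 2, arr.ind = TRUE)
    counts <- matrix(0, nrow = K, ncol = 4L, dimnames = list(NULL, bases))
    support <- 0L
    for (h in seq_len(nrow(hits))) {
      j <- hits[h, 1]; n <- hits[h, 2]
      s0 <- j - left                      # 1-based start in the unpadded input
      if (s0 < 1L || s0 + K - 1L > L) next  # alignment sticks out of window
      sub <- X[, s0:(s0 + K - 1L), n]
      # strand-tied filters: count rc-winning alignments in the filter frame
      if (rc && orients[f, j, n] > 0.5)
        sub <- sub[4:1, rev(seq_len(ncol(sub))), drop = FALSE]
      counts <- counts + t(sub)
      support <- support + 1L
    }
    if (support == 0L) {
      pwm <- matrix(background, nrow = K, ncol = 4L, byrow = TRUE,
                    dimnames = list(NULL, bases))
    } else {
      counts <- counts + pseudocount
      pwm <- counts / rowSums(counts)
    }
    out[[f]] <- list(pwm = pwm, support = support,
                     ic = info_content(pwm, background))
  }
  names(out) <- sprintf("filter%03d", seq_len(nf))
  structure(out, class = "filter_pwms", background = background, width = K)
}

#' @export
print.filter_pwms <- function(x, ...) {
  ics <- vapply(x, `[[`, numeric(1), "ic")
  cat("filter_pwms:", length(x), "filters, width", attr(x, "width"),
      "; IC range", sprintf("%.2f-%.2f bits", min(ics), max(ics)), "\n")
  invisible(x)
}

#' Information content of a PWM
#'
#' Total relative entropy of the PWM against the background distribution,
#' `sum_ij m_ij log2(m_ij / p_j)` in bits, with `0 log 0 := 0`. A uniform
#' PWM under a uniform background scores 0; a 19-position one-hot PWM scores
#' 38 bits (2 bits per position).
#'
#' @param pwm K x 4 matrix of per-position nucleotide probabilities (rows sum
#'   to 1), or an element of a `filter_pwms` object.
#' @param background Length-4 background probabilities.
#' @return Bits (non-negative for any valid background-consistent PWM).
#' @export
info_content <- function(pwm, background = rep(0.25, 4)) {
  if (is.list(pwm)) pwm <- pwm$pwm
  if (any(pwm < 0) || any(pwm > 1)) stop("PWM probabilities outside [0,1]")
  if (any(abs(rowSums(pwm) - 1) > 1e-6)) stop("PWM rows must sum to 1")
  pl <- function(x) ifelse(x > 0, x * log2(x), 0)
  sum(pl(pwm)) - sum(t(pwm) * log2(background))
}

#' Write PWMs in minimal MEME motif format
#' @param pwms `filter_pwms` object or named list of K x 4 matrices.
#' @param path Output path.
#' @param background Length-4 background frequencies.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  mats <- if (inherits(pwms, "filter_pwms"))
    lapply(pwms, `[[`, "pwm") else pwms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", c("A", "C", "G", "T"), background),
                     collapse = " "), ""), con)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    writeLines(c(paste("MOTIF", nm),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                         nrow(m))), con)
    writeLines(apply(m, 1L, function(r) paste(sprintf("%.10f", r),
                                              collapse = "  ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a minimal MEME motif file
#' @param path MEME text file.
#' @return Named list of K x 4 probability matrices (columns A, C, G, T).
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], "MOTIF")) {
      nm <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
      j <- i + 1L
      while (j <= length(lines) &&
             !grepl("letter-probability matrix", lines[j])) j <- j + 1L
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      m <- do.call(rbind, lapply(rows, function(r)
        as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
      colnames(m) <- c("A", "C", "G", "T")
      out[[nm]] <- m
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}

# consensus string -> near-one-hot PWM
consensus_to_pwm <- function(consensus, certainty = 0.97) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix((1 - certainty) / 3, nrow = length(ch), ncol = 4L,
              dimnames = list(NULL, bases))
  m[cbind(seq_along(ch), match(ch, bases))] <- certainty
  m
}

# row-standardize a PWM (center and unit-normalize each position's 4
# probabilities); zero-variance positions become zero rows so they
# contribute a correlation of 0
standardize_pwm_rows <- function(m) {
  rc <- m - rowMeans(m)
  nrm <- sqrt(rowSums(rc^2))
  rc[nrm > 1e-12, ] <- rc[nrm > 1e-12, , drop = FALSE] / nrm[nrm > 1e-12]
  rc[nrm <= 1e-12, ] <- 0
  rc
}

# similarity of two PWMs at a given offset of m2 relative to m1: mean
# per-position Pearson correlation of the probability columns over the
# overlap (zero-variance columns contribute 0)
pwm_overlap_similarity <- function(m1, m2, offset, min_overlap = 5L) {
  C <- standardize_pwm_rows(m1) %*% t(standardize_pwm_rows(m2))
  s <- offset_similarities(C, min_overlap)
  s$similarity[match(offset, s$offset)]
}

revcomp_pwm <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
  colnames(out) <- c("A", "C", "G", "T")
  out
}

# mean of each valid diagonal band of the per-position correlation matrix C
# (rows: filter positions, cols: motif positions)
offset_similarities <- function(C, min_overlap = 5L) {
  K1 <- nrow(C); K2 <- ncol(C)
  offsets <- seq(-(K2 - min_overlap), K1 - min_overlap)
  sims <- vapply(offsets, function(off) {
    i1 <- max(1L, 1L + off); i2 <- max(1L, 1L - off)
    len <- min(K1 - i1, K2 - i2) + 1L
    if (len < min_overlap) return(NA_real_)
    mean(C[cbind(i1 + seq_len(len) - 1L, i2 + seq_len(len) - 1L)])
  }, numeric(1))
  keep <- !is.na(sims)
  list(offset = offsets[keep], similarity = sims[keep])
}

# best similarity of filter PWM vs one motif over all offsets/orientations
pwm_best_match <- function(filter_pwm, motif_pwm, min_overlap = 5L) {
  Z1 <- standardize_pwm_rows(filter_pwm)
  best <- list(similarity = -Inf, offset = NA_integer_, orientation = NA)
  for (orient in c("+", "-")) {
    m2 <- if (orient == "+") motif_pwm else revcomp_pwm(motif_pwm)
    s <- offset_similarities(Z1 %*% t(standardize_pwm_rows(m2)), min_overlap)
    k <- which.max(s$similarity)
    if (s$similarity[k] > best$similarity)
      best <- list(similarity = s$similarity[k], offset = s$offset[k],
                   orientation = orient)
  }
  best
}

#' Match filter PWMs against a motif database
#'
#' Internal comparator standing in for an external motif-comparison tool:
#' every (filter, motif) pair is scored by the best mean per-position Pearson
#' correlation over all offsets and both orientations (overlap >= 5
#' positions). An empirical null is built from column-shuffled filter
#' replicas; per-pair empirical p-values are BH-adjusted and matches with
#' q below the threshold are reported, keeping only the best motif per
#' filter. Filters can also be exported in MEME format via [write_meme()]
#' for external tools.
#'
#' @param pwms `filter_pwms` object.
#' @param motif_db Named list of K x 4 motif matrices (from [read_meme()]),
#'   a MEME file path, or a named character vector of consensus strings.
#' @param q_threshold BH-adjusted significance threshold (default 0.1).
#' @param n_null Number of column-shuffled replicas per filter.
#' @param min_overlap Minimum overlapping positions.
#' @param seed Seed for the null shuffles.
#' @return data.frame: filter, motif, offset, orientation, similarity, p, q
#'   (all scored pairs, `significant` flag; best-per-filter rows marked).
#' @export
match_motifs <- function(pwms, motif_db, q_threshold = 0.1, n_null = 200L,
                         min_overlap = 5L, seed = 1L) {
  if (is.character(motif_db) && length(motif_db) == 1L && file.exists(motif_db))
    motif_db <- read_meme(motif_db)
  if (is.character(motif_db)) motif_db <- lapply(motif_db, consensus_to_pwm)
  if (!length(motif_db)) stop("empty motif database")
  if (any(vapply(motif_db, nrow, integer(1)) > 40L))
    stop("database motifs longer than 40 positions unsupported")
  fmats <- lapply(pwms, `[[`, "pwm")
  set.seed(seed)
  rows <- list()
  for (fn in names(fmats)) {
    fm <- fmats[[fn]]
    Z1 <- standardize_pwm_rows(fm)
    # position-shuffling a filter commutes with row standardization, so a
    # null replica's correlation matrix is a row permutation of the observed
    # one; precompute C per (motif, orientation) and permute its rows
    perms <- replicate(n_null, sample.int(nrow(fm)), simplify = FALSE)
    for (k in seq_along(motif_db)) {
      mm <- motif_db[[k]]
      Cs <- list("+" = Z1 %*% t(standardize_pwm_rows(mm)),
                 "-" = Z1 %*% t(standardize_pwm_rows(revcomp_pwm(mm))))
      obs <- list(similarity = -Inf)
      for (orient in c("+", "-")) {
        s <- offset_similarities(Cs[[orient]], min_overlap)
        j <- which.max(s$similarity)
        if (s$similarity[j] > obs$similarity)
          obs <- list(similarity = s$similarity[j], offset = s$offset[j],
                      orientation = orient)
      }
      null_best <- vapply(perms, function(pm) {
        max(max(offset_similarities(Cs[["+"]][pm, , drop = FALSE],
                                    min_overlap)$similarity),
            max(offset_similarities(Cs[["-"]][pm, , drop = FALSE],
                                    min_overlap)$similarity))
      }, numeric(1))
      p <- (1 + sum(null_best >= obs$similarity - 1e-12)) / (1 + n_null)
      rows[[length(rows) + 1L]] <- data.frame(
        filter = fn, motif = names(motif_db)[k], offset = obs$offset,
        orientation = obs$orientation, similarity = obs$similarity, p = p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q < q_threshold
  # best match per filter (highest similarity among all pairs)
  res$best <- FALSE
  for (fn in unique(res$filter)) {
    idx <- which(res$filter == fn)
    res$best[idx[which.max(res$similarity[idx])]] <- TRUE
  }
  res[order(res$filter, -res$similarity), ]
}

#' Filter nullification influence
#'
#' Each first-layer filter is ablated by replacing its post-ReLU output map
#' with its mean over the evaluation subsample; the per-feature influence is
#' the mean change (original − nullified) in predicted probability, the
#' global influence the sum of squares of the per-feature vector. The
#' procedure is repeated over `n_repeats` random subsamples and averaged.
#'
#' @param model Trained `deepfun_model`.
#' @param X 4 x L x N test tensor.
#' @param n_repeats Number of random subsamples (default 10).
#' @param subsample Fraction of `X` used per repeat (default 0.5; with
#'   `n_repeats = 1` the full set is used and the result is deterministic).
#' @param seed Seed for the subsampling.
#' @return List with `per_feature` (filters x features influence matrix) and
#'   `global` (named numeric vector of sum-of-squares influences).
#' @export
filter_influence <- function(model, X, n_repeats = 10L, subsample = 0.5,
                             seed = 1L) {
  N <- dim(X)[3]
  if (N < 1L) stop("empty test set")
  p <- model$params
  nf <- nrow(p$conv_W[[1]])
  pad <- spec_pads(model$spec)[1]
  set.seed(seed)
  take <- if (n_repeats == 1L) N else max(2L, floor(subsample * N))
  if (take > N) stop("subsample size exceeds test set")
  acc <- matrix(0, nrow = nf, ncol = model$n_features)
  for (r in seq_len(n_repeats)) {
    idx <- if (n_repeats == 1L) seq_len(N) else sample.int(N, take)
    Xs <- X[, , idx, drop = FALSE]
    orig <- predict(model, Xs)
    acts <- conv1_output_maps(model, Xs)$A
    for (f in seq_len(nf)) {
      mean_out <- mean(acts[f, , ])  # mean post-activation output map
      nulled <- predict(model, Xs, nullify = list(filter = f,
                                                  value = mean_out))
      acc[f, ] <- acc[f, ] + colMeans(orig - nulled)
    }
  }
  per_feature <- acc / n_repeats
  rownames(per_feature) <- sprintf("filter%03d", seq_len(nf))
  colnames(per_feature) <- model$features$feature
  global <- rowSums(per_feature^2)
  list(per_feature = per_feature, global = global, n_repeats = n_repeats)
}

#' Correlate filter influence with matched-gene expression
#'
#' For each filter whose best motif match passes the q threshold and whose
#' motif maps to a gene in the expression table, computes the Pearson
#' correlation across tissues between the filter's per-tissue influence
#' (features averaged within tissue) and the gene's expression, then tests
#' (one-sided two-sample t-test) whether high-confidence matches
#' (q < `q_high`) have larger correlations than low-confidence ones
#' (`q_high` <= q < `q_low`).
#'
#' @param influence Result of [filter_influence()].
#' @param matches Result of [match_motifs()] (best rows are used).
#' @param expression Gene x tissue numeric matrix.
#' @param feature_tissue Named character vector mapping feature id -> tissue.
#' @param motif_gene Named character vector mapping motif id -> gene id
#'   (defaults to identity).
#' @param q_high,q_low Confidence thresholds.
#' @return List with `pcc` (data.frame: filter, motif, gene, q, confidence,
#'   pcc) and `test` (one-sided t-test result, or NULL when a group is
#'   empty).
#' @export
influence_expression_correlation <- function(influence, matches, expression,
                                             feature_tissue,
                                             motif_gene = NULL,
                                             q_high = 1e-4, q_low = 0.1) {
  best <- matches[matches$best & matches$q < q_low, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(best))) {
    b <- best[i, ]
    gene <- if (is.null(motif_gene)) b$motif else motif_gene[[b$motif]]
    if (is.null(gene) || !gene %in% rownames(expression)) next
    infl <- influence$per_feature[b$filter, ]
    tiss <- feature_tissue[names(infl)]
    per_tissue <- tapply(infl, tiss, mean)
    shared <- intersect(names(per_tissue), colnames(expression))
    if (length(shared) < 3L) {
      warning("filter ", b$filter, ": fewer than 3 shared tissues; skipped")
      next
    }
    ex <- expression[gene, shared]
    iv <- per_tissue[shared]
    if (stats::sd(ex) < 1e-12 || stats::sd(iv) < 1e-12) {
      warning("filter ", b$filter, ": constant vector, PCC undefined; skipped")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      filter = b$filter, motif = b$motif, gene = gene, q = b$q,
      confidence = if (b$q < q_high) "high" else "low",
      pcc = stats::cor(iv, ex), stringsAsFactors = FALSE)
  }
  pcc <- if (length(rows)) do.call(rbind, rows) else NULL
  test <- NULL
  if (!is.null(pcc) && all(c("high", "low") %in% pcc$confidence) &&
      sum(pcc$confidence == "high") >= 2L && sum(pcc$confidence == "low") >= 2L)
    test <- stats::t.test(pcc$pcc[pcc$confidence == "high"],
                          pcc$pcc[pcc$confidence == "low"],
                          alternative = "greater")
  list(pcc = pcc, test = test)
}
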