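#' Extract reference and alternative allele windows around a variant
#'
#' Both windows are `window` bp long with the first reference-allele base at
#' 0-based offset `window/2` (i.e. centered). For indels the alternative
#' window keeps the same anchor and is trimmed or extended with downstream
#' genome sequence to the fixed width.
#'
#' @param genome `DNAStringSet`.
#' @param variants data.frame with chrom, pos (1-based), id, ref, alt.
#' @param window Even window width in bp (default 1000).
#' @return List with `ref`, `alt` (`DNAStringSet`s over the kept variants),
#'   `kept` (row indices of `variants` scored) and `skipped` (data.frame of
#'   dropped variants and reasons).
#' @export
extract_allele_windows <- function(genome, variants, window = 1000L) {
  if (window %% 2L != 0L) stop("window must be even")
  half <- window %/% 2L
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  refs <- character(0); alts <- character(0)
  kept <- integer(0); skipped <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$chrom %in% names(genome)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(id = v$id, reason = "unknown chromosome")
      next
    }
    L <- chrom_len[[v$chrom]]
    start1 <- v$pos - half               # window start, 1-based
    need_end <- v$pos - 1L + half + nchar(v$ref) + nchar(v$alt)
    if (start1 < 1L || need_end > L) {
      warning("variant ", v$id, " closer than ", half,
              " bp to a chromosome end; skipped")
      skipped[[length(skipped) + 1L]] <-
        data.frame(id = v$id, reason = "near chromosome end")
      next
    }
    genome_ref <- as.character(Biostrings::subseq(
      genome[[v$chrom]], v$pos, v$pos + nchar(v$ref) - 1L))
    if (!identical(genome_ref, toupper(v$ref))) {
      warning("variant ", v$id, ": ref allele '", v$ref,
              "' does not match genome '", genome_ref, "'; skipped")
      skipped[[length(skipped) + 1L]] <-
        data.frame(id = v$id, reason = "ref mismatch")
      next
    }
    up <- as.character(Biostrings::subseq(genome[[v$chrom]], start1,
                                          v$pos - 1L))
    down_len <- window  # generous downstream buffer, trimmed below
    down_start <- v$pos + nchar(v$ref)
    down <- as.character(Biostrings::subseq(
      genome[[v$chrom]], down_start,
      min(L, down_start + down_len - 1L)))
    ref_seq <- substr(paste0(up, v$ref, down), 1L, window)
    alt_seq <- substr(paste0(up, v$alt, down), 1L, window)
    if (nchar(ref_seq) < window || nchar(alt_seq) < window) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(id = v$id, reason = "insufficient 3' sequence")
      next
    }
    refs <- c(refs, ref_seq); alts <- c(alts, alt_seq)
    kept <- c(kept, i)
  }
  list(ref = Biostrings::DNAStringSet(refs),
       alt = Biostrings::DNAStringSet(alts),
       kept = kept,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(id = character(), reason = character()))
}

#' SNP Activity Difference (SAD) scores
#'
#' For each variant and chromatin feature, SAD = Alt − Ref, the difference in
#' predicted activity probability between the alternative- and
#' reference-allele windows. Positive SAD means the alternative allele
#' increases the predicted epigenetic signal.
#'
#' @param model Trained `deepfun_model`.
#' @param variants Variant data.frame (chrom, pos, id, ref, alt).
#' @param genome `DNAStringSet` consistent with the model's training genome.
#' @param feature_subset Optional character vector of feature ids used for
#'   the per-variant `mean_abs_sad` / max summaries (default: all features).
#' @return List with `records` (variant x feature long data.frame:
#'   id, feature, ref_prob, alt_prob, sad) and `summary` (per-variant
#'   max_sad, min_sad, max_abs_sad, mean_abs_sad over the subset).
#' @export
sad_scores <- function(model, variants, genome, feature_subset = NULL) {
  w <- extract_allele_windows(genome, variants,
                              window = model$spec$input_length)
  if (!length(w$kept))
    return(list(records = NULL, summary = NULL, skipped = w$skipped))
  ref_p <- predict(model, encode_batch(w$ref))
  alt_p <- predict(model, encode_batch(w$alt))
  feats <- model$features$feature
  ids <- variants$id[w$kept]
  records <- data.frame(
    id = rep(ids, each = length(feats)),
    feature = rep(feats, times = length(ids)),
    ref_prob = as.vector(t(ref_p)),
    alt_prob = as.vector(t(alt_p)),
    stringsAsFactors = FALSE)
  records$sad <- records$alt_prob - records$ref_prob

  sub <- feature_subset %||% feats
  if (!all(sub %in% feats)) stop("feature_subset contains unknown features")
  sadm <- alt_p - ref_p                      # variants x features
  s <- sadm[, sub, drop = FALSE]
  summary <- data.frame(
    id = ids,
    max_sad = apply(s, 1L, max),
    min_sad = apply(s, 1L, min),
    max_abs_sad = apply(abs(s), 1L, max),
    mean_abs_sad = rowMeans(abs(s)),
    stringsAsFactors = FALSE)
  list(records = records, summary = summary, skipped = w$skipped)
}

#' In-silico saturated mutagenesis of a region
#'
#' Scores every possible single-nucleotide substitution in the region as a
#' synthetic SNV; entries for the reference base are 0 by definition.
#'
#' @param model Trained `deepfun_model`.
#' @param genome `DNAStringSet`.
#' @param chrom,start,end Region (1-based, inclusive).
#' @param feature_subset Optional feature ids (default all).
#' @param cap Maximum region length.
#' @return L x 4 x F array of SAD values (dimnames: position, base, feature).
#' @export
saturated_mutagenesis <- function(model, genome, chrom, start, end,
                                  feature_subset = NULL, cap = 1000L) {
  L <- end - start + 1L
  if (L > cap) stop("region longer than cap (", cap, " bp)")
  bases <- c("A", "C", "G", "T")
  feats <- feature_subset %||% model$features$feature
  grid <- array(0, dim = c(L, 4L, length(feats)),
                dimnames = list(start:end, bases, feats))
  vars <- list()
  for (i in seq_len(L)) {
    pos <- start + i - 1L
    ref <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
    for (b in setdiff(bases, ref))
      vars[[length(vars) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, id = paste0("mut_", pos, "_", b),
        ref = ref, alt = b, stringsAsFactors = FALSE)
  }
  vdf <- do.call(rbind, vars)
  sc <- sad_scores(model, vdf, genome, feature_subset = feats)
  rec <- sc$records[sc$records$feature %in% feats, ]
  pos <- as.integer(sub("mut_([0-9]+)_.*", "\\1", rec$id))
  alt <- sub("mut_[0-9]+_", "", rec$id)
  grid[cbind(pos - start + 1L, match(alt, bases),
             match(rec$feature, feats))] <- rec$sad
  grid
}

# one-sided Wilcoxon rank-sum test; exact permutation enumeration (midranks,
# so ties are handled exactly) when min(n, m) <= 8, else normal approximation
# with tie correction and continuity correction
wilcoxon_rank_sum <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (alternative == "less") return(wilcoxon_rank_sum(b, a, "greater"))
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("groups must be non-empty")
  all_vals <- c(a, b)
  if (length(unique(all_vals)) == 1L) {
    warning("all observations tied; p = 1")
    return(list(statistic = n * m / 2, p.value = 1, exact = TRUE))
  }
  r <- rank(all_vals)
  W <- sum(r[seq_len(n)]) - n * (n + 1) / 2   # Mann-Whitney U for group a
  if (min(n, m) <= 8L && choose(n + m, n) <= 2e5) {
    combs <- utils::combn(n + m, n)
    Ws <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    p <- mean(Ws >= W - 1e-9)
    return(list(statistic = W, p.value = p, exact = TRUE))
  }
  mu <- n * m / 2
  tie_tab <- table(r)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_tab^3 - tie_tab) / ((n + m) * (n + m - 1)))
  z <- (W - mu - 0.5) / sqrt(sigma2)
  list(statistic = W, p.value = stats::pnorm(z, lower.tail = FALSE),
       exact = FALSE)
}

#' Compare SAD summaries between two variant groups
#'
#' One-sided Wilcoxon rank-sum test that group A's per-variant summaries
#' (typically mean |SAD|) exceed group B's, plus the proportion of each
#' group exceeding each value of a threshold ladder.
#'
#' @param group_a,group_b Numeric vectors of per-variant summaries.
#' @param alternative `"greater"` (A > B, default) or `"less"`.
#' @param thresholds Threshold ladder for the proportion curve.
#' @return List with `p.value`, `statistic`, `exact`, and `curve`
#'   (data.frame: threshold, prop_a, prop_b).
#' @export
compare_sad_groups <- function(group_a, group_b,
                               alternative = "greater",
                               thresholds = seq(0, 0.5, by = 0.05)) {
  test <- wilcoxon_rank_sum(group_a, group_b, alternative)
  curve <- data.frame(
    threshold = thresholds,
    prop_a = vapply(thresholds, function(t) mean(group_a >= t), numeric(1)),
    prop_b = vapply(thresholds, function(t) mean(group_b >= t), numeric(1)))
  c(test, list(curve = curve))
}
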