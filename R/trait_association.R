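#' Select lead SNPs from GWAS summary statistics
#'
#' @param summary_stats data.frame with columns snp, chrom, pos, p.
#' @param p_threshold Association p-value cutoff (default 1e-3; genome-wide
#'   analyses may use 1e-8).
#' @return data.frame of loci with p < threshold, in genomic order.
#' @export
select_lead_snps <- function(summary_stats, p_threshold = 1e-3) {
  req <- c("snp", "chrom", "pos", "p")
  if (!all(req %in% names(summary_stats)))
    stop("summary statistics need columns: ", paste(req, collapse = ", "))
  bad <- which(summary_stats$p <= 0 | summary_stats$p > 1)
  if (length(bad))
    stop("p-value outside (0,1] at row ", bad[1])
  out <- summary_stats[summary_stats$p < p_threshold, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Flag regulatory loci by maximum |SAD|
#'
#' A locus is regulatory when its maximum absolute SAD over the selected
#' feature subset strictly exceeds the threshold (default 0.1, applied
#' two-sidedly).
#'
#' @param loci data.frame of lead SNPs (column `snp`).
#' @param sad Long data.frame with columns snp, feature, sad.
#' @param sad_threshold Strict |SAD| cutoff.
#' @param feature_subset Optional character vector of features to consider.
#' @return `loci` with added `max_abs_sad` and logical `regulatory`; loci
#'   absent from the SAD table are dropped with a warning.
#' @export
classify_regulatory <- function(loci, sad, sad_threshold = 0.1,
                                feature_subset = NULL) {
  if (!is.null(feature_subset))
    sad <- sad[sad$feature %in% feature_subset, , drop = FALSE]
  mx <- tapply(abs(sad$sad), sad$snp, max)
  missing <- setdiff(loci$snp, names(mx))
  if (length(missing)) {
    warning(length(missing), " loci missing from the SAD table; excluded")
    loci <- loci[!loci$snp %in% missing, , drop = FALSE]
  }
  loci$max_abs_sad <- as.numeric(mx[loci$snp])
  loci$regulatory <- loci$max_abs_sad > sad_threshold
  loci
}

#' Map lead SNPs to genes and split TAGs by regulatory status
#'
#' A SNP maps to every gene whose TSS lies within `window` bp. A gene with at
#' least one mapped regulatory SNP is a regulatory trait-associated gene
#' (TAG); a gene with mapped lead SNPs but none regulatory is a
#' non-regulatory TAG. The two sets are disjoint by construction.
#'
#' @param loci Output of [classify_regulatory()].
#' @param genes data.frame with gene, chrom, tss (and typically pli).
#' @param window Symmetric TSS window in bp (default 50 kb).
#' @return List with `regulatory`, `non_regulatory` (character vectors of
#'   gene ids) and `mapping` (snp-gene pair data.frame).
#' @export
map_snps_to_genes <- function(loci, genes, window = 50000L) {
  maps <- list()
  for (i in seq_len(nrow(loci))) {
    hit <- genes$chrom == loci$chrom[i] &
      abs(loci$pos[i] - genes$tss) <= window
    if (any(hit))
      maps[[length(maps) + 1L]] <- data.frame(
        snp = loci$snp[i], gene = genes$gene[hit],
        regulatory = loci$regulatory[i], stringsAsFactors = FALSE)
  }
  if (!length(maps))
    return(list(regulatory = character(), non_regulatory = character(),
                mapping = data.frame(snp = character(), gene = character(),
                                     regulatory = logical())))
  mapping <- do.call(rbind, maps)
  reg <- unique(mapping$gene[mapping$regulatory])
  nonreg <- setdiff(unique(mapping$gene), reg)
  list(regulatory = reg, non_regulatory = nonreg, mapping = mapping)
}

fisher_2x2 <- function(in_set_hit, in_set_miss, out_set_hit, out_set_miss) {
  tab <- matrix(c(in_set_hit, in_set_miss, out_set_hit, out_set_miss),
                nrow = 2L, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    return(list(table = tab, odds_ratio = NA_real_, p.value = 1,
                sidedness = "greater"))
  }
  ft <- stats::fisher.test(tab, alternative = "greater")
  or <- if (tab[1, 2] == 0 || tab[2, 1] == 0) Inf else
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(table = tab, odds_ratio = or, p.value = ft$p.value,
       sidedness = "greater")
}

#' Enrichment of a TAG set in LoF-intolerant genes
#'
#' One-sided (greater) Fisher's exact test of the 2x2 table
#' (in TAG set vs not) x (pLI > threshold vs not). Genes with missing pLI
#' are removed from the universe.
#'
#' @param tag_set Character vector of gene ids.
#' @param genes Gene data.frame with gene and pli columns (the universe).
#' @param pli_threshold LoF-intolerance cutoff (default 0.9).
#' @return List: `table` (2x2 counts), `odds_ratio` (sample OR; Inf/NA at
#'   zero cells/margins), `p.value`, `sidedness`.
#' @export
pli_enrichment <- function(tag_set, genes, pli_threshold = 0.9) {
  genes <- genes[!is.na(genes$pli), , drop = FALSE]
  if (!nrow(genes)) stop("empty gene universe after removing missing pLI")
  in_tag <- genes$gene %in% tag_set
  lof <- genes$pli > pli_threshold
  fisher_2x2(sum(in_tag & lof), sum(in_tag & !lof),
             sum(!in_tag & lof), sum(!in_tag & !lof))
}

#' Tissue-specific expressed gene panel
#'
#' For every gene and tissue, a Welch t-statistic compares the tissue's
#' samples against all other samples; each tissue's top `quantile` fraction
#' of genes by t-statistic forms its tissue-specific set.
#'
#' @param expression Gene x sample numeric matrix.
#' @param sample_tissue Character vector: tissue of each column.
#' @param quantile Top fraction per tissue (default 0.05).
#' @return List with `t` (gene x tissue t-statistic matrix) and `top_sets`
#'   (named list of character vectors, size `ceiling(quantile * n_genes)`).
#' @export
tissue_specific_genes <- function(expression, sample_tissue,
                                  quantile = 0.05) {
  stopifnot(ncol(expression) == length(sample_tissue))
  tissues <- unique(sample_tissue)
  n_top <- ceiling(quantile * nrow(expression))
  tmat <- matrix(NA_real_, nrow = nrow(expression), ncol = length(tissues),
                 dimnames = list(rownames(expression), tissues))
  pooled_warned <- FALSE
  for (ti in tissues) {
    in_t <- sample_tissue == ti
    x <- expression[, in_t, drop = FALSE]
    y <- expression[, !in_t, drop = FALSE]
    nx <- ncol(x); ny <- ncol(y)
    mx <- rowMeans(x); my <- rowMeans(y)
    if (nx >= 2L) {
      vx <- apply(x, 1L, stats::var); vy <- apply(y, 1L, stats::var)
      tmat[, ti] <- (mx - my) / sqrt(vx / nx + vy / ny)
    } else {
      # single-sample tissue: pooled variance from the complement
      if (!pooled_warned) {
        warning("tissue '", ti, "' has a single sample; pooled-variance fallback")
        pooled_warned <- TRUE
      }
      vy <- apply(y, 1L, stats::var)
      tmat[, ti] <- (mx - my) / sqrt(vy * (1 / nx + 1 / ny))
    }
  }
  tmat[!is.finite(tmat)] <- 0
  top_sets <- lapply(tissues, function(ti) {
    rownames(expression)[order(tmat[, ti], decreasing = TRUE)[seq_len(n_top)]]
  })
  names(top_sets) <- tissues
  list(t = tmat, top_sets = top_sets, quantile = quantile)
}

#' Tissue-specific enrichment analysis (TSEA)
#'
#' One one-sided Fisher's exact test per tissue of the overlap between the
#' TAG set and that tissue's tissue-specific expressed genes.
#'
#' @param tag_set Character vector of gene ids.
#' @param panel Output of [tissue_specific_genes()].
#' @param universe Character vector: the gene universe.
#' @param adjust Apply BH correction across tissues (default FALSE; raw
#'   p-values are reported).
#' @return data.frame: tissue, shared (|TAG ∩ top set|), tag_size, set_size,
#'   odds_ratio, p (and q when `adjust`).
#' @export
tsea <- function(tag_set, panel, universe, adjust = FALSE) {
  if (!length(universe)) stop("empty gene universe")
  tag_set <- intersect(tag_set, universe)
  rows <- lapply(names(panel$top_sets), function(ti) {
    top <- intersect(panel$top_sets[[ti]], universe)
    a <- length(intersect(tag_set, top))
    res <- fisher_2x2(a, length(tag_set) - a,
                      length(top) - a,
                      length(universe) - length(tag_set) - length(top) + a)
    data.frame(tissue = ti, shared = a, tag_size = length(tag_set),
               set_size = length(top), odds_ratio = res$odds_ratio,
               p = res$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), ]
}

#' Canonical correlation of variant SAD effects against tissue design
#'
#' Finds paired linear projections U = Xa, V = Yb maximizing cor(U, V),
#' computed by singular-value decomposition of the whitened cross-covariance
#' with rank truncation (singular values below `tol` times the largest are
#' dropped; an optional ridge stabilizes P >> N designs). Canonical
#' correlations are non-increasing; projections have unit variance, and
#' canonical loadings (correlations of each original column with the
#' projections) are returned for radius-1 loading plots.
#'
#' @param X N x P matrix (e.g. variant x feature SAD scores).
#' @param Y N x T matrix (e.g. one-hot tissue membership aggregated per
#'   tissue).
#' @param tol Relative singular-value truncation tolerance.
#' @param ridge Non-negative ridge added to each block's covariance.
#' @return List of class `cca_result`: `cor` (canonical correlations), `a`,
#'   `b` (loading vectors, columns per component), `U`, `V` (unit-variance
#'   projections), `x_loadings`, `y_loadings`, `rank`.
#' @export
cca_tissue_association <- function(X, Y, tol = 1e-10, ridge = 0) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  N <- nrow(X)
  if (N < 3L || nrow(Y) != N) stop("need N >= 3 rows in both matrices")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  whiten <- function(M) {
    s <- svd(M)
    keep <- s$d > tol * max(s$d, 0)
    if (!any(keep)) stop("matrix has rank 0 after centering")
    if (ridge > 0) {
      d2 <- sqrt(s$d[keep]^2 + ridge)
      list(Q = M %*% s$v[, keep, drop = FALSE] %*%
             diag(1 / d2, sum(keep)),
           V = s$v[, keep, drop = FALSE], dinv = 1 / d2)
    } else {
      list(Q = s$u[, keep, drop = FALSE],
           V = s$v[, keep, drop = FALSE], dinv = 1 / s$d[keep])
    }
  }
  wx <- whiten(Xc); wy <- whiten(Yc)
  M <- crossprod(wx$Q, wy$Q)
  s <- svd(M)
  k <- min(ncol(wx$Q), ncol(wy$Q))
  rho <- pmin(pmax(s$d[seq_len(k)], 0), 1)

  a <- wx$V %*% (wx$dinv * s$u[, seq_len(k), drop = FALSE]) * sqrt(N - 1)
  b <- wy$V %*% (wy$dinv * s$v[, seq_len(k), drop = FALSE]) * sqrt(N - 1)
  U <- Xc %*% a
  V <- Yc %*% b
  x_loadings <- suppressWarnings(stats::cor(Xc, U))
  y_loadings <- suppressWarnings(stats::cor(Yc, V))
  structure(list(cor = rho, a = a, b = b, U = U, V = V,
                 x_loadings = x_loadings, y_loadings = y_loadings,
                 rank = k),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat("cca_result: rank", x$rank, "; canonical correlations:",
      paste(sprintf("%.3f", x$cor), collapse = ", "), "\n")
  invisible(x)
}

#' Run the GWAS prioritization pipeline
#'
#' Lead-SNP selection, regulatory classification by |SAD|, TSS-window gene
#' mapping, pLI enrichment for both TAG arms, and TSEA for both arms.
#'
#' @param gwas GWAS summary data.frame (snp, chrom, pos, p).
#' @param sad Long SNP x feature SAD data.frame.
#' @param genes Gene data.frame (gene, chrom, tss, pli).
#' @param expression Gene x sample expression matrix.
#' @param sample_tissue Tissue of each expression column.
#' @param p_threshold,sad_threshold,window,quantile Stage parameters.
#' @param feature_subset Features over which max |SAD| is taken.
#' @return List with `loci`, `tags`, `pli` (regulatory / non_regulatory
#'   enrichment results), `tsea` (both arms) and the `panel`.
#' @export
prioritize <- function(gwas, sad, genes, expression, sample_tissue,
                       p_threshold = 1e-3, sad_threshold = 0.1,
                       window = 50000L, quantile = 0.05,
                       feature_subset = NULL) {
  loci <- select_lead_snps(gwas, p_threshold)
  loci <- classify_regulatory(loci, sad, sad_threshold, feature_subset)
  tags <- map_snps_to_genes(loci, genes, window)
  panel <- tissue_specific_genes(expression, sample_tissue, quantile)
  universe <- genes$gene
  list(loci = loci, tags = tags,
       pli = list(regulatory = pli_enrichment(tags$regulatory, genes),
                  non_regulatory = pli_enrichment(tags$non_regulatory, genes)),
       tsea = list(regulatory = tsea(tags$regulatory, panel, universe),
                   non_regulatory = tsea(tags$non_regulatory, panel, universe)),
       panel = panel)
}
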