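test_that("lead-SNP selection filters by the association threshold", {
  stats_df <- data.frame(snp = c("a", "b", "c"), chrom = "chr1",
                         pos = c(30, 10, 20), p = c(1e-4, 5e-3, 1e-2))
  sel <- select_lead_snps(stats_df, 1e-3)
  expect_equal(sel$snp, "a")
  # the stricter genome-wide threshold is supported
  expect_equal(nrow(select_lead_snps(stats_df, 1e-8)), 0L)
  expect_equal(nrow(select_lead_snps(stats_df[0, ], 1e-3)), 0L)
  bad <- transform(stats_df, p = c(0.5, -1, 0.2))
  expect_error(select_lead_snps(bad), "row 2")
  # output in genomic order
  sel2 <- select_lead_snps(stats_df, 0.5)
  expect_equal(sel2$pos, c(10, 20, 30))
})

test_that("regulatory classification applies the strict two-sided 0.1 rule", {
  loci <- data.frame(snp = c("s1", "s2", "s3", "s4"), chrom = "chr1",
                     pos = 1:4, p = 1e-4)
  sad <- rbind(
    data.frame(snp = "s1", feature = c("f1", "f2"), sad = c(0.15, 0.02)),
    data.frame(snp = "s2", feature = c("f1", "f2"), sad = c(-0.2, 0.05)),
    data.frame(snp = "s3", feature = c("f1", "f2"), sad = c(0.1, -0.1)),
    data.frame(snp = "s4", feature = c("f1", "f2"), sad = c(0.3, 0.01)))
  out <- classify_regulatory(loci, sad)
  expect_equal(out$regulatory, c(TRUE, TRUE, FALSE, TRUE))  # 0.1 is strict
  # subset restriction: s4 only exceeds on f1
  out2 <- classify_regulatory(loci, sad, feature_subset = "f2")
  expect_equal(out2$regulatory, rep(FALSE, 4))
  expect_warning(classify_regulatory(rbind(loci,
    data.frame(snp = "s5", chrom = "chr1", pos = 5, p = 1e-4)), sad),
    "missing")
})

test_that("SNP-to-gene mapping respects the 50 kb TSS window and precedence", {
  genes <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                      tss = c(100000, 400000))
  loci <- data.frame(snp = c("near", "far", "mix"), chrom = "chr1",
                     pos = c(110000, 160001, 390000),
                     regulatory = c(FALSE, TRUE, TRUE))
  tags <- map_snps_to_genes(loci, genes)
  # "near" maps to g1 (10 kb); "far" is 60,001 bp from g1 -> unmapped
  expect_true("g1" %in% tags$non_regulatory)
  expect_true("g2" %in% tags$regulatory)
  # a gene with one regulatory and one non-regulatory SNP is regulatory only
  loci2 <- rbind(loci,
                 data.frame(snp = "reg1", chrom = "chr1", pos = 90000,
                            regulatory = TRUE))
  tags2 <- map_snps_to_genes(loci2, genes)
  expect_true("g1" %in% tags2$regulatory)
  expect_false("g1" %in% tags2$non_regulatory)
})

test_that("pLI enrichment equals the hypergeometric tail", {
  genes <- data.frame(gene = paste0("g", 1:10),
                      pli = c(rep(0.95, 5), rep(0.1, 5)))
  res <- pli_enrichment(paste0("g", 1:5), genes)
  expect_equal(res$table[1, ], c(5L, 0L))
  expect_equal(res$p.value, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$odds_ratio, Inf)

  # balanced table: p matches enumeration, OR = 1
  genes2 <- data.frame(gene = paste0("h", 1:40),
                       pli = rep(c(0.95, 0.1), 20))
  tag <- paste0("h", 1:20)    # 10 LoF-intolerant, 10 not
  res2 <- pli_enrichment(tag, genes2)
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p.value, fisher_oracle_p(10, 10, 10, 10),
               tolerance = 1e-12)

  # degenerate margin
  res3 <- pli_enrichment(character(0), genes)
  expect_true(is.na(res3$odds_ratio))
  expect_equal(res3$p.value, 1)
  expect_error(pli_enrichment("g1", data.frame(gene = "g1", pli = NA)),
               "empty")
})

test_that("tissue-specific panels pick designed genes by Welch t", {
  set.seed(71)
  n_genes <- 200
  expr <- matrix(rlnorm(n_genes * 9, 2, 0.3), nrow = n_genes,
                 dimnames = list(paste0("g", 1:n_genes), NULL))
  tissue <- rep(c("liver", "brain", "lung"), each = 3)
  expr["g1", tissue == "liver"] <- expr["g1", tissue == "liver"] * 10
  expr["g2", ] <- 5                     # constant gene
  panel <- tissue_specific_genes(expr, tissue, quantile = 0.05)
  expect_true("g1" %in% panel$top_sets$liver)
  expect_false("g2" %in% unlist(panel$top_sets))
  expect_true(all(lengths(panel$top_sets) == ceiling(0.05 * n_genes)))
  # Welch formula recomputation for one gene/tissue
  x <- expr["g5", tissue == "brain"]; y <- expr["g5", tissue != "brain"]
  tt <- (mean(x) - mean(y)) / sqrt(var(x) / 3 + var(y) / 6)
  expect_equal(panel$t["g5", "brain"], tt, tolerance = 1e-12)
  expect_warning(tissue_specific_genes(expr[, 1:4], c("a", "b", "b", "b")),
                 "single sample")
})

test_that("TSEA ranks the matching tissue first and reports shared counts", {
  set.seed(72)
  universe <- paste0("g", 1:300)
  expr <- matrix(rlnorm(300 * 8, 2, 0.3), nrow = 300,
                 dimnames = list(universe, NULL))
  tissue <- rep(c("t1", "t2"), each = 4)
  special <- paste0("g", 1:15)
  expr[special, tissue == "t1"] <- expr[special, tissue == "t1"] * 8
  panel <- tissue_specific_genes(expr, tissue)
  res <- tsea(panel$top_sets$t1, panel, universe)
  expect_equal(res$tissue[1], "t1")
  expect_equal(res$shared[res$tissue == "t1"],
               length(panel$top_sets$t1))
  # disjoint TAG set: all p = 1
  leftovers <- setdiff(universe, unlist(panel$top_sets))
  res2 <- tsea(leftovers[1:10], panel, universe)
  expect_true(all(res2$p == 1))
  expect_equal(res2$shared, c(0L, 0L))
})

test_that("canonical correlations match self-, orthogonal- and eigen oracles", {
  set.seed(73)
  X <- matrix(rnorm(60), 20, 3)
  # Y a full-rank recoding of X: all canonical correlations are 1
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  res <- cca_tissue_association(X, X %*% A)
  expect_equal(res$cor, rep(1, 3), tolerance = 1e-8)

  # orthogonal column spaces in sample: leading correlation ~ 0
  Z <- matrix(rnorm(40), 20, 2)
  Zc <- scale(Z, scale = FALSE)
  Xc <- scale(X, scale = FALSE)
  Yor <- Zc - Xc %*% solve(crossprod(Xc), crossprod(Xc, Zc))
  res2 <- cca_tissue_association(X, Yor)
  expect_lt(res2$cor[1], 1e-9)

  # random instances against the generalized-eigenvalue oracle
  for (i in 1:10) {
    Xi <- matrix(rnorm(20 * 3), 20, 3)
    Yi <- matrix(rnorm(20 * 2), 20, 2)
    ri <- cca_tissue_association(Xi, Yi)
    expect_equal(ri$cor, cca_eigen_oracle(Xi, Yi), tolerance = 1e-8)
    expect_true(all(diff(ri$cor) <= 1e-12))
    # projections have unit variance
    expect_equal(apply(ri$U, 2, var), rep(1, 2), tolerance = 1e-8)
    expect_equal(apply(ri$V, 2, var), rep(1, 2), tolerance = 1e-8)
    # base-R cross-check
    cc <- stats::cancor(Xi, Yi)
    expect_equal(ri$cor, cc$cor, tolerance = 1e-8)
    # invariance to invertible affine recoding of Y
    B <- matrix(rnorm(4), 2, 2) + 2 * diag(2)
    ri2 <- cca_tissue_association(Xi, sweep(Yi %*% B, 2, c(3, -1), "+"))
    expect_equal(ri2$cor, ri$cor, tolerance = 1e-8)
  }
  expect_error(cca_tissue_association(X[1:2, ], X[1:2, 1:2]), "N >= 3")
})

test_that("the prioritization pipeline mirrors the designed trait structure", {
  fx <- generate_trait_fixture(seed = 74, n_genes = 500, n_tissues = 6,
                               frac_regulatory = 0.06)
  pri <- prioritize(fx$gwas, fx$sad, fx$genes, fx$expression,
                    fx$sample_tissue)
  expect_setequal(pri$tags$regulatory, fx$regulatory_genes)
  expect_setequal(pri$tags$non_regulatory, fx$nonreg_lead_genes)
  expect_lt(pri$pli$regulatory$p.value, 0.05)
  expect_gt(pri$pli$non_regulatory$p.value, 0.05)
  expect_equal(pri$tsea$regulatory$tissue[1], fx$designated_tissue)
})
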