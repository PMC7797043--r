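test_that("toy genome has the requested shape, composition and determinism", {
  g <- generate_toy_genome(seed = 1, n_chrom = 2, chrom_length = 200000)
  expect_length(g, 2L)
  expect_equal(unname(Biostrings::width(g)), c(200000L, 200000L))
  expect_equal(names(g), c("chr1", "chr2"))

  g1 <- generate_toy_genome(seed = 1, n_chrom = 1, chrom_length = 1000)
  gc <- Biostrings::letterFrequency(g1[[1]], "GC", as.prob = TRUE)
  # +-3.2 sd binomial bound at n = 1000, p = 0.5 is ~ +-0.05
  expect_gt(gc, 0.45)
  expect_lt(gc, 0.55)

  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(generate_toy_genome(5, 1, 3000), f1)
  write_genome_fasta(generate_toy_genome(5, 1, 3000), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_error(generate_toy_genome(1, 0, 3000), "n_chrom")
  expect_error(generate_toy_genome(1, 1, 500), "chrom_length")
})

test_that("planted features have the contracted counts and recoverable motifs", {
  g <- generate_toy_genome(seed = 2)
  pl <- plant_motif_features(g, peaks_per_feature = 200, seed = 3)
  expect_length(pl$peaks, 3L)
  expect_true(all(vapply(pl$peaks, length, integer(1)) == 200L))
  expect_equal(nrow(pl$truth$occurrences), 600L)

  # exact scan of the positive peak windows recovers >= 95% of plants
  mot <- example_motifs()
  occ <- pl$truth$occurrences
  found <- vapply(seq_len(nrow(occ)), function(i) {
    o <- occ[i, ]
    window <- Biostrings::subseq(pl$genome[[o$chrom]],
                                 max(1, o$start - 500), o$start + 500)
    length(Biostrings::matchPattern(mot[[o$motif]], window)) >= 1
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("background features contain no planted occurrence", {
  g <- generate_toy_genome(seed = 4, chrom_length = 100000)
  pl <- plant_motif_features(g, motifs = example_motifs()[1],
                             n_features = 2, peaks_per_feature = 40,
                             feature_motifs = c("cre_like", "background"),
                             seed = 5)
  occ <- pl$truth$occurrences
  bg <- pl$peaks[[2]]
  mids <- peaks_gr(GenomicRanges::start(bg) - 1L, GenomicRanges::end(bg))
  for (i in seq_along(bg)) {
    m <- (GenomicRanges::start(bg)[i] - 1L + GenomicRanges::end(bg)[i]) %/% 2L
    w_lo <- m - 500L; w_hi <- m + 500L
    same <- occ$chrom == as.character(GenomeInfoDb::seqnames(bg))[i]
    expect_false(any(same & occ$start < w_hi & occ$start + occ$length > w_lo))
  }
})

test_that("variant sets are genome-consistent and distance-separated", {
  g <- generate_toy_genome(seed = 6, chrom_length = 100000)
  pl <- plant_motif_features(g, peaks_per_feature = 60, seed = 7)
  v <- generate_variant_set(pl$genome, pl$truth, n_disrupting = 50,
                            n_background = 50, seed = 8)
  expect_equal(nrow(v), 100L)
  expect_equal(unname(table(v$label)[c("background", "disrupting")]),
               c(50L, 50L), ignore_attr = TRUE)
  # every ref allele equals the genome base
  for (i in seq_len(nrow(v)))
    expect_identical(as.character(Biostrings::subseq(pl$genome[[v$chrom[i]]],
                                                     v$pos[i], v$pos[i])),
                     v$ref[i])
  # brute-force distance of background variants to every occurrence
  occ <- pl$truth$occurrences
  for (i in which(v$label == "background")) {
    same <- occ$chrom == v$chrom[i]
    d <- pmax(occ$start[same] + 1L - v$pos[i],
              v$pos[i] - (occ$start[same] + occ$length[same]))
    expect_gte(min(d), 1000)
  }
  # VCF round trip
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, path)
  v2 <- read_vcf(path)
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$ref, v$ref)
  expect_equal(v2$alt, v$alt)
})

test_that("trait fixture realizes its designed structure", {
  fx <- generate_trait_fixture(seed = 9, n_genes = 400, n_tissues = 6,
                               frac_regulatory = 0.04)
  reg <- fx$genes$pli[fx$genes$gene %in% fx$regulatory_genes]
  expect_true(all(reg > 0.9))
  other <- fx$genes$pli[!fx$genes$gene %in% fx$regulatory_genes]
  # uniform-on-[0,1] null genes: KS test should not reject wildly
  expect_gt(stats::ks.test(other, "punif")$p.value, 1e-4)

  # designated tissue t-statistics of regulatory genes exceed its 95th
  # percentile, recomputed with the trait-association module's formula
  panel <- tissue_specific_genes(fx$expression, fx$sample_tissue)
  tvals <- panel$t[, fx$designated_tissue]
  cut <- stats::quantile(tvals, 0.95)
  expect_true(all(tvals[fx$regulatory_genes] > cut))

  # files are written and re-readable
  dir <- tempfile()
  fx2 <- generate_trait_fixture(seed = 9, n_genes = 400, n_tissues = 6,
                                frac_regulatory = 0.04, out_dir = dir)
  expect_true(all(file.exists(fx2$files)))
  gw <- utils::read.table(fx2$files[["gwas"]], header = TRUE, sep = "\t")
  expect_equal(nrow(gw), nrow(fx$gwas))
})

test_that("fixture generators are byte-identical under a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  for (d in c(d1, d2)) {
    g <- generate_toy_genome(seed = 11, n_chrom = 1, chrom_length = 60000)
    pl <- plant_motif_features(g, peaks_per_feature = 30, seed = 12,
                               out_dir = d)
    write_genome_fasta(pl$genome, file.path(d, "genome.fa"))
    generate_variant_set(pl$genome, pl$truth, 10, 10, seed = 13,
                         out_vcf = file.path(d, "vars.vcf"))
  }
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})
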