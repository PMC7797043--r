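#' Generate a synthetic genome
#'
#' Draws i.i.d. uniform bases (optionally biased GC) for a configurable number
#' of chromosomes. The result stands in for a reference genome so that the
#' whole peak -> model -> variant pipeline can be exercised without any
#' external download. Sequences are deterministic functions of `seed`.
#'
#' @param seed Integer seed controlling every draw.
#' @param n_chrom Number of chromosomes (>= 1).
#' @param chrom_length Length of each chromosome in bp (>= 1000).
#' @param gc Expected GC fraction (default 0.5, i.e. uniform bases).
#' @param n_run_length If > 0, an `N` run of this length is written into the
#'   middle of each chromosome (used to exercise ambiguous-base encoding).
#' @return A [Biostrings::DNAStringSet] named `chr1`, `chr2`, ...
#' @export
generate_toy_genome <- function(seed, n_chrom = 2L, chrom_length = 200000L,
                                gc = 0.5, n_run_length = 0L) {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (chrom_length < 1000L) stop("chrom_length must be >= 1000")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0,1)")
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    s <- sample(names(p), chrom_length, replace = TRUE, prob = p)
    if (n_run_length > 0L) {
      mid <- chrom_length %/% 2L
      s[seq(mid, length.out = min(n_run_length, chrom_length - mid))] <- "N"
    }
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  Biostrings::DNAStringSet(seqs)
}

#' Write a genome as FASTA
#'
#' @param genome A `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Built-in example motif consensus sequences
#'
#' Three palindromic 8-mers used as default planted motifs: a CRE/ATF-type
#' site (TGACGTCA), a SOX-core-bearing site (ACAATTGT) and a GGATCC-core
#' site (CGGATCCG). Palindromic consensus sites are the prototypical
#' recognition sequences of dimeric transcription factors, and a palindrome
#' is the same evidence on either strand, which suits a strand-symmetric
#' assay. The triple is chosen with minimal self-overlap across shifted or
#' reverse-complemented alignments (one unambiguous alignment frame per
#' site) and minimal pairwise similarity, so that filter-to-motif
#' attribution in tests is unambiguous.
#' @return Named character vector of consensus strings.
#' @export
example_motifs <- function() {
  c(cre_like = "TGACGTCA", sox_like = "ACAATTGT", ggatcc_like = "CGGATCCG")
}

#' Plant motif-dependent chromatin features into a genome
#'
#' Chromatin assays co-localize at shared regulatory elements, so the
#' generator first lays out well-separated candidate "site slots" along each
#' chromosome (adjacent 1000 bp windows overlap by < 200 bp, so distinct
#' slots never merge into one active site) and then assigns each feature's
#' peaks to a random subset of slots; slots may host peaks of several
#' features. For each motif-dependent peak, one occurrence of the feature's
#' motif is written into the genome within +/- `jitter` bp of the peak
#' midpoint and recorded in a truth table. Features assigned `"background"`
#' use slots whose windows contain no planted occurrence.
#'
#' Because instances are written into the sequence, the (modified) genome is
#' part of the return value and must be used downstream.
#'
#' @param genome `DNAStringSet` from [generate_toy_genome()].
#' @param motifs Named character vector of consensus strings (length <= 19).
#' @param n_features Number of features to synthesize.
#' @param peaks_per_feature Positive peaks per feature.
#' @param seed Integer seed.
#' @param feature_motifs Character vector (length `n_features`) of motif names
#'   or `"background"`; defaults to recycling `names(motifs)`.
#' @param peak_width Width of each narrowPeak record (default 200 bp).
#' @param slot_spacing,slot_jitter Slot grid pitch and per-slot positional
#'   jitter in bp; the defaults (900, 45) keep adjacent site windows below
#'   the 200 bp merge threshold.
#' @param jitter Maximum |offset| of the motif start from the peak midpoint.
#' @param out_dir If non-NULL, one narrowPeak file per feature is written here.
#' @return List with elements `genome` (motif-bearing `DNAStringSet`),
#'   `peaks` (named list of `GRanges`), `truth` (list: `occurrences`
#'   data.frame with 0-based starts, `features` data.frame mapping feature to
#'   dependency motif), and `files` (paths, when `out_dir` given).
#' @export
plant_motif_features <- function(genome, motifs = example_motifs(),
                                 n_features = length(motifs),
                                 peaks_per_feature = 200L, seed = 1L,
                                 feature_motifs = NULL,
                                 peak_width = 200L, slot_spacing = 900L,
                                 slot_jitter = 45L, jitter = 100L,
                                 out_dir = NULL) {
  if (any(nchar(motifs) > 19L)) stop("motif longer than the 19 bp filter window")
  if (is.null(feature_motifs))
    feature_motifs <- rep_len(names(motifs), n_features)
  stopifnot(length(feature_motifs) == n_features)
  set.seed(seed)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  seqs <- strsplit(as.character(genome), "")
  # registry of planted intervals per chromosome (1-based start/end)
  planted <- data.frame(chrom = character(), start1 = integer(),
                        end1 = integer())
  occ <- list(); peak_list <- list()
  feature_ids <- sprintf("feat%02d", seq_len(n_features))

  overlaps_planted <- function(chrom, s1, e1) {
    idx <- planted$chrom == chrom
    any(idx & planted$start1 <= e1 & planted$end1 >= s1)
  }

  # candidate slots: jittered grid, one pooled table across chromosomes
  slots <- do.call(rbind, lapply(names(genome), function(chrom) {
    grid <- seq(600L, chrom_len[[chrom]] - 600L, by = slot_spacing)
    data.frame(chrom = chrom,
               mid = grid + sample(seq(-slot_jitter, slot_jitter),
                                   length(grid), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  n_slots <- nrow(slots)
  if (n_slots < peaks_per_feature)
    stop("genome too short: only ", n_slots, " slots for ",
         peaks_per_feature, " peaks per feature")

  slot_has_plant <- logical(n_slots)
  # motif-bearing features first so background features see the full registry
  for (f in order(feature_motifs == "background")) {
    mname <- feature_motifs[f]
    pool <- if (mname == "background") which(!slot_has_plant) else
      seq_len(n_slots)
    if (length(pool) < peaks_per_feature)
      stop("not enough motif-free slots for a background feature")
    take <- sample(pool, peaks_per_feature)
    peaks_f <- list()
    for (si in take) {
      chrom <- slots$chrom[si]; mid <- slots$mid[si]
      if (mname != "background") {
        motif <- motifs[[mname]]
        mlen <- nchar(motif)
        placed <- FALSE
        for (attempt in seq_len(50L)) {
          off <- sample(seq(-jitter, jitter - mlen), 1L)
          s1 <- mid + off + 1L   # 1-based start of the occurrence
          e1 <- s1 + mlen - 1L
          if (!overlaps_planted(chrom, s1, e1)) {
            seqs[[chrom]][s1:e1] <- strsplit(motif, "")[[1]]
            planted <- rbind(planted, data.frame(
              chrom = chrom, start1 = s1, end1 = e1))
            occ[[length(occ) + 1L]] <- data.frame(
              chrom = chrom, start = s1 - 1L, length = mlen, motif = mname,
              feature = feature_ids[f], stringsAsFactors = FALSE)
            slot_has_plant[si] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place motif without overlapping a prior plant")
      } else {
        # background window must stay clear of every occurrence
        if (overlaps_planted(chrom, mid - 500L + 1L, mid + 500L)) next
      }
      half <- peak_width %/% 2L
      peaks_f[[length(peaks_f) + 1L]] <- data.frame(
        chrom = chrom, start = mid - half, end = mid + (peak_width - half),
        stringsAsFactors = FALSE)
    }
    pf <- do.call(rbind, peaks_f)
    gr <- GenomicRanges::GRanges(
      pf$chrom, IRanges::IRanges(start = pf$start + 1L, end = pf$end),
      name = sprintf("%s_peak%03d", feature_ids[f], seq_len(nrow(pf))),
      score = 1000L, signalValue = 1, pValue = -1, qValue = -1,
      peak = peak_width %/% 2L)
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(chrom_len)
    peak_list[[feature_ids[f]]] <- sort(gr)
  }
  peak_list <- peak_list[feature_ids]

  new_genome <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(new_genome) <- names(genome)

  occurrences <- if (length(occ)) do.call(rbind, occ) else
    data.frame(chrom = character(), start = integer(), length = integer(),
               motif = character(), feature = character())
  truth <- list(
    occurrences = occurrences,
    features = data.frame(feature = feature_ids, motif = feature_motifs,
                          stringsAsFactors = FALSE))

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- vapply(names(peak_list), function(fid) {
      path <- file.path(out_dir, paste0(fid, ".narrowPeak"))
      write_narrowpeak(peak_list[[fid]], path)
      path
    }, character(1))
  }
  list(genome = new_genome, peaks = peak_list, truth = truth, files = files)
}

#' Write a GRanges as an ENCODE narrowPeak (BED6+4) file
#' @param gr `GRanges` with optional `name`, `score`, `signalValue`, `pValue`,
#'   `qValue`, `peak` metadata columns (defaults filled in when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(gr, path) {
  m <- S4Vectors::mcols(gr)
  g <- function(col, default) if (col %in% names(m)) m[[col]] else default
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = g("name", paste0("peak", seq_along(gr))),
    score = g("score", 0L),
    strand = ".",
    signalValue = g("signalValue", 0),
    pValue = g("pValue", -1),
    qValue = g("qValue", -1),
    peak = g("peak", -1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate motif-disrupting and background variants
#'
#' Disrupting variants substitute one base inside a planted motif occurrence
#' (every consensus position carries maximal information, so any in-motif
#' substitution breaks the exact site). Background variants are placed at
#' least 1000 bp away from every planted occurrence. Reference alleles are
#' read from the genome, so the emitted VCF is internally consistent.
#'
#' @param genome Motif-bearing genome from [plant_motif_features()].
#' @param truth Truth list from [plant_motif_features()].
#' @param n_disrupting,n_background Group sizes.
#' @param seed Integer seed.
#' @param out_vcf Optional path; when given a VCF v4.2 file is written.
#' @return data.frame with columns chrom, pos (1-based), id, ref, alt,
#'   label (`disrupting`/`background`), feature (dependent feature or NA),
#'   motif.
#' @export
generate_variant_set <- function(genome, truth, n_disrupting = 50L,
                                 n_background = 50L, seed = 1L,
                                 out_vcf = NULL) {
  occ <- truth$occurrences
  if (n_disrupting > 0L && nrow(occ) == 0L)
    stop("truth table has no planted occurrences to disrupt")
  set.seed(seed)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  bases <- c("A", "C", "G", "T")
  base_at <- function(chrom, pos1)
    as.character(Biostrings::subseq(genome[[chrom]], pos1, pos1))

  rows <- list()
  pick <- sample(nrow(occ), n_disrupting, replace = n_disrupting > nrow(occ))
  for (i in seq_len(n_disrupting)) {
    o <- occ[pick[i], ]
    pos1 <- o$start + sample.int(o$length, 1L)  # 1-based position inside motif
    ref <- base_at(o$chrom, pos1)
    alt <- sample(setdiff(bases, ref), 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = o$chrom, pos = pos1, ref = ref, alt = alt,
      label = "disrupting", feature = o$feature, motif = o$motif,
      stringsAsFactors = FALSE)
  }
  n_bg <- 0L; tries <- 0L
  while (n_bg < n_background && tries < 200L * n_background) {
    chrom <- sample(names(genome), 1L)
    pos1 <- sample(1001:(chrom_len[[chrom]] - 1000L), 1L)
    idx <- occ$chrom == chrom
    dmin <- if (any(idx))
      min(pmax(0L, pmax(occ$start[idx] + 1L - pos1,
                        pos1 - (occ$start[idx] + occ$length[idx]))))
    else Inf
    if (dmin >= 1000) {
      ref <- base_at(chrom, pos1)
      if (ref %in% bases) {
        alt <- sample(setdiff(bases, ref), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, pos = pos1, ref = ref, alt = alt,
          label = "background", feature = NA_character_,
          motif = NA_character_, stringsAsFactors = FALSE)
        n_bg <- n_bg + 1L
      }
    }
    tries <- tries + 1L
  }
  if (n_bg < n_background)
    stop("could not place ", n_background, " background variants >= 1 kb from plants")
  variants <- do.call(rbind, rows)
  variants$id <- sprintf("var%04d", seq_len(nrow(variants)))
  variants <- variants[, c("chrom", "pos", "id", "ref", "alt",
                           "label", "feature", "motif")]
  if (!is.null(out_vcf)) write_vcf(variants, out_vcf)
  variants
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write variants as a minimal VCF v4.2 file
#' @param variants data.frame with chrom, pos, id, ref, alt.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                     variants$chrom, variants$pos, variants$id,
                     variants$ref, variants$alt), con)
  invisible(path)
}

#' Read a minimal VCF file into a variant data.frame
#' @param path VCF path (uncompressed).
#' @return data.frame with chrom, pos, id, ref, alt.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body))
    return(data.frame(chrom = character(), pos = integer(), id = character(),
                      ref = character(), alt = character()))
  parts <- strsplit(body, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             id = vapply(parts, `[`, "", 3L),
             ref = vapply(parts, `[`, "", 4L),
             alt = vapply(parts, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic GWAS trait fixture
#'
#' Builds coupled gene, GWAS, expression and SAD tables in which a designed
#' subset of genes is simultaneously (i) close to genome-wide-significant
#' SNPs carrying large |SAD|, (ii) loss-of-function intolerant (pLI drawn
#' from (0.9, 1]), and (iii) specifically over-expressed in one designated
#' tissue. A second, disjoint set of genes receives lead SNPs with
#' negligible SAD (the non-regulatory arm); remaining genes are null.
#'
#' Genes are laid on one virtual chromosome with 120 kb spacing so the
#' +/- 50 kb TSS windows used downstream never span two genes.
#'
#' @param seed Integer seed.
#' @param n_genes Total genes.
#' @param n_tissues Number of tissues; tissue 1 (`tissueA`) is designated.
#' @param frac_regulatory Fraction of genes given the regulatory design.
#' @param samples_per_tissue Expression replicates per tissue.
#' @param n_nonreg_lead Number of genes given non-regulatory lead SNPs.
#' @param effect_fold Expression fold-change of regulatory genes in the
#'   designated tissue.
#' @param sad_high,sad_low Ranges (length-2) of |SAD| for regulatory and
#'   non-regulatory lead SNPs.
#' @param out_dir Optional directory; TSV files are written when given.
#' @return List with `gwas`, `genes`, `expression` (matrix), `sample_tissue`,
#'   `sad` (long SNP x feature table), `designated_tissue`,
#'   `regulatory_genes`, `nonreg_lead_genes`, and `files` when written.
#' @export
generate_trait_fixture <- function(seed, n_genes = 1000L, n_tissues = 10L,
                                   frac_regulatory = 0.05,
                                   samples_per_tissue = 3L,
                                   n_nonreg_lead = 50L,
                                   effect_fold = 8,
                                   sad_high = c(0.15, 0.5),
                                   sad_low = c(0, 0.05),
                                   out_dir = NULL) {
  if (frac_regulatory <= 0 || frac_regulatory >= 1)
    stop("frac_regulatory must be in (0,1)")
  set.seed(seed)
  tissues <- paste0("tissue", LETTERS[seq_len(n_tissues)])
  designated <- tissues[1L]
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  tss <- 60000L + 120000L * (seq_len(n_genes) - 1L)

  n_reg <- max(1L, round(frac_regulatory * n_genes))
  reg_idx <- sample.int(n_genes, n_reg)
  nonreg_idx <- sample(setdiff(seq_len(n_genes), reg_idx), n_nonreg_lead)

  pli <- stats::runif(n_genes)            # null genes: uniform [0,1]
  pli[reg_idx] <- stats::runif(n_reg, 0.9, 1)
  genes <- data.frame(gene = gene_ids, chrom = "chrT", tss = tss, pli = pli,
                      stringsAsFactors = FALSE)

  # expression: log-normal noise; regulatory genes boosted in tissue 1
  n_samples <- n_tissues * samples_per_tissue
  sample_tissue <- rep(tissues, each = samples_per_tissue)
  base_expr <- matrix(stats::rlnorm(n_genes * n_samples, meanlog = 2,
                                    sdlog = 0.4),
                      nrow = n_genes,
                      dimnames = list(gene_ids,
                                      paste0(sample_tissue, "_s",
                                             rep(seq_len(samples_per_tissue),
                                                 times = n_tissues))))
  # regulatory genes: strong, coordinated expression in the designated
  # tissue (low within-tissue dispersion), so the designed tissue-specific
  # set is unambiguous even with few replicates per tissue
  n_boost <- sum(sample_tissue == designated)
  base_expr[reg_idx, sample_tissue == designated] <-
    matrix(stats::rlnorm(n_reg * n_boost,
                         meanlog = 2 + log(effect_fold), sdlog = 0.15),
           nrow = n_reg)

  # GWAS summary statistics: lead SNPs 10 kb from their gene's TSS
  mk_snps <- function(idx, tag, pmin, pmax) {
    data.frame(snp = sprintf("rs_%s_%04d", tag, seq_along(idx)),
               chrom = "chrT", pos = tss[idx] + 10000L,
               p = 10^stats::runif(length(idx), log10(pmin), log10(pmax)),
               stringsAsFactors = FALSE)
  }
  reg_snps <- mk_snps(reg_idx, "reg", 1e-12, 1e-6)
  nonreg_snps <- mk_snps(nonreg_idx, "non", 1e-6, 5e-4)
  null_idx <- setdiff(seq_len(n_genes), c(reg_idx, nonreg_idx))
  null_snps <- mk_snps(null_idx, "null", 5e-3, 1)
  gwas <- rbind(reg_snps, nonreg_snps, null_snps)

  # designed SAD table: one pseudo-feature per tissue
  features <- paste0("dnase_", tissues)
  mk_sad <- function(snps, rng, focus_tissue = NULL) {
    do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      sad <- stats::runif(length(features), sad_low[1], sad_low[2]) *
        sample(c(-1, 1), length(features), replace = TRUE)
      if (!is.null(focus_tissue)) {
        j <- match(paste0("dnase_", focus_tissue), features)
        sad[j] <- stats::runif(1, rng[1], rng[2]) * sample(c(-1, 1), 1)
      }
      data.frame(snp = snps$snp[i], feature = features, sad = sad,
                 stringsAsFactors = FALSE)
    }))
  }
  sad <- rbind(mk_sad(reg_snps, sad_high, designated),
               mk_sad(nonreg_snps, sad_low, NULL),
               mk_sad(null_snps, sad_low, NULL))

  out <- list(gwas = gwas, genes = genes, expression = base_expr,
              sample_tissue = sample_tissue, sad = sad,
              designated_tissue = designated,
              regulatory_genes = gene_ids[reg_idx],
              nonreg_lead_genes = gene_ids[nonreg_idx])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    }
    expr_df <- data.frame(gene = rownames(base_expr), base_expr,
                          check.names = FALSE)
    out$files <- c(gwas = w(gwas, "gwas.tsv"),
                   genes = w(genes, "genes.tsv"),
                   expression = w(expr_df, "expression.tsv"),
                   sad = w(sad, "sad.tsv"))
  }
  out
}
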