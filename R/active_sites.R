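#' Read a narrowPeak / BED peak file
#'
#' Accepts ENCODE narrowPeak (BED6+4) or any >= 3-column BED dialect.
#' `track`/`browser` header lines are skipped silently. Coordinates are
#' 0-based half-open on disk and returned as a 1-based `GRanges`.
#'
#' @param path Path to the peak file.
#' @return `GRanges`; the `midpoint` metadata column holds
#'   `floor((start0 + end0) / 2)` in 0-based coordinates.
#' @export
read_peak_file <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)\\b", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("peak file '", path, "' contains no records")
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed peak line ", lineno[which(nf < 3L)[1]],
         " in '", path, "': fewer than 3 fields")
  chrom <- vapply(parts, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("malformed peak line ", lineno[bad[1]], " in '", path,
         "': non-numeric coordinates")
  if (any(end0 <= start0))
    stop("integrity error at line ", lineno[which(end0 <= start0)[1]],
         " in '", path, "': end <= start")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0))
  S4Vectors::mcols(gr)$midpoint <- (start0 + end0) %/% 2L
  gr
}

peak_midpoints0 <- function(gr) {
  m <- S4Vectors::mcols(gr)
  if ("midpoint" %in% names(m)) return(m$midpoint)
  (GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) %/% 2L
}

#' Build 1000 bp epigenomic active sites from per-feature peak sets
#'
#' Each peak midpoint is extended 500 bp on either side; overlapping windows
#' are then greedily merged (left-to-right sweep per chromosome) until no two
#' emitted sites overlap by more than 200 bp. A merged site's center is the
#' contributing-peak-count-weighted mean of the merged midpoints, rounded
#' half-up; because re-centering can in principle recreate a > 200 bp
#' overlap, the sweep is iterated to a fixed point. Peaks lying within
#' 1000 bp of rRNA/snRNA/snoRNA/tRNA genes are removed beforehand, and sites
#' that would truncate past a chromosome end are dropped.
#'
#' @param peak_sets Named list of `GRanges`, one per chromatin feature.
#' @param genome `DNAStringSet` (used for chromosome lengths/validation).
#' @param exclusion Optional GFF3 path or `GRanges` of genes; entries whose
#'   `type`/`gene_biotype` is rRNA, snRNA, snoRNA or tRNA define exclusion
#'   zones.
#' @param max_overlap Maximum tolerated overlap between emitted sites (bp).
#' @param window Site width in bp.
#' @return `GRanges` of `window`-bp sites with metadata columns
#'   `center` (0-based), `contributing_peaks` and `source_features`
#'   (comma-separated feature ids).
#' @export
build_active_sites <- function(peak_sets, genome, exclusion = NULL,
                               max_overlap = 200L, window = 1000L) {
  stopifnot(is.list(peak_sets), length(peak_sets) > 0L)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("feature", seq_along(peak_sets))
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  half <- window %/% 2L

  excl <- load_exclusion_ranges(exclusion)

  items <- list()
  for (fid in names(peak_sets)) {
    gr <- peak_sets[[fid]]
    if (!length(gr)) next
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    if (!all(chroms %in% names(chrom_len)))
      stop("peak on unknown chromosome: ",
           setdiff(chroms, names(chrom_len))[1])
    if (!is.null(excl) && length(excl)) {
      d <- GenomicRanges::distanceToNearest(gr, excl, ignore.strand = TRUE)
      drop <- rep(FALSE, length(gr))
      drop[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance < 1000L
      gr <- gr[!drop]
      if (!length(gr)) next
      chroms <- as.character(GenomeInfoDb::seqnames(gr))
    }
    items[[fid]] <- data.frame(
      chrom = chroms,
      center = as.numeric(peak_midpoints0(gr)),
      weight = 1,
      features = fid,
      stringsAsFactors = FALSE)
  }
  if (!length(items)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, items)

  # iterate the merge sweep to a fixed point
  repeat {
    res <- merge_pass(df, half, max_overlap)
    df <- res$df
    if (!res$changed) break
  }

  ok <- df$center - half >= 0 & df$center + half <= chrom_len[df$chrom]
  df <- df[ok, , drop = FALSE]
  df <- df[order(df$chrom, df$center), , drop = FALSE]
  if (!nrow(df)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(
    df$chrom,
    IRanges::IRanges(start = df$center - half + 1L,
                     end = df$center + half),
    center = as.integer(df$center),
    contributing_peaks = as.integer(df$weight),
    source_features = df$features)
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_len)
  names(gr) <- sprintf("site%05d", seq_along(gr))
  gr
}

# one left-to-right sweep: cluster items whose windows chain-overlap by more
# than max_overlap, emit weighted-center representatives
merge_pass <- function(df, half, max_overlap) {
  out <- list(); changed <- FALSE
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    d <- d[order(d$center), , drop = FALSE]
    ws <- d$center - half
    we <- d$center + half
    n <- nrow(d)
    cluster_id <- integer(n)
    cid <- 1L; max_end <- we[1]; cluster_id[1] <- 1L
    if (n > 1L) for (i in 2:n) {
      if (ws[i] < max_end - max_overlap) {
        cluster_id[i] <- cid
        max_end <- max(max_end, we[i])
      } else {
        cid <- cid + 1L
        cluster_id[i] <- cid
        max_end <- we[i]
      }
    }
    for (k in unique(cluster_id)) {
      idx <- which(cluster_id == k)
      if (length(idx) > 1L) changed <- TRUE
      w <- d$weight[idx]
      center <- floor(sum(d$center[idx] * w) / sum(w) + 0.5)  # round half-up
      feats <- sort(unique(unlist(strsplit(d$features[idx], ","))))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, center = center, weight = sum(w),
        features = paste(feats, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  list(df = do.call(rbind, out), changed = changed)
}

load_exclusion_ranges <- function(exclusion) {
  if (is.null(exclusion)) return(NULL)
  if (is.character(exclusion)) {
    if (!file.exists(exclusion)) {
      warning("annotation '", exclusion, "' not found; exclusions skipped")
      return(NULL)
    }
    exclusion <- rtracklayer::import(exclusion)
  }
  m <- S4Vectors::mcols(exclusion)
  classes <- c("rRNA", "snRNA", "snoRNA", "tRNA")
  keep <- rep(FALSE, length(exclusion))
  for (col in c("gene_biotype", "biotype", "type"))
    if (col %in% names(m)) keep <- keep | as.character(m[[col]]) %in% classes
  exclusion[keep]
}

#' Build the binary site-by-feature label matrix
#'
#' Entry (s, f) is 1 iff any peak of feature f overlaps site s by at least
#' one bp.
#'
#' @param sites `GRanges` from [build_active_sites()].
#' @param peak_sets The same named list of peak `GRanges`.
#' @return Object of class `label_matrix`: list with `sites`, `features`
#'   (data.frame of feature metadata) and `labels` (binary matrix).
#' @export
build_label_matrix <- function(sites, peak_sets) {
  labels <- matrix(0L, nrow = length(sites), ncol = length(peak_sets),
                   dimnames = list(names(sites), names(peak_sets)))
  for (j in seq_along(peak_sets)) {
    gr <- peak_sets[[j]]
    if (!length(gr)) {
      warning("feature '", names(peak_sets)[j],
              "' has no peaks; emitting a zero column")
      next
    }
    hits <- GenomicRanges::findOverlaps(sites, gr, minoverlap = 1L,
                                        ignore.strand = TRUE)
    labels[unique(S4Vectors::queryHits(hits)), j] <- 1L
  }
  structure(list(sites = sites,
                 features = data.frame(feature = names(peak_sets),
                                       stringsAsFactors = FALSE),
                 labels = labels),
            class = "label_matrix")
}

#' @export
print.label_matrix <- function(x, ...) {
  cat("label_matrix:", nrow(x$labels), "sites x", ncol(x$labels),
      "features;", sum(x$labels), "positive entries\n")
  invisible(x)
}

#' Fraction of the genome covered by active sites
#'
#' @param sites `GRanges` of sites.
#' @param genome `DNAStringSet`.
#' @return Covered bp / total bp, in \[0, 1\].
#' @export
genome_coverage <- function(sites, genome) {
  total <- sum(as.numeric(Biostrings::width(genome)))
  if (total == 0) stop("empty genome")
  if (!length(sites)) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(sites)))) / total
}
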