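#' One-hot encode a DNA sequence
#'
#' Rows are A, C, G, T; each column carries a single 1 in the row of the base
#' at that position. `N` (and other IUPAC ambiguity codes would be rejected)
#' encodes as an all-zero column, so every column sums to at most 1.
#'
#' @param sequence DNA string over A/C/G/T/N, case-insensitive.
#' @return 4 x nchar(sequence) binary matrix with rownames A, C, G, T.
#' @export
one_hot_encode <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid base '", chars[bad[1]], "' at position ", bad[1])
  m <- matrix(0, nrow = 4L, ncol = length(chars),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(chars, c("A", "C", "G", "T"))
  hit <- which(!is.na(idx))
  m[cbind(idx[hit], hit)] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#' @param mat 4 x L one-hot matrix (all-zero columns decode to `N`).
#' @return Character scalar.
#' @export
one_hot_decode <- function(mat) {
  bases <- c("A", "C", "G", "T")
  out <- apply(mat, 2L, function(col) {
    i <- which(col == 1)
    if (length(i) == 1L) bases[i] else "N"
  })
  paste(out, collapse = "")
}

# reverse-complement of a one-hot matrix: complement = reverse the row order
# (A<->T, C<->G), reverse the column order
one_hot_rc <- function(mat) {
  out <- mat[4:1, rev(seq_len(ncol(mat))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

#' Extract site sequences from a genome
#' @param sites `GRanges` of active sites.
#' @param genome `DNAStringSet`.
#' @return `DNAStringSet`, one entry per site.
#' @export
site_sequences <- function(sites, genome) {
  chroms <- as.character(GenomeInfoDb::seqnames(sites))
  if (!all(chroms %in% names(genome)))
    stop("site on chromosome absent from genome")
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(sites), function(i) {
    as.character(Biostrings::subseq(genome[[chroms[i]]],
                                    GenomicRanges::start(sites)[i],
                                    GenomicRanges::end(sites)[i]))
  }, character(1)))
  names(seqs) <- names(sites)
  seqs
}

# stack one-hot matrices into a (4, L, N) array
encode_batch <- function(seqs) {
  n <- length(seqs)
  L <- unique(nchar(as.character(seqs)))
  if (length(L) != 1L) stop("sequences of unequal length")
  X <- array(0, dim = c(4L, L, n))
  for (i in seq_len(n)) X[, , i] <- one_hot_encode(seqs[[i]])
  X
}

# largest-remainder allocation of n items to fractions
split_sizes <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Build an encoded, split dataset from sites and labels
#'
#' Encodes every site's sequence as a one-hot tensor, attaches its label
#' vector, and assigns sites to train/validation/test splits by a seeded
#' random permutation (largest-remainder rounding of the fractions). With
#' `augment = TRUE`, each training example additionally contributes its
#' reverse complement with identical labels; validation and test sets are
#' never augmented.
#'
#' @param sites `GRanges` of active sites.
#' @param genome `DNAStringSet`.
#' @param labels `label_matrix` from [build_label_matrix()].
#' @param fractions Named numeric `(train, validation, test)`, summing to 1.
#' @param seed Integer split seed.
#' @param augment Logical; reverse-complement augmentation of training data.
#' @return Object of class `deepfun_dataset`: list with `X` (4 x L x N array,
#'   forward strand), `y` (N x F binary matrix), `split` (character vector),
#'   `site_ids`, `fractions`, `seed`, `augment`.
#' @export
make_dataset <- function(sites, genome, labels,
                         fractions = c(train = 0.8, validation = 0.1,
                                       test = 0.1),
                         seed = 1L, augment = TRUE) {
  if (any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be positive and sum to 1")
  stopifnot(inherits(labels, "label_matrix"))
  n <- length(sites)
  seqs <- site_sequences(sites, genome)
  X <- encode_batch(seqs)
  y <- labels$labels
  stopifnot(nrow(y) == n)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- split_sizes(n, fractions)
  split <- character(n)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "validation"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  structure(list(X = X, y = y, split = split,
                 site_ids = names(sites), fractions = fractions,
                 seed = seed, augment = augment),
            class = "deepfun_dataset")
}

#' @export
print.deepfun_dataset <- function(x, ...) {
  cat("deepfun_dataset:", dim(x$X)[3], "sites x", ncol(x$y), "features (",
      paste(names(table(x$split)), table(x$split), collapse = ", "),
      "); rc augmentation:", x$augment, "\n")
  invisible(x)
}

# tensors for one split; training tensors get rc copies appended when the
# dataset was built with augment = TRUE
dataset_tensors <- function(dataset, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  idx <- which(dataset$split == which)
  X <- dataset$X[, , idx, drop = FALSE]
  y <- dataset$y[idx, , drop = FALSE]
  if (which == "train" && isTRUE(dataset$augment) && length(idx)) {
    Xrc <- X[4:1, rev(seq_len(dim(X)[2])), , drop = FALSE]
    X2 <- array(0, dim = c(4L, dim(X)[2], 2L * length(idx)))
    X2[, , seq_along(idx)] <- X
    X2[, , length(idx) + seq_along(idx)] <- Xrc
    X <- X2
    y <- rbind(y, y)
  }
  list(X = X, y = y, ids = dataset$site_ids[idx])
}
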