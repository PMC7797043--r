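#' Run the planted-motif study end to end
#'
#' Generates a toy genome, plants motif-dependent chromatin features, builds
#' 1000 bp active sites and the label matrix, encodes and splits the data,
#' trains the reduced convolutional model, and evaluates held-out AUC per
#' feature. This is the desk-scale experiment used throughout the package's
#' tests and documentation.
#'
#' @param seed Master seed; sub-stages derive their own seeds from it.
#' @param n_chrom,chrom_length Genome shape (default 2 x 200 kb).
#' @param motifs Named consensus strings to plant (default
#'   [example_motifs()]).
#' @param peaks_per_feature Positive peaks per feature (default 200).
#' @param spec Model architecture (default [desk_model_spec()]).
#' @param config Training configuration (default: 30-epoch cap, patience
#'   12).
#' @param restarts Number of random initializations piloted. Following the
#'   practice of keeping the model with the smallest validation loss among
#'   several trained candidates, each initialization is piloted for
#'   `pilot_epochs`, and the best seed is then retrained from scratch for
#'   the full epoch budget. The selected model never trains for more than
#'   `config$max_epochs` epochs.
#' @param pilot_epochs Epochs per pilot run.
#' @param verbose Print training progress.
#' @return List with `genome`, `peaks`, `truth`, `sites`, `labels`,
#'   `dataset`, `model`, `auc` (held-out per-feature data.frame).
#' @export
planted_motif_experiment <- function(seed = 1L, n_chrom = 2L,
                                     chrom_length = 200000L,
                                     motifs = example_motifs(),
                                     peaks_per_feature = 200L,
                                     spec = desk_model_spec(),
                                     config = NULL, restarts = 8L,
                                     pilot_epochs = 10L, verbose = FALSE) {
  if (is.null(config))
    config <- train_config(learning_rate = 0.005, decay = 0.95,
                           batch_size = 8L, max_epochs = 30L,
                           patience = 12L, seed = seed + 2L)
  genome0 <- generate_toy_genome(seed, n_chrom, chrom_length)
  planted <- plant_motif_features(genome0, motifs = motifs,
                                  peaks_per_feature = peaks_per_feature,
                                  seed = seed + 1L)
  sites <- build_active_sites(planted$peaks, planted$genome)
  labels <- build_label_matrix(sites, planted$peaks)
  dataset <- make_dataset(sites, planted$genome, labels, seed = seed + 2L)
  model <- train_best_model(spec, dataset, labels$features, config,
                            base_seed = seed + 3L, restarts = restarts,
                            pilot_epochs = pilot_epochs, verbose = verbose)
  te <- dataset_tensors(dataset, "test")
  scores <- predict(model, te$X)
  auc <- evaluate_auc(scores, te$y)
  list(genome = planted$genome, peaks = planted$peaks,
       truth = planted$truth, sites = sites, labels = labels,
       dataset = dataset, model = model, auc = auc)
}

#' Train several random initializations and keep the best
#'
#' Pilots `restarts` differently-seeded initializations for `pilot_epochs`
#' epochs each, then retrains the initialization with the smallest pilot
#' validation loss for the full budget in `config`.
#'
#' @param spec `model_spec`.
#' @param dataset `deepfun_dataset`.
#' @param feature_meta Feature metadata data.frame.
#' @param config `train_config` for the final run.
#' @param base_seed Base initialization seed; restart r uses `base_seed + r`.
#' @param restarts,pilot_epochs Pilot protocol.
#' @param verbose Print progress.
#' @return The selected trained `deepfun_model`.
#' @export
train_best_model <- function(spec, dataset, feature_meta, config,
                             base_seed = 1L, restarts = 8L,
                             pilot_epochs = 10L, verbose = FALSE) {
  n_features <- nrow(feature_meta)
  if (restarts <= 1L) {
    model <- build_model(spec, n_features, seed = base_seed,
                         feature_meta = feature_meta)
    return(train_model(model, dataset, config, verbose = verbose))
  }
  pilot_cfg <- config
  pilot_cfg$max_epochs <- as.integer(pilot_epochs)
  best_seed <- NA_integer_; best_val <- Inf
  for (r in seq_len(restarts)) {
    m <- build_model(spec, n_features, seed = base_seed + r,
                     feature_meta = feature_meta)
    m <- train_model(m, dataset, pilot_cfg)
    v <- min(m$log$val_loss)
    if (verbose)
      message(sprintf("pilot %d (seed %d): best val %.4f", r,
                      base_seed + r, v))
    if (v < best_val) { best_val <- v; best_seed <- base_seed + r }
  }
  model <- build_model(spec, n_features, seed = best_seed,
                       feature_meta = feature_meta)
  train_model(model, dataset, config, verbose = verbose)
}
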