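---
title: "Methods: sequence-based chromatin models, SAD variant scoring and trait prioritization at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-based chromatin models, SAD variant scoring and trait prioritization at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package models

`deepfun` implements a sequence-to-chromatin pipeline of the kind used to
annotate non-coding variants with dense epigenomic maps:

1. **Epigenomic active sites.** Per-assay peak calls (DNase-seq, histone
   ChIP, TF ChIP) are reduced to 1000 bp genomic intervals: each peak is
   extended 500 bp on either side of its midpoint and overlapping windows
   are greedily merged until no two sites overlap by more than 200 bp. Each
   site carries a binary label vector saying which chromatin features have
   a peak overlapping it.
2. **Multitask convolutional model.** A CNN maps the one-hot encoded
   1000 bp sequence of a site to per-feature activity probabilities through
   convolution, ReLU (or a saturating-exponential first-layer activation at
   desk scale, see below), max-pooling, fully connected hidden layers with
   dropout, and a sigmoid output per feature. The loss is mean binary
   cross-entropy across features; optimization is minibatch RMSprop with
   early stopping on validation loss (patience 12 epochs), keeping the
   parameters of the best validation epoch.
3. **SNP Activity Difference (SAD).** For a variant, the model scores the
   1000 bp window carrying the reference allele and the same window
   carrying the alternative allele (variant centered at offset 500); SAD =
   Alt − Ref per feature. Negative SAD means the alternative allele is
   predicted to reduce the epigenetic signal. In-silico saturated
   mutagenesis scores every possible substitution in a region the same way.
4. **Filter interpretation.** First-layer filters are converted to PWMs by
   stacking the sequence alignments at which a filter exceeds half of its
   maximum activation (pseudocount 0.5). Information content is the total
   relative entropy against the background base composition (bits;
   `0·log 0 = 0`), so a uniform PWM scores 0 and a 19-position consensus
   scores 38. Filters are matched to a motif database by the best mean
   per-position Pearson correlation over all offsets and orientations
   (overlap ≥ 5), with an empirical null from position-shuffled filter
   replicas and BH-adjusted q-values. Filter *influence* is measured by
   nullification: a filter's post-activation output map is replaced by its
   mean over the evaluation set, and the per-feature influence is the mean
   change in predicted probability (global influence: sum of squares),
   averaged over 10 random half-subsamples of the test set.
5. **Trait prioritization.** GWAS lead SNPs (p < 1e-3; stricter thresholds
   supported) are called *regulatory loci* when their maximum |SAD| over
   the selected features strictly exceeds 0.1. SNPs map to every gene with
   a TSS within ±50 kb; genes with ≥ 1 regulatory SNP are regulatory
   trait-associated genes (TAGs), remaining mapped genes non-regulatory
   TAGs. Both arms are tested (one-sided Fisher) for enrichment in
   LoF-intolerant genes (pLI > 0.9) and in per-tissue top-5% t-statistic
   expression panels (TSEA). Canonical correlation analysis relates a
   variant × feature SAD matrix to a design matrix over tissues.

# The synthetic fixture generator

Everything is testable offline through `generate_toy_genome()`,
`plant_motif_features()`, `generate_variant_set()` and
`generate_trait_fixture()`. The default study conditions are a 2 × 200 kb
i.i.d.-uniform genome, three chromatin features with 200 positive peaks
each, one 8-mer consensus motif planted per feature within ±100 bp of each
peak midpoint, 50 motif-disrupting versus 50 background variants
(background ≥ 1 kb from any plant), and a trait fixture of 1000 genes ×
10 tissues in which 5% of genes are simultaneously pLI-intolerant,
strongly expressed in one designated tissue, and near low-p/high-|SAD|
SNPs.

Design choices worth knowing:

* **Site slots.** Real assays co-localize at shared regulatory elements,
  so peaks are laid on a jittered grid of candidate "slots" (pitch 900 bp,
  jitter ±45 bp) that several features can share. Adjacent 1000 bp windows
  then overlap by < 200 bp, so distinct slots never chain-merge, labels
  are clean, and the number of training sites is maximal for the stated
  peak counts. Chain-merging itself is exercised separately by unit tests
  against a brute-force oracle.
* **Default motifs.** The planted 8-mers (`TGACGTCA`, `ACAATTGT`,
  `CGGATCCG`) are palindromic consensus sites of the kind bound by dimeric
  transcription factors. They are chosen to have minimal self-overlap
  under shifts and reverse complementation and minimal pairwise
  similarity. This matters: pilot experiments showed that motifs with
  strong shifted/reverse-complement self-matches give convolutional
  filters no unambiguous alignment frame, and at a few hundred training
  examples their filters essentially never converge; palindromes also
  present the same evidence on both strands, matching a strand-symmetric
  assay. Any other consensus set can be passed via `motifs =`.
* **What the generator does not emulate:** read-level noise, peak-calling
  artifacts, GC/repeat structure, linkage disequilibrium between SNPs, and
  diploid genotypes. Passing fixtures therefore demonstrates correctness
  of the pipeline and learnability of clean motif signal, not performance
  on real epigenomes.

# The desk-scale model

The full-scale architecture (`model_spec()` defaults) follows the
three-conv-layer family with 300 × 19 filters (pool 3, symmetric zero
padding of 9 per side), layers of 200 × 11 (pool 4) and 200 × 7 (pool 4),
two 1000-unit hidden layers with 30% dropout, and a sigmoid output.

Training such a model needs millions of sites. The desk preset
(`desk_model_spec()`) keeps the first layer (32 × 19 filters, pool 3,
pad 18) and 64/64 hidden layers but makes three adaptations that pilot
experiments showed to be jointly necessary for learning from ~380 sites
within 30 epochs:

* **Global max pooling** between the conv stack and the dense layers. A
  positional flatten (333 positions × 32 filters) has ~20 parameters per
  training example; with hand-planted *ideal* motif filters the dense
  readout still failed to generalize, while the model memorized the
  training set. One position-invariant activation per filter is the
  standard small-data readout for motif models.
* **Per-filter batch normalization** after the convolution (the
  convention of the architecture family this model extends), with running
  statistics for inference.
* **Saturating-exponential first-layer activation** (`exp(z)`, capped),
  initialized in a sparse-firing regime (BN shift −3). Exponential tail
  amplification makes rare strong alignments dominate the pooled maximum,
  which is what lets randomly initialized filters lock onto planted
  motifs; ReLU is used everywhere else and for the full-scale default.

Optimization: RMSprop (lr 0.005, squared-gradient decay 0.95 at desk
scale; lr 0.002, decay 0.98 full-scale defaults), minibatch 8, optional L2
and momentum (off by default), dropout active only in training. Because
convergence from a random initialization is stochastic at this data scale,
`train_best_model()` pilots 8 initializations for 10 epochs and retrains
the best-validation seed for the full ≤ 30 epoch budget — the same
"train several settings, keep the smallest validation loss" selection used
at full scale. All randomness (weights, shuffling, dropout masks) derives
from explicit seeds; identical seeds give identical loss trajectories.

Reverse-complement augmentation doubles the training set (labels copied;
validation/test are never augmented), applied after splitting so a window
and its reverse complement cannot straddle splits. Splits are by site
(80/10/10, largest-remainder rounding); an optional hold-out-chromosome
mode is not implemented because the uniform toy genome has no homology to
leak.

# Numerical conventions

* Coordinates are BED-style 0-based half-open on disk and 1-based
  internally (`GRanges`); peak midpoints are `floor((start0+end0)/2)`;
  merged-site centers are contributing-peak-weighted means rounded half
  up.
* Merging runs the left-to-right sweep to a fixed point, because
  re-centering can in principle re-create a > 200 bp overlap.
* Exclusion zones: peaks with a gap < 1000 bp to an rRNA/snRNA/snoRNA/tRNA
  gene (GFF3 `type`/`gene_biotype`) are dropped before windowing.
* `N` bases one-hot encode as all-zero columns.
* AUC is the midrank Mann–Whitney statistic (ties credited 0.5); features
  with an empty class report `NA`.
* The one-sided Wilcoxon rank-sum test enumerates all assignments exactly
  (midranks, so ties are handled) when `min(n, m) ≤ 8`, otherwise uses the
  normal approximation with tie and continuity corrections.
* Fisher tests are one-sided ("greater"); degenerate margins report
  OR = NA and p = 1. TSEA reports raw p-values by default (BH optional).
* CCA: columns are centered, each block is whitened by SVD with relative
  rank tolerance 1e-10 (optional ridge for P ≫ N), and the canonical
  correlations are the singular values of the whitened cross-covariance —
  non-increasing by construction. Projections are scaled to unit variance
  and canonical loadings (variable–projection correlations) are returned
  for radius-1 loading plots.
* The SAD threshold 0.1 and lead-SNP threshold 1e-3 are strict
  inequalities; |SAD| makes the rule two-sided.

# Problem sizes

The test-suite and the reproduction script run, by design, at: 400 kb
genome, 3 × 200 peaks (≈ 380 sites, ≈ 600 training examples after
augmentation), a 32-filter model trained ≤ 30 epochs with 8 × 10-epoch
pilots, 100 scored variants, and a 1000-gene × 10-tissue trait fixture.
A full suite run takes a few minutes on one CPU core.

# Known limitations

* The desk preset's global pooling discards positional information, so it
  cannot represent position-dependent grammar; the full-scale spec keeps
  the positional flatten.
* Filter-to-PWM conversion reports background PWMs (support 0) for
  filters that never clear half-max activation; with the exponential
  activation every filter has positive output, so support-0 only arises
  under the ReLU path.
* The motif comparator is an internal stand-in useful for controlled
  fixtures; for real analyses the MEME export (`write_meme()`) feeds
  external comparison tools.
* Gene mapping uses a symmetric ±50 kb TSS window for every SNP;
  LD-aware, gene-length-aware aggregation is deliberately out of scope,
  which inflates multi-gene assignments near dense loci.
* Serialization uses RDS and plain text (FASTA/narrowPeak/VCF/TSV/MEME);
  model checkpoints are R objects, not a cross-language format.
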