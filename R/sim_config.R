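#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions a generated cohort emulates: a single
#' synthetic chromosome partitioned into exon blocks tiled by 1-2 PCR
#' amplicons, a truth set dominated by SNPs (default composition scales
#' the 15811:325 SNP:indel ratio of a gold-standard exome truth set to
#' 1000 variants), per-sample call sets with mostly run-specific false
#' positives, recurrent true positives, false negatives partly explained
#' by sites under 10 reads, and amplicon coverage with high-GC dropout.
#' Class-conditional annotation distributions (the truncated log-normal /
#' beta families that separate FP from TP) are hyper-parameters of the
#' config, not constants in code.
#'
#' @param seed Master integer seed; every stage and sample derives its own
#'   stream from it, so identical configs reproduce byte-identical
#'   cohorts.
#' @param genome_length Synthetic chromosome length in bases (>= 10 kb).
#' @param n_exons Number of exon blocks.
#' @param exon_length_range Exon lengths, sampled uniformly (bases).
#' @param amplicon_length_range Allowed amplicon span (bases); default
#'   156-240.
#' @param gc_high_fraction,gc_low_fraction Fractions of exon blocks built
#'   with high (> 0.75) and low (< 0.25) GC composition.
#' @param n_homopolymer_runs,n_triplet_repeats Sequence motifs planted in
#'   mid-GC exon interiors (homopolymers of length >= 6; triplet repeats).
#' @param n_truth_snps,n_truth_indels Truth-set composition.
#' @param n_samples Cohort size.
#' @param fn_rate_snp,fn_rate_indel Per-sample probabilities that a truth
#'   variant is missed.
#' @param fp_per_sample_snp,fp_per_sample_indel Expected false-positive
#'   records per sample and class.
#' @param fp_unique_fraction Target fraction of distinct cohort FPs seen
#'   in exactly one sample (the run-specific error share).
#' @param fp_recurrent_inclusion Probability that a recurrent-pool FP is
#'   emitted in any given sample.
#' @param multiallelic_fp_indel_fraction Probability an FP indel record is
#'   emitted multiallelic (>= 3 alternate alleles).
#' @param low_depth_fn_fraction Fraction of false negatives placed at
#'   sites with depth below 10 reads.
#' @param mean_coverage Target mean read depth over the amplicon panel.
#' @param gc_dropout_strength Unitless >= 0; expected amplicon read counts
#'   scale with `exp(-strength * penalty(GC))` where the penalty rises
#'   linearly above GC 0.6 (low-GC amplicons are not penalized).
#' @param hc_trim Bases trimmed from each target interval end to form the
#'   high-confidence region.
#' @param annotation Nested list of class-conditional annotation
#'   distribution hyper-parameters; see the package vignette.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       n_exons = 800,
                       exon_length_range = c(120, 300),
                       amplicon_length_range = c(156, 240),
                       gc_high_fraction = 0.05,
                       gc_low_fraction = 0.03,
                       n_homopolymer_runs = 30,
                       n_triplet_repeats = 30,
                       n_truth_snps = 980,
                       n_truth_indels = 20,
                       n_samples = 9,
                       fn_rate_snp = 0.03,
                       fn_rate_indel = 0.30,
                       fp_per_sample_snp = 50,
                       fp_per_sample_indel = 25,
                       fp_unique_fraction = 0.71,
                       fp_recurrent_inclusion = 0.9,
                       multiallelic_fp_indel_fraction = 0.10,
                       low_depth_fn_fraction = 0.33,
                       mean_coverage = 100,
                       gc_dropout_strength = 8,
                       hc_trim = 5,
                       annotation = default_annotation_params()) {
  cfg <- list(
    seed = as.integer(seed),
    chrom = "chr1",
    genome_length = as.integer(genome_length),
    n_exons = as.integer(n_exons),
    exon_length_range = as.integer(exon_length_range),
    amplicon_length_range = as.integer(amplicon_length_range),
    gc_high_fraction = gc_high_fraction,
    gc_low_fraction = gc_low_fraction,
    n_homopolymer_runs = as.integer(n_homopolymer_runs),
    n_triplet_repeats = as.integer(n_triplet_repeats),
    n_truth_snps = as.integer(n_truth_snps),
    n_truth_indels = as.integer(n_truth_indels),
    n_samples = as.integer(n_samples),
    fn_rate_snp = fn_rate_snp,
    fn_rate_indel = fn_rate_indel,
    fp_per_sample_snp = as.integer(fp_per_sample_snp),
    fp_per_sample_indel = as.integer(fp_per_sample_indel),
    fp_unique_fraction = fp_unique_fraction,
    fp_recurrent_inclusion = fp_recurrent_inclusion,
    multiallelic_fp_indel_fraction = multiallelic_fp_indel_fraction,
    low_depth_fn_fraction = low_depth_fn_fraction,
    mean_coverage = mean_coverage,
    gc_dropout_strength = gc_dropout_strength,
    hc_trim = as.integer(hc_trim),
    annotation = annotation
  )
  probs <- c("gc_high_fraction", "gc_low_fraction", "fn_rate_snp",
             "fn_rate_indel", "fp_unique_fraction",
             "fp_recurrent_inclusion", "multiallelic_fp_indel_fraction",
             "low_depth_fn_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must lie in [0, 1]")
    }
  }
  counts <- c("n_exons", "n_homopolymer_runs", "n_triplet_repeats",
              "n_truth_snps", "n_truth_indels", "n_samples",
              "fp_per_sample_snp", "fp_per_sample_indel")
  for (p in counts) {
    if (cfg[[p]] < 0) stop(p, " must be >= 0")
  }
  if (cfg$genome_length < 1e4) stop("genome_length must be >= 10 kb")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  if (cfg$gc_dropout_strength < 0) {
    stop("gc_dropout_strength must be >= 0")
  }
  if (cfg$amplicon_length_range[1] > cfg$amplicon_length_range[2] ||
      cfg$amplicon_length_range[1] < 1) {
    stop("invalid amplicon_length_range")
  }
  if (cfg$exon_length_range[2] > 2 * cfg$amplicon_length_range[2] - 6) {
    stop("exons longer than two amplicons cannot be tiled; shrink ",
         "exon_length_range or widen amplicon_length_range")
  }
  block <- cfg$genome_length %/% cfg$n_exons
  if (block < cfg$exon_length_range[2] + 2 * cfg$amplicon_length_range[2]) {
    stop("genome_length too small for n_exons: blocks must fit an exon ",
         "plus flanking amplicon overhang")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default class-conditional annotation distribution parameters
#'
#' Log-normal location/scale and beta shapes for the caller annotation
#' block, chosen so that false positives sit at low GQ/QUAL/FAO, strand
#' bias pushed toward 1, and elevated homopolymer context for indels,
#' with enough overlap against true positives that threshold tuning is a
#' real trade-off.
#'
#' @return Nested list with `tp` and `fp` components.
#' @export
default_annotation_params <- function() {
  list(
    tp = list(
      gq_meanlog = log(70), gq_sdlog = 0.5,
      qual_meanlog = log(900), qual_sdlog = 0.7,
      fdp_meanlog = log(120), fdp_sdlog = 0.4,
      af_shape1 = 18, af_shape2 = 18,
      stb_shape1 = 2, stb_shape2 = 8,
      hrun_lambda_snp = 0.5, hrun_lambda_indel = 1.5,
      fxx_shape1 = 1, fxx_shape2 = 40,
      stbp_min = 0.02, stbp_max = 1
    ),
    fp = list(
      gq_meanlog = log(6), gq_sdlog = 1.0,
      qual_meanlog = log(35), qual_sdlog = 0.9,
      fdp_meanlog = log(45), fdp_sdlog = 0.8,
      fao_meanlog = log(4), fao_sdlog = 1.0,
      stb_shape1 = 6, stb_shape2 = 1.6,
      hrun_lambda_snp = 1.0, hrun_offset_indel = 4,
      hrun_lambda_indel = 1.5,
      fxx_shape1 = 3, fxx_shape2 = 15,
      stbp_min = 0, stbp_max = 0.2
    )
  )
}

#' Benchmark-scale training configuration for filter tuning
#'
#' The canonical configuration used to derive filter thresholds on
#' synthetic data: roughly 10,000 training true positives and 2,000 false
#' positives per variant class in a single pooled training sample. The
#' per-class truth counts deliberately depart from the SNP-dominated
#' default composition so both classes train on comparable call volumes.
#'
#' @param seed Master seed.
#' @return A [sim_config()].
#' @export
tuning_training_config <- function(seed = 1L) {
  sim_config(
    seed = seed,
    genome_length = 4e6,
    n_exons = 4000,
    n_truth_snps = 10500,
    n_truth_indels = 10500,
    n_samples = 1,
    fn_rate_snp = 0.05,
    fn_rate_indel = 0.05,
    fp_per_sample_snp = 2000,
    fp_per_sample_indel = 2000
  )
}
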