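# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

# small cohort: 3 samples, fast, used by most module tests
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- make_cohort(sim_config(
      seed = 7L, genome_length = 6e5, n_exons = 240,
      n_truth_snps = 300, n_truth_indels = 40, n_samples = 3,
      fp_per_sample_snp = 30, fp_per_sample_indel = 20))
  }
  fixture_env$small
}

# benchmark-scale training cohort shared by the acceptance suite
training_cohort <- function() {
  if (is.null(fixture_env$training)) {
    fixture_env$training <- make_cohort(tuning_training_config(seed = 1L))
  }
  fixture_env$training
}

# random reference string for normalization property tests
random_genome <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE,
           prob = c(0.3, 0.2, 0.2, 0.3)), collapse = ""))
}

# per-base membership oracle: explicit base set of an interval tibble
oracle_base_set <- function(s) {
  if (nrow(s) == 0) return(character())
  unlist(lapply(seq_len(nrow(s)), function(i) {
    paste0(s$chrom[i], ":", seq.int(s$start[i], s$end[i] - 1L))
  }))
}

# random non-canonical interval tibble on a small coordinate range
random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1000,
                             max_len = 60) {
  st <- sample.int(max_pos, n, replace = TRUE) - 1L
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = st,
    end = st + sample.int(max_len, n, replace = TRUE)
  )
}
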