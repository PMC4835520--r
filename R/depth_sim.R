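# Amplicon read-count simulation with GC dropout. Reads span their
# amplicon exactly (amplicon sequencing produces amplicon-length
# fragments; realistic read sequences are out of scope). Expected read
# counts scale with exp(-strength * penalty(GC)); the penalty rises
# linearly above GC 0.6 and is zero below, because low-GC amplicons show
# no coverage bias in this chemistry. Counts are normalized so the
# expected genome-wide mean coverage equals the configured value, then
# drawn per amplicon from a Poisson.

gc_penalty <- function(gc) pmax(0, gc - 0.6) / 0.4

#' Simulate per-amplicon reads and the per-base depth track
#'
#' @param cfg A [sim_config()].
#' @param regions Result of [make_region_sets()].
#' @param seed Integer seed for this sample's read counts.
#' @param dir Optional directory; writes `<sample>.reads.bed` and
#'   `<sample>.bedgraph`.
#' @param sample_id Label used in file names and read names.
#' @return List with `reads` (tibble `chrom`, `start`, `end`, `name`),
#'   `depth` (track covering the chromosome, zero runs included),
#'   `realized_mean`, and per-amplicon expected counts `lambda`.
#' @export
make_depth_and_reads <- function(cfg, regions, seed, dir = NULL,
                                 sample_id = "S1") {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  amp <- regions$amplicons
  if (is.null(amp) || nrow(amp) == 0) stop("amplicon set must be built")
  len <- amp$end - amp$start
  w <- exp(-cfg$gc_dropout_strength * gc_penalty(amp$gc))
  target_bases <- interval_width(regions$targets)
  lambda <- cfg$mean_coverage * target_bases * w / sum(w * len)
  n_reads <- withr::with_seed(as.integer(seed),
                              rpois(length(lambda), lambda))
  idx <- rep(seq_len(nrow(amp)), n_reads)
  reads <- tibble(
    chrom = amp$chrom[idx],
    start = amp$start[idx],
    end = amp$end[idx],
    name = paste0(sample_id, "_r", seq_along(idx))
  )
  depth <- reads_to_depth(reads)
  # extend the track with a zero run to the chromosome end so every
  # position has a defined depth
  last <- if (nrow(depth) > 0) max(depth$end) else 0L
  if (last < cfg$genome_length) {
    depth <- bind_rows(depth, tibble(chrom = cfg$chrom, start = last,
                                     end = cfg$genome_length, depth = 0))
  }
  out <- list(
    reads = reads,
    depth = depth,
    realized_mean = mean_coverage_of_reads(reads, regions$targets),
    lambda = lambda
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    rb <- file.path(dir, paste0(sample_id, ".reads.bed"))
    dg <- file.path(dir, paste0(sample_id, ".bedgraph"))
    write_bed(reads, rb)
    write_bedgraph(depth, dg)
    out$reads_path <- rb
    out$depth_path <- dg
  }
  out
}
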