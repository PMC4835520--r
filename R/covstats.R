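# Depth tracks and coverage statistics. A depth track follows bedGraph
# semantics: non-overlapping 0-based half-open spans with a per-base read
# depth. Bases of a target region not spanned by the track count as depth
# zero in summaries.

validate_depth_track <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(track)))
  if (any(track$depth < 0)) stop("depth must be non-negative")
  invisible(track)
}

#' Read a bedGraph depth track
#'
#' @param path Path to a bedGraph file.
#' @return Tibble `chrom`, `start`, `end`, `depth` (0-based half-open).
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    depth = as.numeric(S4Vectors::mcols(gr)$score)
  )
}

#' Write a depth track as bedGraph
#'
#' @param track Depth track tibble.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  gr <- iset_to_granges(track)
  S4Vectors::mcols(gr)$score <- track$depth
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Depth at point positions
#'
#' @param track Depth track tibble.
#' @param chrom,pos Vectors of chromosome and 1-based position.
#' @return Numeric depth per position; `NA` where the track has no span
#'   covering the position.
#' @export
depth_at <- function(track, chrom, pos) {
  validate_depth_track(track)
  if (length(chrom) == 0) return(numeric())
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(start = pos, width = 1L))
  s <- iset_to_granges(track)
  h <- harmonize_seqlevels(q, s)
  ov <- GenomicRanges::findOverlaps(h$a, h$b, select = "first")
  out <- rep(NA_real_, length(chrom))
  hit <- !is.na(ov)
  out[hit] <- track$depth[ov[hit]]
  out
}

# internal: per-base depth vector over a target interval set, including
# zeros for target bases the track does not span.
target_base_depths <- function(track, targets) {
  tgr <- iset_to_granges(targets)
  dgr <- iset_to_granges(track)
  h <- harmonize_seqlevels(dgr, tgr)
  ov <- GenomicRanges::findOverlaps(h$a, h$b)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    h$a[S4Vectors::queryHits(ov)], h$b[S4Vectors::subjectHits(ov)]))
  d <- track$depth[S4Vectors::queryHits(ov)]
  total <- interval_width(targets)
  covered <- sum(as.double(w))
  if (covered > total + 0.5) {
    stop("depth track spans overlap; not a valid bedGraph track")
  }
  c(rep(d, w), rep(0, total - covered))
}

#' Coverage summary over target regions
#'
#' Mean coverage; `breadth_k`, the fraction of target bases with depth at
#' least `k`; uniformity, the fraction of target bases with depth at least
#' 20 % of the mean coverage; and the inter-quartile range of base depth
#' (median-unbiased quantiles, `type = 8`).
#'
#' @param track Depth track tibble.
#' @param targets Canonical interval set; must be non-empty.
#' @param k Depth threshold for breadth (default 20).
#' @return One-row tibble `mean_coverage`, `breadth_k`, `k`, `uniformity`,
#'   `iqr`.
#' @export
region_depth_summary <- function(track, targets, k = 20) {
  validate_depth_track(track)
  if (nrow(targets) == 0) stop("empty target region set")
  d <- target_base_depths(track, targets)
  mu <- mean(d)
  q <- quantile(d, c(0.25, 0.75), type = 8, names = FALSE)
  tibble(
    mean_coverage = mu,
    breadth_k = mean(d >= k),
    k = k,
    uniformity = mean(d >= 0.2 * mu),
    iqr = q[2] - q[1]
  )
}

#' Per-amplicon coverage, throughput share and GC statistics
#'
#' Reads are assigned to the amplicon they overlap most, ties going to the
#' left-most amplicon; reads overlapping no amplicon stay unassigned.
#' Reported per amplicon: assigned read count, reads-per-million (assigned
#' reads over total reads in millions), per-base mean depth within the
#' amplicon computed from all reads, GC fraction of the amplicon sequence
#' and its class (`high` > 0.75, `low` < 0.25, else `mid`).
#'
#' @param reads Read placements: tibble `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param amplicons Tibble of amplicon intervals (`chrom`, `start`, `end`,
#'   optional `amp_id`); zero-length amplicons are rejected.
#' @param reference FASTA path, `DNAStringSet` or named character vector.
#' @return Tibble of per-amplicon statistics.
#' @export
amplicon_stats <- function(reads, amplicons, reference) {
  if (any(amplicons$end <= amplicons$start)) {
    stop("amplicons must have positive length")
  }
  amplicons <- arrange(as_tibble(amplicons), .data$chrom, .data$start)
  agr <- iset_to_granges(amplicons)
  rgr <- iset_to_granges(reads)
  h <- harmonize_seqlevels(rgr, agr)
  ov <- GenomicRanges::findOverlaps(h$a, h$b)
  n_assigned <- integer(nrow(amplicons))
  if (length(ov) > 0) {
    olap <- GenomicRanges::width(GenomicRanges::pintersect(
      h$a[S4Vectors::queryHits(ov)], h$b[S4Vectors::subjectHits(ov)]))
    # maximal overlap, ties to the left-most amplicon: amplicons are sorted,
    # so the smallest subject index among maxima wins
    o <- order(S4Vectors::queryHits(ov), -olap, S4Vectors::subjectHits(ov))
    first <- !duplicated(S4Vectors::queryHits(ov)[o])
    assigned <- S4Vectors::subjectHits(ov)[o][first]
    tab <- table(assigned)
    n_assigned[as.integer(names(tab))] <- as.integer(tab)
  }
  # per-base mean depth within each amplicon from all reads
  cov <- GenomicRanges::coverage(h$a)
  mean_depth <- vapply(seq_len(nrow(amplicons)), function(i) {
    v <- cov[[amplicons$chrom[i]]]
    if (is.null(v)) return(0)
    if (length(v) < amplicons$end[i]) {
      v <- c(v, S4Vectors::Rle(0L, amplicons$end[i] - length(v)))
    }
    span <- IRanges::IRanges(amplicons$start[i] + 1L, amplicons$end[i])
    mean(IRanges::Views(v, span)[[1]])
  }, numeric(1))

  seqs <- reference_as_strings(reference)
  gc <- vapply(seq_len(nrow(amplicons)), function(i) {
    s <- substr(seqs[[amplicons$chrom[i]]], amplicons$start[i] + 1L,
                amplicons$end[i])
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("G", "C"))
    sum(f) / nchar(s)
  }, numeric(1))

  tibble(
    amp_id = amplicons[["amp_id"]] %||% seq_len(nrow(amplicons)),
    chrom = amplicons$chrom,
    start = amplicons$start,
    end = amplicons$end,
    n_reads = n_assigned,
    reads_per_million = n_assigned / (nrow(reads) / 1e6),
    mean_depth = mean_depth,
    gc = gc,
    gc_class = dplyr::case_when(gc > 0.75 ~ "high",
                                gc < 0.25 ~ "low",
                                TRUE ~ "mid")
  )
}

#' Per-exon coverage table for one sample
#'
#' Helper feeding [hard_region_classifier()]: per exon, the per-base mean
#' depth and the fraction of exon bases with depth > 0.
#'
#' @param track Depth track tibble.
#' @param exons Tibble `chrom`, `start`, `end` with an `exon_id` column.
#' @return Tibble `exon_id`, `mean_depth`, `covered_fraction`.
#' @export
exon_coverage <- function(track, exons) {
  stopifnot(!is.null(exons[["exon_id"]]))
  validate_depth_track(track)
  out <- lapply(seq_len(nrow(exons)), function(i) {
    d <- target_base_depths(track, exons[i, c("chrom", "start", "end")])
    tibble(exon_id = exons$exon_id[i], mean_depth = mean(d),
           covered_fraction = mean(d > 0))
  })
  bind_rows(out)
}

#' Classify hard-to-sequence exons across a cohort
#'
#' An exon is `always_low` when its per-base mean depth is below
#' `depth_threshold` (default 10 reads) in every sample, and `partial_f`
#' for f in {0.5, 0.25, 0.1} when its covered fraction is below f in every
#' sample. The partial classes are nested by construction. Exons absent
#' from a sample's table are treated as depth 0 in that sample and counted
#' in `n_missing_entries`.
#'
#' @param cov_table Tibble with `exon_id`, `sample`, `mean_depth`,
#'   `covered_fraction`, from >= 2 samples.
#' @param depth_threshold Always-low depth cut-off (reads).
#' @return List with per-exon `classes` tibble and a one-row `summary`.
#' @export
hard_region_classifier <- function(cov_table, depth_threshold = 10) {
  stopifnot(all(c("exon_id", "sample", "mean_depth", "covered_fraction")
                %in% names(cov_table)))
  samples <- unique(cov_table$sample)
  if (length(samples) < 2) stop("need coverage tables from >= 2 samples")
  full <- tidyr::expand_grid(exon_id = unique(cov_table$exon_id),
                             sample = samples) %>%
    left_join(cov_table, by = c("exon_id", "sample"))
  n_missing <- sum(is.na(full$mean_depth))
  full$mean_depth[is.na(full$mean_depth)] <- 0
  full$covered_fraction[is.na(full$covered_fraction)] <- 0
  classes <- full %>%
    group_by(.data$exon_id) %>%
    summarise(
      always_low = all(.data$mean_depth < depth_threshold),
      partial_0.5 = all(.data$covered_fraction < 0.5),
      partial_0.25 = all(.data$covered_fraction < 0.25),
      partial_0.1 = all(.data$covered_fraction < 0.1),
      .groups = "drop"
    )
  list(
    classes = classes,
    summary = tibble(
      n_exons = nrow(classes),
      n_samples = length(samples),
      n_missing_entries = n_missing,
      n_always_low = sum(classes$always_low),
      n_partial_0.5 = sum(classes$partial_0.5),
      n_partial_0.25 = sum(classes$partial_0.25),
      n_partial_0.1 = sum(classes$partial_0.1)
    )
  )
}
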