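# Region-set construction: one exon per block, tiled by one amplicon
# when it fits inside the allowed amplicon span, otherwise by two
# overlapping amplicons. Targets are the union of amplicons; the
# high-confidence set trims each target interval's ends, mimicking a
# truth-set provider excluding boundary bases.

#' Build the named region sets of a synthetic design
#'
#' @param cfg A [sim_config()].
#' @param reference Result of [make_reference()] (used for amplicon GC
#'   annotation and bounds checks).
#' @param dir Optional directory: writes `cds.bed`, `amplicons.bed`,
#'   `targets.bed`, `high_confidence.bed`.
#' @return List with `exons` (tibble with `exon_id`, `gene`), `amplicons`
#'   (tibble with `amp_id`, `gc`, `gc_class`), and canonical interval
#'   sets `cds`, `targets`, `high_confidence`.
#' @export
make_region_sets <- function(cfg, reference, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(reference[["seq"]])) stop("reference must exist")
  blocks <- reference$blocks
  block_len <- blocks$end[1] - blocks$start[1]
  amin <- cfg$amplicon_length_range[1]
  amax <- cfg$amplicon_length_range[2]

  # uniform draw on lo:hi that never degenerates to sample(1:n) semantics
  sample_range <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

  built <- withr::with_seed(derive_seed(cfg$seed, 21L), {
    exon_len <- cfg$exon_length_range[1] - 1L +
      sample.int(diff(cfg$exon_length_range) + 1L, cfg$n_exons,
                 replace = TRUE)
    es <- blocks$start + (block_len - exon_len) %/% 2L
    ee <- es + exon_len
    amp <- vector("list", cfg$n_exons)
    for (i in seq_len(cfg$n_exons)) {
      if (exon_len[i] > 2L * amax - 6L) {
        stop("exon longer than two amplicons; invalid configuration")
      }
      if (exon_len[i] <= amax) {
        al <- sample_range(max(amin, exon_len[i]), amax)
        a1 <- es[i] - (al - exon_len[i]) %/% 2L
        amp[[i]] <- tibble(exon_id = i,
                           start = a1, end = a1 + al)
      } else {
        lmin <- max(amin, (exon_len[i] + 6L + 1L) %/% 2L)
        l1 <- sample_range(lmin, amax)
        l2 <- sample_range(lmin, amax)
        a1s <- es[i] - 3L
        a2e <- ee[i] + 3L
        amp[[i]] <- tibble(exon_id = i,
                           start = c(a1s, a2e - l2),
                           end = c(a1s + l1, a2e))
      }
    }
    list(exon_start = es, exon_end = ee, amp = bind_rows(amp))
  })

  exons <- tibble(
    exon_id = seq_len(cfg$n_exons),
    chrom = cfg$chrom,
    start = built$exon_start,
    end = built$exon_end,
    gene = paste0("GENE", sprintf("%04d", (seq_len(cfg$n_exons) - 1L) %/%
                                    3L + 1L)),
    gc_class = blocks$gc_class
  )
  amp <- built$amp
  amp$chrom <- cfg$chrom
  amp$amp_id <- sprintf("AMP%05d", seq_len(nrow(amp)))
  seqstr <- as.character(reference$seq[[1]])
  amp$gc <- vapply(seq_len(nrow(amp)), function(i) {
    ch <- strsplit(substr(seqstr, amp$start[i] + 1L, amp$end[i]), "")[[1]]
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  amp$gc_class <- dplyr::case_when(amp$gc > 0.75 ~ "high",
                                   amp$gc < 0.25 ~ "low",
                                   TRUE ~ "mid")
  amp <- amp[c("amp_id", "exon_id", "chrom", "start", "end", "gc",
               "gc_class")]

  targets <- interval_set(amp)
  regions <- list(
    exons = exons,
    amplicons = amp,
    cds = interval_set(exons),
    targets = targets,
    high_confidence = shrink_intervals(targets, cfg$hc_trim)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_bed(mutate(exons, name = .data$gene), file.path(dir, "cds.bed"))
    write_bed(mutate(amp, name = .data$amp_id),
              file.path(dir, "amplicons.bed"))
    write_bed(regions$targets, file.path(dir, "targets.bed"))
    write_bed(regions$high_confidence,
              file.path(dir, "high_confidence.bed"))
  }
  regions
}
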