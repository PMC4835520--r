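#' Generate a full synthetic cohort
#'
#' Runs every generator stage — reference, region sets, truth set, and
#' per-sample depth tracks, read placements and annotated call sets —
#' under streams derived from the master seed, so the same config always
#' reproduces the same cohort. When `dir` is given, all artifacts are
#' written as plain-text FASTA / BED / bedGraph / VCF plus per-sample
#' label TSVs.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return A `synthetic_cohort`: list with `cfg`, `reference`, `regions`,
#'   `truth`, and `samples` (per sample: `depth`, `reads`, `calls`,
#'   `labels`, and file paths when written).
#' @export
make_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) if (is.null(dir)) NULL else file.path(dir, ...)

  reference <- make_reference(cfg, path = pth("reference.fa"))
  regions <- make_region_sets(cfg, reference, dir = dir)
  truth <- make_truth_variants(cfg, reference, regions,
                               path = pth("truth.vcf"))
  fp_pool <- make_fp_pool(cfg, truth)

  samples <- lapply(seq_len(cfg$n_samples), function(s) {
    sid <- paste0("S", s)
    dp <- make_depth_and_reads(cfg, regions,
                               seed = derive_seed(cfg$seed, 60L, s),
                               dir = dir, sample_id = sid)
    cs <- make_callset(cfg, truth, dp, sample_id = s, fp_pool = fp_pool,
                       path = pth(paste0(sid, ".vcf")))
    if (!is.null(dir)) {
      utils::write.table(cs$labels, pth(paste0(sid, ".labels.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(sample_id = sid, depth = dp$depth, reads = dp$reads,
         realized_mean = dp$realized_mean, calls = cs$calls,
         labels = cs$labels, vcf = cs$path,
         depth_path = dp$depth_path, reads_path = dp$reads_path)
  })
  names(samples) <- paste0("S", seq_len(cfg$n_samples))

  structure(
    list(cfg = cfg, reference = reference, regions = regions,
         truth = truth, fp_pool = fp_pool, samples = samples, dir = dir),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d samples, %d truth variants (%d SNP / %d indel), %d amplicons\n",
    length(x$samples), nrow(x$truth$variants),
    sum(x$truth$variants$variant_class == "SNP"),
    sum(x$truth$variants$variant_class != "SNP"),
    nrow(x$regions$amplicons)))
  invisible(x)
}

#' Normalized, labelled calls for one cohort sample
#'
#' Convenience for benchmarking and tuning: runs the sample's emitted
#' records through multiallelic splitting and left-alignment, restricts
#' them to high-confidence ∩ CDS, and attaches the generator's truth
#' labels by exact key.
#'
#' @param cohort A `synthetic_cohort`.
#' @param sample Sample index or name.
#' @return Normalized call tibble with a `label` column.
#' @export
cohort_labelled_calls <- function(cohort, sample = 1) {
  s <- cohort$samples[[sample]]
  core <- intersect_intervals(cohort$regions$high_confidence,
                              cohort$regions$cds)
  norm <- normalize_variants(s$calls, cohort$reference$seq)
  norm <- restrict_to_regions(norm, core)
  lab <- s$labels[s$labels$label != "FN", ]
  norm$label <- lab$label[match(variant_key(norm), variant_key(lab))]
  if (anyNA(norm$label)) {
    stop("internal error: emitted call without a generator label")
  }
  norm
}
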