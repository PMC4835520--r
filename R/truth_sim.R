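# Truth-set construction. Candidate variant positions form a strided
# grid over the evaluation core (high-confidence ∩ CDS) so variants never
# collide even after left-alignment shifts; the grid is shuffled once and
# consumed sequentially by the truth set, the recurrent FP pool and each
# sample's unique FPs.

# internal: shuffled 0-based candidate positions, stride 10, with margins
# so short deletions stay inside their interval.
position_grid <- function(cfg, regions) {
  core <- intersect_intervals(regions$high_confidence, regions$cds)
  slots <- unlist(lapply(seq_len(nrow(core)), function(i) {
    lo <- core$start[i] + 2L
    hi <- core$end[i] - 6L
    if (hi < lo) return(integer())
    seq.int(lo, hi, by = 10L)
  }))
  withr::with_seed(derive_seed(cfg$seed, 31L), sample(slots))
}

# internal: build variant alleles at grid slots. kind is "SNP" or
# "indel"; returns tibble(chrom, pos, ref, alt) 1-based, un-aligned.
alleles_at_slots <- function(cfg, seqstr, slots, kind) {
  n <- length(slots)
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  pos <- slots + 1L
  base_at <- substr_vec(seqstr, pos, pos)
  if (kind == "SNP") {
    alt <- vapply(base_at, function(b) sample(setdiff(BASES, b), 1), "")
    tibble(chrom = cfg$chrom, pos = pos, ref = base_at, alt = unname(alt))
  } else {
    is_del <- runif(n) < 0.5
    len <- sample(1:3, n, replace = TRUE)
    ref <- ifelse(is_del,
                  substr_vec(seqstr, pos, pos + len),
                  base_at)
    ins <- vapply(len, function(l) {
      paste(sample(BASES, l, replace = TRUE), collapse = "")
    }, "")
    alt <- ifelse(is_del, base_at, paste0(base_at, ins))
    tibble(chrom = cfg$chrom, pos = pos, ref = ref, alt = alt)
  }
}

# internal: vectorized substr at differing positions
substr_vec <- function(s, from, to) {
  substring(s, from, to)
}

#' Generate the truth variant set
#'
#' Draws the configured numbers of SNPs and indels at non-colliding
#' positions inside high-confidence ∩ CDS, left-aligns them, and verifies
#' membership after alignment (variants that shift outside the core are
#' replaced). The returned object also carries the unconsumed position
#' grid, from which false-positive placement later draws, so synthetic
#' call sets never collide with truth sites.
#'
#' @param cfg A [sim_config()].
#' @param reference Result of [make_reference()].
#' @param regions Result of [make_region_sets()].
#' @param path Optional truth VCF output path.
#' @return A `truth_set`: list with `variants` (normalized tibble with
#'   `variant_class`), `spare_slots`, `regions`, `reference` and `path`.
#' @export
make_truth_variants <- function(cfg, reference, regions, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  seqstr <- as.character(reference$seq[[1]])
  grid <- position_grid(cfg, regions)
  core <- intersect_intervals(regions$high_confidence, regions$cds)
  n_need <- cfg$n_truth_snps + cfg$n_truth_indels
  if (n_need > length(grid)) {
    stop(sprintf(
      "requested %d truth variants but only %d candidate positions exist",
      n_need, length(grid)))
  }

  take <- function(slots, n, kind, seed_stream) {
    withr::with_seed(derive_seed(cfg$seed, seed_stream), {
      got <- empty <- tibble()
      used <- 0L
      while (nrow(got) < n) {
        want <- n - nrow(got)
        batch_n <- min(length(slots) - used, max(want + 8L, ceiling(want * 1.2)))
        if (batch_n <= 0) stop("candidate position grid exhausted")
        batch <- alleles_at_slots(cfg, seqstr,
                                  slots[(used + 1L):(used + batch_n)], kind)
        used <- used + batch_n
        batch <- left_align(batch, setNames(seqstr, cfg$chrom))
        keep <- points_in_intervals(core, batch$chrom, batch$pos - 1L)
        got <- bind_rows(got, batch[keep, ])
        got <- got[!duplicated(variant_key(got)), ]
      }
      list(variants = got[seq_len(n), ], n_used = used)
    })
  }

  drop_first <- function(x, n) if (n > 0) x[-seq_len(n)] else x
  snp <- take(grid, cfg$n_truth_snps, "SNP", 32L)
  grid2 <- drop_first(grid, snp$n_used)
  indel <- take(grid2, cfg$n_truth_indels, "indel", 33L)
  spare <- drop_first(grid2, indel$n_used)

  variants <- bind_rows(snp$variants, indel$variants) %>%
    arrange(.data$chrom, .data$pos, .data$alt)
  variants$n_original_alts <- 1L
  if (!is.null(path)) {
    write_vcf(variants, path,
              contigs = setNames(cfg$genome_length, cfg$chrom),
              sample_id = "TRUTH")
  }
  structure(
    list(variants = variants, spare_slots = spare, regions = regions,
         reference = reference, path = path),
    class = "truth_set")
}
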