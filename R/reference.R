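# Synthetic reference construction. The chromosome is partitioned into
# one block per exon; each block is generated with a GC composition drawn
# from its designated class (high > 0.75, low < 0.25, mid ~ 0.5), and
# homopolymer runs (>= 6 bp) plus triplet repeats are planted inside
# mid-GC block centres, where exons will later sit, emulating the
# hard-to-call sequence contexts of flow-space chemistry.

BASES <- c("A", "C", "G", "T")

block_base_probs <- list(
  high = c(A = 0.06, C = 0.44, G = 0.44, T = 0.06),
  low = c(A = 0.44, C = 0.06, G = 0.06, T = 0.44),
  mid = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
)

# internal: deterministic block layout shared by make_reference and
# make_region_sets; one block per exon, GC class assigned by config.
block_layout <- function(cfg) {
  block_len <- cfg$genome_length %/% cfg$n_exons
  n_high <- round(cfg$gc_high_fraction * cfg$n_exons)
  n_low <- round(cfg$gc_low_fraction * cfg$n_exons)
  classes <- c(rep("high", n_high), rep("low", n_low),
               rep("mid", cfg$n_exons - n_high - n_low))
  classes <- withr::with_seed(derive_seed(cfg$seed, 11L), sample(classes))
  tibble(
    block = seq_len(cfg$n_exons),
    start = (seq_len(cfg$n_exons) - 1L) * block_len,
    end = seq_len(cfg$n_exons) * block_len,
    gc_class = classes
  )
}

#' Generate the synthetic reference sequence
#'
#' @param cfg A [sim_config()].
#' @param path Optional FASTA output path (60-column wrapped).
#' @return List with `seq` (a named `DNAStringSet`), the block layout
#'   tibble, a `motifs` tibble of planted homopolymer/triplet intervals,
#'   and `path` when written.
#' @export
make_reference <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  blocks <- block_layout(cfg)
  block_len <- blocks$end[1] - blocks$start[1]
  chars <- withr::with_seed(derive_seed(cfg$seed, 12L), {
    unlist(lapply(blocks$gc_class, function(cl) {
      sample(BASES, block_len, replace = TRUE,
             prob = block_base_probs[[cl]])
    }))
  })
  tail_n <- cfg$genome_length - length(chars)
  if (tail_n > 0) {
    chars <- c(chars, withr::with_seed(
      derive_seed(cfg$seed, 13L),
      sample(BASES, tail_n, replace = TRUE)))
  }

  # plant motifs in the centres of distinct mid-GC blocks
  mid_blocks <- blocks$block[blocks$gc_class == "mid"]
  n_mot <- cfg$n_homopolymer_runs + cfg$n_triplet_repeats
  if (n_mot > length(mid_blocks)) {
    stop("not enough mid-GC blocks to plant the configured motifs")
  }
  motifs <- withr::with_seed(derive_seed(cfg$seed, 14L), {
    chosen <- sample(mid_blocks, n_mot)
    out <- vector("list", n_mot)
    for (i in seq_len(n_mot)) {
      b <- chosen[i]
      centre <- blocks$start[b] + block_len %/% 2L
      if (i <= cfg$n_homopolymer_runs) {
        len <- sample(6:9, 1)
        base <- sample(BASES, 1)
        motif <- strrep(base, len)
        type <- "homopolymer"
      } else {
        unit <- paste(sample(BASES, 3, replace = TRUE), collapse = "")
        reps <- sample(4:6, 1)
        motif <- strrep(unit, reps)
        len <- nchar(motif)
        type <- "triplet"
      }
      at <- centre + sample(-30:30, 1)
      chars[(at + 1L):(at + len)] <- strsplit(motif, "")[[1]]
      out[[i]] <- tibble(type = type, start = at, end = at + len)
    }
    bind_rows(out)
  })

  seq <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(seq) <- cfg$chrom
  if (!is.null(path)) {
    Biostrings::writeXStringSet(seq, path, width = 60)
  }
  list(seq = seq, blocks = blocks, motifs = motifs, path = path)
}

#' Count homopolymer runs of at least a given length
#'
#' Linear scan over a sequence; used to verify planted sequence structure.
#'
#' @param seq A `DNAStringSet`, single string, or character scalar.
#' @param min_len Minimum run length (default 6).
#' @return Integer count of maximal single-base runs of length
#'   `>= min_len`.
#' @export
count_homopolymer_runs <- function(seq, min_len = 6) {
  if (methods::is(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
  r <- rle(strsplit(seq, "")[[1]])
  sum(r$lengths >= min_len)
}

#' GC fraction of a sequence window
#'
#' @param seq `DNAStringSet` or character scalar.
#' @param start,end Optional 0-based half-open window; default whole
#'   sequence.
#' @export
gc_fraction <- function(seq, start = NULL, end = NULL) {
  if (methods::is(seq, "DNAStringSet")) seq <- as.character(seq[[1]])
  if (!is.null(start)) seq <- substr(seq, start + 1L, end)
  ch <- strsplit(seq, "")[[1]]
  mean(ch %in% c("G", "C"))
}
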