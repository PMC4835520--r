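# Variant normalization: multiallelic splitting, indel left-alignment and
# region restriction. Benchmarking compares normalized single-alt records
# by exact (chrom, pos, ref, alt) keys, so both call sets and truth must go
# through the same normalization before matching.

#' Classify normalized alleles
#'
#' @param ref,alt Character vectors of REF/ALT alleles (single alt).
#' @return Character vector: `"SNP"`, `"insertion"`, `"deletion"` or
#'   `"complex"` (equal-length multi-base substitution).
#' @export
classify_alleles <- function(ref, alt) {
  lr <- nchar(ref)
  la <- nchar(alt)
  dplyr::case_when(
    lr == 1 & la == 1 ~ "SNP",
    la > lr ~ "insertion",
    lr > la ~ "deletion",
    TRUE ~ "complex"
  )
}

#' Split multiallelic records into one record per alternate allele
#'
#' Each output record carries `n_original_alts`, the alternate allele count
#' of the originating VCF line; per-allele annotations (`ao`, `fao`) are
#' routed to the matching record and converted to numeric, site-level
#' annotations are copied. Records that arrive already split keep any
#' existing `n_original_alts`.
#'
#' @param calls Variant-record tibble (see [read_vcf()]).
#' @return Tibble with one row per (record, alt) pair.
#' @export
split_multiallelic <- function(calls) {
  if (nrow(calls) == 0) {
    out <- calls
    out$n_original_alts <- integer()
    return(out)
  }
  if (anyNA(calls$alt) || any(calls$alt %in% c("", "."))) {
    stop("records without alternate alleles cannot be split")
  }
  alts <- strsplit(calls$alt, ",", fixed = TRUE)
  k <- lengths(alts)
  prior <- calls[["n_original_alts"]] %||% rep(NA_integer_, nrow(calls))
  n_orig <- ifelse(k == 1L & !is.na(prior), prior, k)

  split_per_alt <- function(col) {
    if (is.null(calls[[col]])) return(rep(NA_real_, sum(k)))
    parts <- strsplit(as.character(calls[[col]]), ",", fixed = TRUE)
    bad <- !is.na(calls[[col]]) & lengths(parts) != k
    if (any(bad)) {
      stop(sprintf("per-allele annotation '%s' has wrong arity at %s:%d",
                   col, calls$chrom[which(bad)[1]], calls$pos[which(bad)[1]]))
    }
    parts[is.na(calls[[col]])] <- lapply(k[is.na(calls[[col]])],
                                         function(m) rep(NA, m))
    suppressWarnings(as.numeric(unlist(parts)))
  }
  ao_num <- split_per_alt("ao")
  fao_num <- split_per_alt("fao")

  out <- calls[rep(seq_len(nrow(calls)), k), ]
  out$alt <- unlist(alts)
  out$ao <- ao_num
  out$fao <- fao_num
  out$n_original_alts <- rep(as.integer(n_orig), k)
  as_tibble(out)
}

# internal: left-align and trim a single (pos, ref, alt) against one
# chromosome sequence given as a plain character string. Returns
# list(pos, ref, alt). Implements the standard normalization contract:
# repeatedly trim identical trailing bases (extending left with the
# reference when an allele would empty), then trim identical leading bases
# while both alleles keep >= 2 bases; iterate to a fixed point.
left_align_one <- function(pos, ref, alt, chromseq) {
  repeat {
    changed <- FALSE
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (substr(ref, nr, nr) != substr(alt, na, na)) break
      if (nr == 1L || na == 1L) {
        if (pos == 1L) break
        b <- substr(chromseq, pos - 1L, pos - 1L)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
        pos <- pos - 1L
        nr <- nr + 1L; na <- na + 1L
      }
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      changed <- TRUE
    }
    while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      changed <- TRUE
    }
    if (!changed) break
  }
  list(pos = pos, ref = ref, alt = alt)
}

# internal: coerce a reference argument (FASTA path, DNAStringSet or named
# character vector) into a named character vector of chromosome sequences.
reference_as_strings <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference) && !is.null(names(reference))) {
    return(reference)
  }
  stop("reference must be a FASTA path, DNAStringSet or named character vector")
}

#' Left-align and trim single-alt variant records
#'
#' Shifts indels to their left-most equivalent position against the
#' reference, keeping one anchor base (VCF convention), and removes shared
#' leading/trailing bases so the representation is minimal. Applying the
#' original and the normalized edit to the reference yields identical
#' haplotypes, and the operation is idempotent. SNPs pass through
#' unchanged. Adds `variant_class`, `indel_length` and `normalized`
#' columns.
#'
#' @param calls Variant-record tibble with single-alt records (run
#'   [split_multiallelic()] first).
#' @param reference FASTA path, `DNAStringSet`, or named character vector
#'   of chromosome sequences.
#' @return The normalized tibble.
#' @export
left_align <- function(calls, reference) {
  if (nrow(calls) == 0) {
    calls$variant_class <- character()
    calls$indel_length <- integer()
    calls$normalized <- logical()
    return(calls)
  }
  if (any(grepl(",", calls$alt, fixed = TRUE))) {
    stop("multiallelic records present; run split_multiallelic() first")
  }
  seqs <- reference_as_strings(reference)
  missing_chrom <- setdiff(unique(calls$chrom), names(seqs))
  if (length(missing_chrom) > 0) {
    stop("reference does not cover chromosome(s): ",
         paste(missing_chrom, collapse = ", "))
  }
  pos <- as.integer(calls$pos)
  ref <- as.character(calls$ref)
  alt <- as.character(calls$alt)
  chrom <- as.character(calls$chrom)
  # reference consistency check, vectorized
  obs <- substr(seqs[chrom], pos, pos + nchar(ref) - 1L)
  bad <- obs != ref
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "REF allele disagrees with reference at %s:%d (VCF '%s', reference '%s')",
      chrom[i], pos[i], ref[i], obs[i]))
  }
  needs <- !(nchar(ref) == 1L & nchar(alt) == 1L)
  for (i in which(needs)) {
    r <- left_align_one(pos[i], ref[i], alt[i], seqs[[chrom[i]]])
    pos[i] <- r$pos
    ref[i] <- r$ref
    alt[i] <- r$alt
  }
  out <- calls
  out$pos <- pos
  out$ref <- ref
  out$alt <- alt
  out$variant_class <- classify_alleles(ref, alt)
  out$indel_length <- abs(nchar(ref) - nchar(alt))
  out$normalized <- TRUE
  out
}

#' Normalize a call set (split then left-align)
#'
#' @inheritParams left_align
#' @export
normalize_variants <- function(calls, reference) {
  left_align(split_multiallelic(calls), reference)
}

#' Restrict variants to an evaluation region set
#'
#' A record is retained iff its (0-based converted) POS lies inside the
#' region set; the REF span is not considered, so boundary indels are
#' handled by their anchor position only.
#'
#' @param calls Variant-record tibble.
#' @param regions Canonical interval set.
#' @return The retained subset.
#' @export
restrict_to_regions <- function(calls, regions) {
  if (nrow(calls) == 0) return(calls)
  calls[points_in_intervals(regions, calls$chrom, calls$pos - 1L), ]
}

#' Apply a variant edit to a reference sequence
#'
#' Utility for haplotype-equivalence checks: substitutes `alt` for `ref`
#' at `pos` in the chromosome string.
#'
#' @param chromseq Chromosome sequence as a single string.
#' @param pos 1-based position.
#' @param ref,alt Alleles.
#' @return The edited haplotype string.
#' @export
apply_variant <- function(chromseq, pos, ref, alt) {
  stopifnot(substr(chromseq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(chromseq, 1L, pos - 1L), alt,
         substr(chromseq, pos + nchar(ref), nchar(chromseq)))
}
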