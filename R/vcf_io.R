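# VCF input/output for caller-annotated call sets.
#
# Records carry the flow-space caller annotation block: AO, DP, FAO, FDP,
# FXX, HRUN, QD, STB, STBP as INFO keys (AO and FAO per-alt), GQ as a
# FORMAT field, plus N_ORIG_ALTS tracking multiallelic origin through
# splitting. Reading is delegated to vcfR; writing is plain-text VCF 4.2
# serialization so generated cohorts are byte-reproducible.

INFO_KEYS_NUM <- c("DP", "FDP", "FXX", "HRUN", "QD", "STB", "STBP")
INFO_KEYS_PER_ALT <- c("AO", "FAO")

#' Read a caller-annotated VCF into a variant-record tibble
#'
#' Multiallelic records are kept as single rows with comma-separated `alt`
#' (and per-alt `ao`/`fao` strings); use [split_multiallelic()] to expand
#' them. Missing annotations become `NA` rather than dropping the record.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @return Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `qual`, `filter`, the annotation block in lower case (`ao`, `dp`,
#'   `fao`, `fdp`, `fxx`, `gq`, `hrun`, `qd`, `stb`, `stbp`) and
#'   `n_original_alts` when present in INFO.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- v@fix
  if (is.null(fx) || nrow(fx) == 0) {
    return(empty_variant_tibble())
  }
  out <- tibble(
    chrom = as.character(fx[, "CHROM"]),
    pos = as.integer(fx[, "POS"]),
    ref = as.character(fx[, "REF"]),
    alt = as.character(fx[, "ALT"]),
    qual = suppressWarnings(as.numeric(fx[, "QUAL"])),
    filter = as.character(fx[, "FILTER"])
  )
  for (k in INFO_KEYS_PER_ALT) {
    out[[tolower(k)]] <- as.character(
      vcfR::extract.info(v, element = k))
  }
  for (k in INFO_KEYS_NUM) {
    out[[tolower(k)]] <- suppressWarnings(as.numeric(
      vcfR::extract.info(v, element = k)))
  }
  noa <- suppressWarnings(as.integer(
    vcfR::extract.info(v, element = "N_ORIG_ALTS")))
  if (!all(is.na(noa))) out$n_original_alts <- noa
  if (!is.null(v@gt) && ncol(v@gt) >= 2) {
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ",
                                            as.numeric = TRUE))
    out$gq <- as.numeric(gq[, 1])
  } else {
    out$gq <- NA_real_
  }
  out
}

empty_variant_tibble <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), qual = double(), filter = character(),
    ao = character(), fao = character(), dp = double(), fdp = double(),
    fxx = double(), hrun = double(), qd = double(), stb = double(),
    stbp = double(), gq = double()
  )
}

# internal: format a numeric INFO value compactly, "." for NA
fmt_info_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", formatC(x, format = "g", digits = digits))
}

#' Write a variant-record tibble as VCF 4.2
#'
#' Serializes records with the caller annotation block as INFO keys, GQ
#' as a FORMAT field, and `N_ORIG_ALTS` carrying multiallelic origin.
#' Output is plain text (never gzipped) so repeated runs of the synthetic
#' generator are byte-identical.
#'
#' @param calls Variant-record tibble (see [read_vcf()] for columns; all
#'   annotation columns are optional).
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @param sample_id Sample column name, default `"SAMPLE"`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, contigs = NULL, sample_id = "SAMPLE") {
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=ampliqc",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs))
    },
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observations\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=FAO,Number=A,Type=Integer,Description=\"Flow-space alternate allele observations\">",
    "##INFO=<ID=FDP,Number=1,Type=Integer,Description=\"Flow-space read depth\">",
    "##INFO=<ID=FXX,Number=1,Type=Float,Description=\"Flow evaluator failed reads ratio\">",
    "##INFO=<ID=HRUN,Number=1,Type=Integer,Description=\"Homopolymer run length at the locus\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality per read depth\">",
    "##INFO=<ID=STB,Number=1,Type=Float,Description=\"Strand bias ratio\">",
    "##INFO=<ID=STBP,Number=1,Type=Float,Description=\"Strand bias p value\">",
    "##INFO=<ID=N_ORIG_ALTS,Number=1,Type=Integer,Description=\"Alternate allele count of the originating record\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  n <- nrow(calls)
  if (n == 0) {
    writeLines(meta, path)
    return(invisible(path))
  }
  info_parts <- list()
  add_part <- function(key, vals) {
    info_parts[[length(info_parts) + 1L]] <<-
      ifelse(is.na(vals) | vals == ".", NA_character_,
             paste0(key, "=", vals))
  }
  for (k in INFO_KEYS_PER_ALT) {
    col <- tolower(k)
    if (!is.null(calls[[col]])) add_part(k, as.character(calls[[col]]))
  }
  for (k in INFO_KEYS_NUM) {
    col <- tolower(k)
    if (!is.null(calls[[col]])) add_part(k, fmt_info_num(calls[[col]]))
  }
  if (!is.null(calls[["n_original_alts"]])) {
    add_part("N_ORIG_ALTS", as.character(calls[["n_original_alts"]]))
  }
  if (length(info_parts) > 0) {
    pm <- do.call(cbind, info_parts)
    info <- apply(pm, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) == 0) "." else paste(r, collapse = ";")
    })
  } else {
    info <- rep(".", n)
  }
  gq <- calls[["gq"]] %||% rep(NA_real_, n)
  gt <- calls[["gt"]] %||% rep("0/1", n)
  filt <- calls[["filter"]] %||% rep(".", n)
  qual <- calls[["qual"]] %||% rep(NA_real_, n)
  body <- paste(
    calls$chrom, calls$pos, ".", calls$ref, calls$alt,
    fmt_info_num(qual), ifelse(is.na(filt), ".", filt), info,
    "GT:GQ",
    paste0(gt, ":", ifelse(is.na(gq), ".", as.integer(round(gq)))),
    sep = "\t"
  )
  writeLines(c(meta, body), path)
  invisible(path)
}
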