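#' Genomic interval sets
#'
#' An interval set is a tibble of strand-free genomic intervals in BED
#' convention: `chrom`, 0-based inclusive `start`, exclusive `end`.
#' [interval_set()] canonicalizes its input: intervals are sorted by
#' `(chrom, start)` and overlapping or bookended intervals are merged, so
#' all downstream set algebra operates on disjoint, ordered intervals.
#' Canonicalization is idempotent.
#'
#' @param chrom Character vector of sequence names, or a data frame with
#'   columns `chrom`, `start`, `end` (in which case `start`/`end` are
#'   ignored).
#' @param start,end Integer vectors, 0-based half-open coordinates.
#' @return A tibble with columns `chrom`, `start`, `end`, canonical.
#' @examples
#' interval_set("chr1", c(0L, 5L), c(10L, 20L))
#' @export
interval_set <- function(chrom, start = NULL, end = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
    chrom <- as.character(df$chrom)
    start <- df$start
    end <- df$end
  }
  if (length(chrom) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(chrom) || anyNA(start) || anyNA(end)) {
    stop("interval set must not contain NA coordinates")
  }
  if (any(start < 0L) || any(start >= end)) {
    stop("intervals require 0 <= start < end")
  }
  granges_to_iset(GenomicRanges::reduce(iset_to_granges(
    tibble(chrom = chrom, start = start, end = end))))
}

# internal: 0-based half-open tibble -> GRanges (1-based closed)
iset_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_iset <- function(gr) {
  gr <- GenomicRanges::sort(GenomeInfoDb::sortSeqlevels(gr))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# internal: put two GRanges on a common seqlevel universe
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Intersect two interval sets per base
#'
#' @param a,b Canonical interval sets (see [interval_set()]).
#' @return The canonical interval set of bases present in both `a` and `b`.
#' @export
intersect_intervals <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(interval_set(character()))
  }
  h <- harmonize_seqlevels(iset_to_granges(a), iset_to_granges(b))
  granges_to_iset(GenomicRanges::intersect(h$a, h$b))
}

#' Subtract one interval set from another per base
#'
#' @param a,b Canonical interval sets.
#' @return Canonical interval set of bases in `a` but not in `b`.
#' @export
subtract_intervals <- function(a, b) {
  if (nrow(a) == 0) return(interval_set(character()))
  if (nrow(b) == 0) return(interval_set(a))
  h <- harmonize_seqlevels(iset_to_granges(a), iset_to_granges(b))
  granges_to_iset(GenomicRanges::setdiff(h$a, h$b))
}

#' Union of two interval sets
#'
#' @param a,b Canonical interval sets.
#' @return Canonical interval set of bases in either input.
#' @export
union_intervals <- function(a, b) {
  interval_set(bind_rows(a[c("chrom", "start", "end")],
                         b[c("chrom", "start", "end")]))
}

#' Pad every interval by a symmetric flank
#'
#' Each interval is extended by `flank` bases on both sides, clipped at
#' coordinate zero, and the result re-canonicalized (so intervals brought
#' within touching distance merge).
#'
#' @param s Canonical interval set.
#' @param flank Non-negative integer number of bases.
#' @export
pad_intervals <- function(s, flank) {
  flank <- as.integer(flank)
  if (length(flank) != 1 || is.na(flank) || flank < 0L) {
    stop("flank must be a single non-negative integer")
  }
  if (nrow(s) == 0) return(interval_set(character()))
  interval_set(s$chrom, pmax(0L, s$start - flank), s$end + flank)
}

# internal: shrink each interval by `trim` bases per side, dropping emptied
# intervals. Used to carve high-confidence cores out of target intervals.
shrink_intervals <- function(s, trim) {
  trim <- as.integer(trim)
  st <- s$start + trim
  en <- s$end - trim
  keep <- st < en
  if (!any(keep)) return(interval_set(character()))
  interval_set(s$chrom[keep], st[keep], en[keep])
}

#' Total number of bases covered by an interval set
#'
#' @param s Canonical interval set.
#' @return A double (base count).
#' @export
interval_width <- function(s) {
  if (nrow(s) == 0) return(0)
  sum(as.double(s$end - s$start))
}

#' Membership of point positions in an interval set
#'
#' @param s Canonical interval set.
#' @param chrom Character vector of sequence names.
#' @param pos0 Integer vector of 0-based positions.
#' @return Logical vector: is each position inside `s`?
#' @export
points_in_intervals <- function(s, chrom, pos0) {
  if (length(chrom) == 0) return(logical())
  if (nrow(s) == 0) return(rep(FALSE, length(chrom)))
  q <- GenomicRanges::GRanges(as.character(chrom),
                              IRanges::IRanges(start = pos0 + 1L, width = 1L))
  h <- harmonize_seqlevels(q, iset_to_granges(s))
  GenomicRanges::countOverlaps(h$a, h$b) > 0L
}

#' Read a BED file
#'
#' Reads BED3/BED6 via rtracklayer and returns 0-based half-open tibble
#' coordinates. The `name` column (e.g. gene symbol or amplicon id) is kept
#' when present. No canonicalization is applied, so gene models with
#' overlapping exons survive the round trip; pass the result through
#' [interval_set()] when a canonical set is needed.
#'
#' @param path Path to a BED file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm) && !all(is.na(nm))) out$name <- as.character(nm)
  out
}

#' Write intervals to a BED file
#'
#' @param s Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(s, path) {
  gr <- iset_to_granges(s)
  if (!is.null(s[["name"]])) S4Vectors::mcols(gr)$name <- s[["name"]]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
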