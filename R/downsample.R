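# Random read downsampling and the coverage/variant-loss curve fits.
# Thinning is Bernoulli per read with p = target_mean / current_mean,
# mirroring samtools -s behaviour; depth is then recomputed from the
# retained reads. Variant callability after thinning is emulated by a
# site-depth rule: a truth variant is lost iff its post-thinning depth
# falls below `callable_depth` (default 20 reads, anchored to the
# breadth-at-20x statistic the coverage analysis is built on).

#' Depth track from read placements
#'
#' @param reads Tibble `chrom`, `start`, `end` (0-based half-open).
#' @return Depth track tibble covering each chromosome from base 0 to the
#'   last read end, zero-depth runs included.
#' @export
reads_to_depth <- function(reads) {
  if (nrow(reads) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  depth = numeric()))
  }
  cov <- GenomicRanges::coverage(iset_to_granges(reads))
  out <- lapply(names(cov), function(ch) {
    v <- cov[[ch]]
    ends <- cumsum(S4Vectors::runLength(v))
    tibble(chrom = ch,
           start = c(0L, head(ends, -1)),
           end = ends,
           depth = as.numeric(S4Vectors::runValue(v)))
  })
  bind_rows(out)
}

#' Mean coverage of a read set over target regions
#'
#' @param reads Read placement tibble.
#' @param targets Canonical interval set.
#' @return Mean per-base depth over the target bases.
#' @export
mean_coverage_of_reads <- function(reads, targets) {
  if (nrow(reads) == 0) return(0)
  rgr <- iset_to_granges(reads)
  tgr <- iset_to_granges(targets)
  h <- harmonize_seqlevels(rgr, tgr)
  ov <- GenomicRanges::findOverlaps(h$a, h$b)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    h$a[S4Vectors::queryHits(ov)], h$b[S4Vectors::subjectHits(ov)]))
  sum(as.double(w)) / interval_width(targets)
}

#' Randomly downsample reads to a target mean coverage
#'
#' @param reads Read placement tibble.
#' @param targets Canonical interval set defining the mean-coverage
#'   denominator.
#' @param target_mean Desired mean coverage; must not exceed the current
#'   mean.
#' @param seed Integer seed for the Bernoulli thinning.
#' @return List with `reads` (retained subset), `depth` (recomputed
#'   track), `p_keep`, `current_mean` and `realized_mean`.
#' @export
downsample_reads <- function(reads, targets, target_mean, seed) {
  cur <- mean_coverage_of_reads(reads, targets)
  if (target_mean > cur + 1e-9) {
    stop(sprintf("target mean %.1f exceeds current mean %.1f",
                 target_mean, cur))
  }
  p <- min(1, target_mean / cur)
  keep <- withr::with_seed(as.integer(seed),
                           runif(nrow(reads)) < p)
  kept <- reads[keep, ]
  depth <- reads_to_depth(kept)
  list(
    reads = kept,
    depth = depth,
    p_keep = p,
    current_mean = cur,
    realized_mean = mean_coverage_of_reads(kept, targets)
  )
}

#' Fraction of truth variants lost at a coverage level
#'
#' The callability emulation: a variant is lost iff the post-thinning
#' depth at its position is below `callable_depth`.
#'
#' @param truth Normalized truth tibble (`chrom`, `pos`).
#' @param depth Depth track after thinning.
#' @param callable_depth Site depth required to keep a call (default 20).
#' @export
variant_loss_fraction <- function(truth, depth, callable_depth = 20) {
  d <- depth_at(depth, truth$chrom, truth$pos)
  d[is.na(d)] <- 0
  mean(d < callable_depth)
}

#' Run a downsampling titration series
#'
#' Thins the read set to each target mean coverage, recomputes the depth
#' track, and records realized mean, breadth at `k`, and the fraction of
#' truth variants lost under the callability rule.
#'
#' @param reads Read placement tibble.
#' @param targets Canonical interval set.
#' @param truth Normalized truth tibble.
#' @param levels Numeric vector of target mean coverages (e.g.
#'   `c(90, 80, 70, 60, 50, 40, 30, 20)`).
#' @param seed Integer master seed; each level derives its own stream.
#' @param k Breadth threshold (default 20).
#' @return Tibble with one row per level.
#' @export
run_downsample_series <- function(reads, targets, truth, levels, seed,
                                  k = 20) {
  levels <- sort(levels, decreasing = TRUE)
  rows <- lapply(seq_along(levels), function(i) {
    ds <- downsample_reads(reads, targets, levels[i],
                           seed = derive_seed(seed, 900L, i))
    cs <- region_depth_summary(ds$depth, targets, k = k)
    tibble(
      target_mean = levels[i],
      realized_mean = ds$realized_mean,
      breadth_20 = cs$breadth_k,
      variants_lost = variant_loss_fraction(truth, ds$depth,
                                            callable_depth = k)
    )
  })
  bind_rows(rows)
}

#' Fit the coverage-breadth and variant-loss curves
#'
#' Least-squares fits of the two relationships the downsampling titration
#' exposes: breadth(mean) = 1 - exp(-(mean - m0)/tau), fitted with
#' Levenberg-Marquardt and predictions clipped to \[0, 1\]; and
#' loss(breadth) = a + b * breadth, by ordinary least squares. Each fit
#' reports r-squared; a degenerate (constant) series yields `NA` r-squared
#' for the affected fit.
#'
#' @param series Tibble from [run_downsample_series()] (columns
#'   `realized_mean`, `breadth_20`, and optionally `variants_lost`).
#' @return List with `exponential` (m0, tau, r2), `linear` (intercept,
#'   slope, r2) and the input `series`.
#' @export
fit_coverage_curves <- function(series) {
  stopifnot(nrow(series) >= 4)
  m <- series$realized_mean
  b <- series$breadth_20
  r2_of <- function(obs, pred) {
    sst <- sum((obs - mean(obs))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((obs - pred)^2) / sst
  }
  expo <- tryCatch({
    fit <- minpack.lm::nlsLM(
      b ~ 1 - exp(-(m - m0) / tau),
      start = list(m0 = min(m) * 0.5, tau = max(diff(range(m)) / 2, 1)),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    p <- coef(fit)
    pred <- pmin(1, pmax(0, 1 - exp(-(m - p[["m0"]]) / p[["tau"]])))
    tibble(m0 = p[["m0"]], tau = p[["tau"]], r2 = r2_of(b, pred))
  }, error = function(e) tibble(m0 = NA_real_, tau = NA_real_,
                                r2 = NA_real_))
  if (!is.null(series[["variants_lost"]]) &&
      length(unique(b)) > 1) {
    lf <- lm(series$variants_lost ~ b)
    lin <- tibble(intercept = coef(lf)[[1]], slope = coef(lf)[[2]],
                  r2 = r2_of(series$variants_lost, stats::fitted(lf)))
  } else {
    lin <- tibble(intercept = NA_real_, slope = NA_real_, r2 = NA_real_)
  }
  list(exponential = expo, linear = lin, series = series)
}
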