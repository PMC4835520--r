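# Multi-parameter quality-filter derivation. Five caller parameters per
# variant class (SNP: GQ, FDP, QUAL, STB, FAO; indel: GQ, FDP, QUAL,
# HRUN, FAO) are searched exhaustively over a candidate-threshold grid;
# the selected combination maximizes false-positive removal subject to
# retaining at least the target fraction of training true positives.
# Removal is the OR of one-sided failing conditions: a call is removed
# iff GQ < GQ_min, FDP < FDP_min, QUAL < QUAL_min, FAO < FAO_min, or
# STB > STB_max (SNPs) / HRUN > HRUN_max (indels).

TVC_PARAMETERS <- c("AO", "DP", "FAO", "FDP", "FXX", "GQ", "HRUN", "QD",
                    "QUAL", "STB", "STBP")

tuning_parameters <- function(variant_class) {
  if (variant_class == "SNP") {
    list(names = c("gq", "fdp", "qual", "stb", "fao"),
         direction = c("min", "min", "min", "max", "min"))
  } else {
    list(names = c("gq", "fdp", "qual", "hrun", "fao"),
         direction = c("min", "min", "min", "max", "min"))
  }
}

#' Construct a filter specification
#'
#' @param variant_class `"SNP"` or `"indel"`.
#' @param thresholds Named list: `gq_min`, `fdp_min`, `qual_min`,
#'   `fao_min`, plus `stb_max` (SNP) or `hrun_max` (indel).
#' @param stringency Optional label (`"low"`, `"medium"`, `"high"`, ...).
#' @param target_retention Optional TP-retention target in (0, 1].
#' @export
filter_spec <- function(variant_class, thresholds, stringency = NA_character_,
                        target_retention = NA_real_) {
  variant_class <- match.arg(variant_class, c("SNP", "indel"))
  pars <- tuning_parameters(variant_class)
  want <- paste0(pars$names, ifelse(pars$direction == "min", "_min", "_max"))
  missing <- setdiff(want, names(thresholds))
  if (length(missing) > 0) {
    stop("missing thresholds: ", paste(missing, collapse = ", "))
  }
  thresholds <- lapply(thresholds[want], as.numeric)
  if (any(vapply(thresholds, is.na, logical(1)))) {
    stop("thresholds must be finite numbers")
  }
  structure(
    list(variant_class = variant_class, stringency = stringency,
         thresholds = thresholds, target_retention = target_retention),
    class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Filter spec (%s%s):\n", x$variant_class,
              if (is.na(x$stringency)) "" else
                paste0(", ", x$stringency, "-stringency")))
  for (nm in names(x$thresholds)) {
    cat(sprintf("  %s = %g\n", nm, x$thresholds[[nm]]))
  }
  if (!is.na(x$target_retention)) {
    cat(sprintf("  target TP retention = %g\n", x$target_retention))
  }
  invisible(x)
}

# internal: keep / missing vectors for a call table under a spec. A call
# with any required parameter missing is flagged `missing` (it can never
# be kept); otherwise `keep` is the AND of the one-sided pass conditions.
spec_keeps <- function(calls, spec) {
  pars <- tuning_parameters(spec$variant_class)
  keep <- rep(TRUE, nrow(calls))
  miss <- rep(FALSE, nrow(calls))
  for (j in seq_along(pars$names)) {
    col <- pars$names[j]
    thr_name <- paste0(col, ifelse(pars$direction[j] == "min",
                                   "_min", "_max"))
    x <- calls[[col]]
    if (is.null(x)) x <- rep(NA_real_, nrow(calls))
    miss <- miss | is.na(x)
    ok <- if (pars$direction[j] == "min") {
      x >= spec$thresholds[[thr_name]]
    } else {
      x <= spec$thresholds[[thr_name]]
    }
    ok[is.na(ok)] <- FALSE
    keep <- keep & ok
  }
  list(keep = keep & !miss, missing = miss)
}

#' Apply a filter specification to a call set
#'
#' A call is removed iff any failing condition holds; retained records get
#' `FILTER = "PASS"`, removed records `FILTER = "ts_<stringency>"`. Calls
#' missing a required parameter are removed with `FILTER = "ts_missing"`
#' and counted separately. Applying a spec to its own retained set removes
#' nothing (idempotence).
#'
#' @param calls Normalized call tibble carrying the tuning parameters in
#'   lower case.
#' @param spec A [filter_spec()].
#' @return List with `retained`, `removed`, the annotated `calls` tibble
#'   and a one-row `counts` summary.
#' @export
apply_filter <- function(calls, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  sk <- spec_keeps(calls, spec)
  keep <- sk$keep
  tag <- if (is.na(spec$stringency)) "ts_filter" else
    paste0("ts_", spec$stringency)
  filt <- ifelse(sk$missing, "ts_missing", ifelse(keep, "PASS", tag))
  out <- calls
  out$filter <- filt
  list(
    retained = out[keep, ],
    removed = out[!keep, ],
    calls = out,
    counts = tibble(
      n = nrow(calls),
      n_retained = sum(keep),
      n_removed = sum(filt == tag),
      n_missing = sum(filt == "ts_missing")
    )
  )
}

# internal: candidate threshold grids. For each parameter: an always-
# permissive sentinel (-Inf for _min, +Inf for _max), the deciles of the
# TP distribution, and any preset thresholds supplied for that parameter.
candidate_grid <- function(tp_calls, pars, probs, preset_values) {
  lapply(seq_along(pars$names), function(j) {
    x <- tp_calls[[pars$names[j]]]
    qs <- quantile(x, probs = probs, type = 8, names = FALSE)
    extra <- preset_values[[pars$names[j]]] %||% numeric()
    if (pars$direction[j] == "min") {
      sort(unique(c(-Inf, qs, extra)))
    } else {
      # transformed below to min-semantics on -x; keep natural scale here
      sort(unique(c(qs, extra, Inf)))
    }
  })
}

# internal: 5-D suffix cumulative sum via per-dimension matrix products
suffix_cumsum_array <- function(arr) {
  dims <- dim(arr)
  nd <- length(dims)
  for (d in seq_len(nd)) {
    perm <- c(d, setdiff(seq_len(nd), d))
    a <- aperm(arr, perm)
    sz <- dim(a)
    m <- matrix(a, nrow = sz[1])
    tr <- upper.tri(matrix(0, sz[1], sz[1]), diag = TRUE) * 1
    m <- tr %*% m
    a <- array(m, dim = sz)
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Derive filter thresholds at a target true-positive retention
#'
#' Exhaustive search over the per-parameter candidate grid (TP-distribution
#' deciles plus preset thresholds plus an always-permissive sentinel).
#' Feasible combinations retain at least `target_retention` of training
#' TPs; among those, the combination removing the most FPs is selected.
#' Ties are broken by higher TP retention, then by more permissive
#' thresholds in the fixed order GQ, FDP, QUAL, HRUN/STB, FAO. The
#' always-permissive combination guarantees feasibility.
#'
#' The search is exact: calls are binned by the number of candidate
#' thresholds they pass per parameter, and retained counts for all
#' combinations are obtained by a 5-dimensional suffix cumulative sum, so
#' the result equals brute-force enumeration of the grid.
#'
#' @param calls Labelled normalized call tibble (`label` column with
#'   `"TP"`/`"FP"`) carrying the tuning parameters.
#' @param variant_class `"SNP"` or `"indel"`.
#' @param target_retention Minimum fraction of training TPs the filter
#'   must retain (presets: 0.99 low, 0.95 medium, 0.90 high stringency).
#' @param candidate_probs Quantile probabilities for the TP candidate
#'   grid; default deciles.
#' @param presets Optional list of [filter_spec()]s whose thresholds are
#'   added to the candidate grid; defaults to the shipped presets for the
#'   class.
#' @return A tuning result: list with the selected `spec`,
#'   `train_retention`, `train_fp_removal`, counts, grid sizes and the
#'   number of tied optima.
#' @export
tune_thresholds <- function(calls, variant_class = c("SNP", "indel"),
                            target_retention,
                            candidate_probs = seq(0, 1, by = 0.1),
                            presets = NULL) {
  variant_class <- match.arg(variant_class)
  stopifnot(target_retention > 0, target_retention <= 1)
  pars <- tuning_parameters(variant_class)
  stopifnot(!is.null(calls[["label"]]))
  calls <- filter_class(calls, variant_class)
  need <- pars$names
  have <- intersect(need, names(calls))
  if (length(have) < length(need)) {
    stop("calls lack tuning parameter(s): ",
         paste(setdiff(need, have), collapse = ", "))
  }
  complete <- stats::complete.cases(calls[need])
  n_dropped <- sum(!complete)
  calls <- calls[complete, ]
  tp <- calls[calls$label == "TP", ]
  fp <- calls[calls$label == "FP", ]
  if (nrow(tp) == 0 || nrow(fp) == 0) {
    stop("both TP and FP labels must be represented")
  }

  if (is.null(presets)) {
    presets <- tryCatch(filter_presets(), error = function(e) list())
  }
  preset_values <- list()
  for (p in presets) {
    if (!inherits(p, "filter_spec") || p$variant_class != variant_class) next
    for (nm in names(p$thresholds)) {
      col <- sub("_(min|max)$", "", nm)
      preset_values[[col]] <- c(preset_values[[col]], p$thresholds[[nm]])
    }
  }
  cand <- candidate_grid(tp, pars, candidate_probs, preset_values)
  # transform to uniform min-semantics: keep iff x' >= t'
  xform <- function(x, dir) if (dir == "min") x else -x
  cand_t <- lapply(seq_along(cand), function(j) {
    sort(xform(cand[[j]], pars$direction[j]))
  })
  dims <- lengths(cand_t)

  bin_index <- function(df) {
    idx <- vapply(seq_along(cand_t), function(j) {
      findInterval(xform(df[[pars$names[j]]], pars$direction[j]),
                   cand_t[[j]])
    }, integer(nrow(df)))
    idx <- matrix(idx, ncol = length(cand_t))
    stopifnot(all(idx >= 1L))
    1L + (idx - 1L) %*% cumprod(c(1L, dims[-length(dims)]))
  }
  tp_arr <- array(tabulate(bin_index(tp), nbins = prod(dims)), dim = dims)
  fp_arr <- array(tabulate(bin_index(fp), nbins = prod(dims)), dim = dims)
  tp_kept <- suffix_cumsum_array(tp_arr)
  fp_kept <- suffix_cumsum_array(fp_arr)

  feasible <- tp_kept >= target_retention * nrow(tp) - 1e-9
  stopifnot(any(feasible))  # the all-permissive cell is always feasible
  removed <- nrow(fp) - fp_kept
  best_removed <- max(removed[feasible])
  cand_cells <- which(feasible & removed == best_removed)
  best_tp <- max(tp_kept[cand_cells])
  cand_cells <- cand_cells[tp_kept[cand_cells] == best_tp]
  n_ties <- length(cand_cells)
  ai <- arrayInd(cand_cells, dims)
  # most permissive = smallest index, lexicographic in parameter order
  o <- do.call(order, as.data.frame(ai))
  sel <- ai[o[1], ]

  thresholds <- list()
  for (j in seq_along(cand_t)) {
    t_prime <- cand_t[[j]][sel[j]]
    thr <- if (pars$direction[j] == "min") t_prime else -t_prime
    thresholds[[paste0(pars$names[j],
                       ifelse(pars$direction[j] == "min", "_min",
                              "_max"))]] <- thr
  }
  stringency <- c("0.99" = "low", "0.95" = "medium",
                  "0.9" = "high")[as.character(target_retention)]
  spec <- filter_spec(variant_class, thresholds,
                      stringency = stringency %||% NA_character_,
                      target_retention = target_retention)
  train_retention <- best_tp / nrow(tp)
  stopifnot(train_retention >= target_retention - 1e-9)
  structure(
    list(
      spec = spec,
      train_retention = train_retention,
      train_fp_removal = best_removed / nrow(fp),
      n_tp = nrow(tp),
      n_fp = nrow(fp),
      n_dropped_incomplete = n_dropped,
      grid_sizes = dims,
      n_ties = n_ties
    ),
    class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf(
    "Tuned %s filter (target retention %.2f): TP retained %.4f, FP removed %.4f\n",
    x$spec$variant_class, x$spec$target_retention, x$train_retention,
    x$train_fp_removal))
  print(x$spec)
  invisible(x)
}

#' Advisory robustness flags for indel calls
#'
#' Flags indels whose structure marks them as likely erroneous without
#' removing them: `multiallelic_suspect` (3 or more alternate alleles in
#' the originating record), `long_indel_suspect` (indel length above 100
#' bp) and `homopolymer_context` (HRUN of 5 or more). Missing inputs
#' yield `FALSE`.
#'
#' @param calls Normalized call tibble with `n_original_alts`,
#'   `indel_length` and `hrun` columns.
#' @return `calls` with the three logical flag columns appended.
#' @export
flag_suspect_indels <- function(calls) {
  noa <- calls[["n_original_alts"]] %||% rep(NA_integer_, nrow(calls))
  il <- calls[["indel_length"]] %||% abs(nchar(calls$ref) - nchar(calls$alt))
  hr <- calls[["hrun"]] %||% rep(NA_real_, nrow(calls))
  calls$multiallelic_suspect <- !is.na(noa) & noa >= 3L
  calls$long_indel_suspect <- !is.na(il) & il > 100L
  calls$homopolymer_context <- !is.na(hr) & hr >= 5
  calls
}

#' Per-parameter distribution summaries by truth label
#'
#' For each of the 11 caller parameters (AO, DP, FAO, FDP, FXX, GQ, HRUN,
#' QD, QUAL, STB, STBP) and each label, reports quantiles and a binned
#' histogram. A parameter missing on more than half the calls is marked
#' unavailable.
#'
#' @param calls Labelled call tibble (`label` column) with the parameters
#'   in lower case.
#' @param probs Quantile probabilities for the summary.
#' @param bins Histogram bin count.
#' @return List with `summary` and `histograms` tibbles.
#' @export
summarize_parameters <- function(calls,
                                 probs = c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1),
                                 bins = 20) {
  stopifnot(!is.null(calls[["label"]]))
  summ <- list()
  hists <- list()
  for (p in TVC_PARAMETERS) {
    x_all <- calls[[tolower(p)]]
    if (is.null(x_all)) x_all <- rep(NA_real_, nrow(calls))
    available <- mean(is.na(x_all)) <= 0.5
    rng <- if (all(is.na(x_all))) c(0, 1) else
      range(x_all, na.rm = TRUE, finite = TRUE)
    if (!available || !all(is.finite(rng))) rng <- c(0, 1)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    for (lab in unique(calls$label)) {
      x <- x_all[calls$label == lab]
      qs <- if (available && any(!is.na(x))) {
        quantile(x, probs = probs, type = 8, na.rm = TRUE, names = FALSE)
      } else {
        rep(NA_real_, length(probs))
      }
      summ[[length(summ) + 1L]] <- tibble(
        parameter = p, label = lab, available = available,
        n = sum(!is.na(x)), n_missing = sum(is.na(x)),
        prob = probs, quantile = qs)
      if (available && any(!is.na(x))) {
        xh <- pmin(pmax(x[!is.na(x)], rng[1]), rng[2])
        cnt <- hist(xh, breaks = brk, plot = FALSE)$counts
        hists[[length(hists) + 1L]] <- tibble(
          parameter = p, label = lab,
          bin_mid = (head(brk, -1) + tail(brk, -1)) / 2,
          count = cnt)
      }
    }
  }
  list(summary = bind_rows(summ), histograms = bind_rows(hists))
}

#' Shipped filter-threshold presets
#'
#' Reads the plain-text preset configuration (key = value lines,
#' `<class>.<stringency>.<threshold>`) and returns named
#' [filter_spec()]s. The bundled file carries the low/medium/high
#' stringency presets for SNPs and indels targeting 99/95/90 % TP
#' retention.
#'
#' @param path Preset file; defaults to the configuration shipped with
#'   the package.
#' @return Named list of filter specs (e.g. `snp_low`, `indel_high`).
#' @export
filter_presets <- function(path = system.file("extdata",
                                              "filter_presets.cfg",
                                              package = "ampliqc")) {
  if (!nzchar(path) || !file.exists(path)) stop("preset file not found")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed preset line: ", lines[which(bad)[1]])
  keys <- strsplit(trimws(vapply(kv, `[`, "", 1)), ".", fixed = TRUE)
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  stopifnot(all(lengths(keys) == 3), !anyNA(vals))
  df <- tibble(
    class = vapply(keys, `[`, "", 1),
    stringency = vapply(keys, `[`, "", 2),
    field = vapply(keys, `[`, "", 3),
    value = vals)
  out <- list()
  for (grp in split(df, paste(df$class, df$stringency, sep = "_"))) {
    cls <- if (grp$class[1] == "snp") "SNP" else "indel"
    thr <- setNames(as.list(grp$value[grp$field != "target_retention"]),
                    grp$field[grp$field != "target_retention"])
    tr <- grp$value[grp$field == "target_retention"]
    out[[paste(grp$class[1], grp$stringency[1], sep = "_")]] <-
      filter_spec(cls, thr, stringency = grp$stringency[1],
                  target_retention = if (length(tr)) tr else NA_real_)
  }
  out[order(names(out))]
}
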