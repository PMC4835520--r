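# Per-sample call-set construction. True positives are the truth minus a
# per-class false-negative draw placed preferentially (to the configured
# fraction) at sites the sample covers with fewer than 10 reads. False
# positives mix sample-specific variants with draws from a cohort-wide
# recurrent pool; the split is solved so the expected fraction of
# distinct cohort FPs observed in exactly one sample equals the
# configured uniqueness. Annotations come from class-conditional
# distributions; a configured fraction of FP indel records is emitted
# multiallelic (>= 3 alternate alleles).

# internal: solve the per-sample unique-FP share f so that the expected
# fraction of distinct FPs seen in exactly one of S samples equals u,
# given pool-inclusion probability q.
solve_unique_share <- function(u, q, S) {
  if (S <= 1) return(1)
  g <- function(f) {
    P <- (1 - f) / q              # pool size per unit of per-sample FP count
    uni <- S * f + P * S * q * (1 - q)^(S - 1)
    tot <- S * f + P * (1 - (1 - q)^S)
    uni / tot - u
  }
  if (g(1) < 0) return(1)
  uniroot(g, c(1e-9, 1), tol = 1e-9)$root
}

# internal: sample the caller annotation block for n calls
sample_annotations <- function(n, label, vclass, ann) {
  if (n == 0) {
    return(tibble(ao = numeric(), dp = numeric(), fao = numeric(),
                  fdp = numeric(), fxx = numeric(), gq = numeric(),
                  hrun = numeric(), qd = numeric(), qual = numeric(),
                  stb = numeric(), stbp = numeric()))
  }
  p <- ann[[tolower(label)]]
  if (label == "TP") {
    fdp <- pmax(10, round(rlnorm(n, p$fdp_meanlog, p$fdp_sdlog)))
    af <- rbeta(n, p$af_shape1, p$af_shape2)
    fao <- pmax(1, rbinom(n, fdp, af))
    hrun <- if (vclass == "SNP") rpois(n, p$hrun_lambda_snp) else
      rpois(n, p$hrun_lambda_indel)
  } else {
    fdp <- pmax(4, round(rlnorm(n, p$fdp_meanlog, p$fdp_sdlog)))
    fao <- pmax(1, round(rlnorm(n, p$fao_meanlog, p$fao_sdlog)))
    hrun <- if (vclass == "SNP") rpois(n, p$hrun_lambda_snp) else
      p$hrun_offset_indel + rpois(n, p$hrun_lambda_indel)
  }
  qual <- rlnorm(n, p$qual_meanlog, p$qual_sdlog)
  gq <- pmin(99, pmax(1, round(rlnorm(n, p$gq_meanlog, p$gq_sdlog))))
  dp <- round(fdp * runif(n, 1.0, 1.15))
  ao <- pmin(dp, round(fao * runif(n, 1.0, 1.1)))
  tibble(
    ao = ao, dp = dp, fao = fao, fdp = fdp,
    fxx = rbeta(n, p$fxx_shape1, p$fxx_shape2),
    gq = gq, hrun = hrun,
    qd = qual / pmax(1, dp), qual = qual,
    stb = 0.5 + 0.5 * rbeta(n, p$stb_shape1, p$stb_shape2),
    stbp = runif(n, p$stbp_min, p$stbp_max)
  )
}

# internal: construct FP variant definitions (alleles and multiallelic
# structure) at grid slots. Multiallelic records get three insertion
# alts of increasing length, the typical flow-space homopolymer error
# mode. Returns a tibble with one row per record; `alt` comma-joined.
fp_variant_defs <- function(cfg, seqstr, slots, n_snp, n_indel) {
  defs <- list()
  if (n_snp > 0) {
    s <- alleles_at_slots(cfg, seqstr, slots[seq_len(n_snp)], "SNP")
    s$class <- "SNP"
    s$n_alts <- 1L
    defs[[1]] <- s
  }
  if (n_indel > 0) {
    sl <- slots[n_snp + seq_len(n_indel)]
    ind <- alleles_at_slots(cfg, seqstr, sl, "indel")
    ind$class <- "indel"
    multi <- runif(n_indel) < cfg$multiallelic_fp_indel_fraction
    if (any(multi)) {
      pos <- ind$pos[multi]
      anchor <- substring(seqstr, pos, pos)
      ext <- vapply(seq_along(pos), function(i) {
        b <- sample(BASES, 1)
        paste(paste0(anchor[i], strrep(b, 1:3)), collapse = ",")
      }, "")
      ind$ref[multi] <- anchor
      ind$alt[multi] <- ext
    }
    ind$n_alts <- ifelse(multi, 3L, 1L)
    defs[[length(defs) + 1]] <- ind
  }
  bind_rows(defs)
}

# internal: cohort-level FP structure: the recurrent pool and per-sample
# unique-slot chunks, all derived deterministically from the master seed.
make_fp_pool <- function(cfg, truth) {
  seqstr <- as.character(truth$reference$seq[[1]])
  q <- cfg$fp_recurrent_inclusion
  f <- solve_unique_share(cfg$fp_unique_fraction, q, cfg$n_samples)
  pool_n_snp <- round((1 - f) * cfg$fp_per_sample_snp / q)
  pool_n_indel <- round((1 - f) * cfg$fp_per_sample_indel / q)
  uniq_snp <- round(f * cfg$fp_per_sample_snp)
  uniq_indel <- round(f * cfg$fp_per_sample_indel)

  slots <- truth$spare_slots
  need_pool <- pool_n_snp + pool_n_indel
  need_per_sample <- uniq_snp + uniq_indel
  # head room: unique-FP construction drops variants whose left-aligned
  # key collides with truth or pool, so chunks carry spare slots
  chunk <- ceiling(need_per_sample * 1.3) + 8L
  if (need_pool + cfg$n_samples * chunk > length(slots)) {
    stop("not enough spare candidate positions for the configured FP counts")
  }
  pool <- withr::with_seed(derive_seed(cfg$seed, 41L), {
    defs <- fp_variant_defs(cfg, seqstr, slots[seq_len(max(need_pool, 0))],
                            pool_n_snp, pool_n_indel)
    defs
  })
  pool_keys <- if (nrow(pool) > 0) {
    split_keys <- normalize_variants(pool, setNames(seqstr, cfg$chrom))
    variant_key(split_keys)
  } else {
    character()
  }
  chunks <- lapply(seq_len(cfg$n_samples), function(s) {
    slots[need_pool + (s - 1L) * chunk + seq_len(chunk)]
  })
  list(pool = pool, pool_keys = pool_keys, chunks = chunks,
       unique_share = f, q = q,
       uniq_snp = uniq_snp, uniq_indel = uniq_indel)
}

#' Generate one sample's annotated call set
#'
#' @param cfg A [sim_config()].
#' @param truth A `truth_set` from [make_truth_variants()].
#' @param depth The sample's depth (result of [make_depth_and_reads()] or
#'   a depth-track tibble).
#' @param sample_id Integer sample index in `1:n_samples`.
#' @param seed Optional seed override; defaults to a stream derived from
#'   the master seed and `sample_id`.
#' @param fp_pool Optional cohort FP structure (built deterministically
#'   from the config when omitted, so standalone calls reproduce the
#'   cohort's pool).
#' @param path Optional VCF output path.
#' @return List with `calls` (record tibble as emitted to VCF, one row
#'   per VCF line), `labels` (normalized per-allele label table with
#'   `label` in TP/FP/FN), `sample_id` and `path`.
#' @export
make_callset <- function(cfg, truth, depth, sample_id, seed = NULL,
                         fp_pool = NULL, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "truth_set"))
  sample_id <- as.integer(sample_id)
  if (sample_id < 1L || sample_id > cfg$n_samples) {
    stop("sample_id must lie in 1:n_samples (got ", sample_id, ")")
  }
  if (is.list(depth) && !is.data.frame(depth)) depth <- depth$depth
  seed <- seed %||% derive_seed(cfg$seed, 50L, sample_id)
  seqstr <- as.character(truth$reference$seq[[1]])
  refvec <- setNames(seqstr, cfg$chrom)
  if (is.null(fp_pool)) fp_pool <- make_fp_pool(cfg, truth)

  tv <- truth$variants
  tv$site_depth <- depth_at(depth, tv$chrom, tv$pos)
  tv$site_depth[is.na(tv$site_depth)] <- 0

  pick_fn <- function(sub, rate) {
    n_fn <- round(rate * nrow(sub))
    if (n_fn == 0) return(integer())
    low <- which(sub$site_depth < 10)
    n_low <- min(round(cfg$low_depth_fn_fraction * n_fn), length(low))
    idx_low <- low[sample.int(length(low), n_low)]
    rest <- setdiff(seq_len(nrow(sub)), idx_low)
    c(idx_low, rest[sample.int(length(rest), n_fn - n_low)])
  }

  out <- withr::with_seed(seed, {
    is_snp <- tv$variant_class == "SNP"
    fn_idx_snp <- pick_fn(tv[is_snp, ], cfg$fn_rate_snp)
    fn_idx_indel <- pick_fn(tv[!is_snp, ], cfg$fn_rate_indel)
    fn <- bind_rows(tv[is_snp, ][fn_idx_snp, ],
                    tv[!is_snp, ][fn_idx_indel, ])
    fn_keys <- variant_key(fn)
    tp <- tv[!(variant_key(tv) %in% fn_keys), ]

    ann_tp_snp <- sample_annotations(sum(tp$variant_class == "SNP"),
                                     "TP", "SNP", cfg$annotation)
    ann_tp_ind <- sample_annotations(sum(tp$variant_class != "SNP"),
                                     "TP", "indel", cfg$annotation)
    tp_rec <- bind_rows(
      dplyr::bind_cols(tp[tp$variant_class == "SNP",
                          c("chrom", "pos", "ref", "alt")], ann_tp_snp),
      dplyr::bind_cols(tp[tp$variant_class != "SNP",
                          c("chrom", "pos", "ref", "alt")], ann_tp_ind))
    tp_rec$n_original_alts <- 1L
    tp_rec$ao <- as.character(tp_rec$ao)
    tp_rec$fao <- as.character(tp_rec$fao)

    # recurrent pool draws for this sample
    pool <- fp_pool$pool
    take_pool <- if (nrow(pool) > 0) {
      runif(nrow(pool)) < fp_pool$q
    } else {
      logical()
    }
    pool_rec <- pool[take_pool, ]

    # sample-specific FPs from this sample's slot chunk, dropping any
    # whose normalized keys collide with truth or pool
    slots <- fp_pool$chunks[[sample_id]]
    n_us <- fp_pool$uniq_snp
    n_ui <- fp_pool$uniq_indel
    uniq <- fp_variant_defs(cfg, seqstr, slots,
                            min(n_us, length(slots)),
                            min(n_ui, max(0L, length(slots) - n_us)))
    if (nrow(uniq) > 0) {
      uniq$.rid <- seq_len(nrow(uniq))
      un <- normalize_variants(
        uniq[c("chrom", "pos", "ref", "alt", ".rid")], refvec)
      keys <- variant_key(un)
      taboo <- c(variant_key(truth$variants), fp_pool$pool_keys)
      bad_rid <- unique(un$.rid[keys %in% taboo | duplicated(keys)])
      uniq <- uniq[!(uniq$.rid %in% bad_rid), ]
      uniq$.rid <- NULL
    }

    fp_rec <- bind_rows(pool_rec, uniq)
    if (nrow(fp_rec) > 0) {
      ann_fp <- bind_rows(
        sample_annotations(sum(fp_rec$class == "SNP"), "FP", "SNP",
                           cfg$annotation),
        sample_annotations(sum(fp_rec$class == "indel"), "FP", "indel",
                           cfg$annotation))
      fp_rec <- dplyr::bind_cols(
        bind_rows(fp_rec[fp_rec$class == "SNP", ],
                  fp_rec[fp_rec$class == "indel", ])[
                    c("chrom", "pos", "ref", "alt", "n_alts")], ann_fp)
      # per-alt annotation strings for multiallelic records
      fp_rec$ao <- as.character(fp_rec$ao)
      fp_rec$fao <- as.character(fp_rec$fao)
      multi <- fp_rec$n_alts > 1L
      if (any(multi)) {
        split_counts <- function(total, k) {
          c0 <- rep(floor(total / k), k)
          extra <- total - sum(c0)
          if (extra > 0) c0[seq_len(extra)] <- c0[seq_len(extra)] + 1L
          paste(c0, collapse = ",")
        }
        for (i in which(multi)) {
          fp_rec$ao[i] <- split_counts(
            as.integer(fp_rec$ao[i]) + 2L, fp_rec$n_alts[i])
          fp_rec$fao[i] <- split_counts(
            as.integer(fp_rec$fao[i]) + 2L, fp_rec$n_alts[i])
        }
      }
      fp_rec$n_original_alts <- fp_rec$n_alts
      fp_rec[["n_alts"]] <- NULL
    }

    if (!is.null(fp_rec[["class"]])) fp_rec[["class"]] <- NULL
    if (!is.null(fp_rec[["n_alts"]])) fp_rec[["n_alts"]] <- NULL
    calls <- bind_rows(tp_rec, fp_rec) %>%
      arrange(.data$chrom, .data$pos, .data$alt)
    calls$filter <- "."
    calls$gt <- "0/1"

    tp_lab <- mutate(tp[c("chrom", "pos", "ref", "alt")],
                     label = "TP", n_original_alts = 1L)
    fn_lab <- mutate(fn[c("chrom", "pos", "ref", "alt")],
                     label = "FN", n_original_alts = 1L)
    fp_lab <- if (nrow(fp_rec) > 0) {
      fl <- normalize_variants(
        fp_rec[c("chrom", "pos", "ref", "alt", "n_original_alts")], refvec)
      fl$label <- "FP"
      fl[c("chrom", "pos", "ref", "alt", "label", "n_original_alts")]
    } else {
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), label = character(),
             n_original_alts = integer())
    }
    labels <- bind_rows(tp_lab[c("chrom", "pos", "ref", "alt", "label",
                                 "n_original_alts")],
                        fn_lab[c("chrom", "pos", "ref", "alt", "label",
                                 "n_original_alts")],
                        fp_lab) %>%
      arrange(.data$label, .data$chrom, .data$pos, .data$alt)
    list(calls = calls, labels = labels)
  })

  if (!is.null(path)) {
    write_vcf(out$calls, path,
              contigs = setNames(cfg$genome_length, cfg$chrom),
              sample_id = paste0("S", sample_id))
  }
  list(calls = out$calls, labels = out$labels, sample_id = sample_id,
       path = path)
}
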