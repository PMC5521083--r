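#' Down-sample read pairs
#'
#' Uniform random subsample of read pairs (mates kept together), without
#' replacement, deterministic under `seed`.
#'
#' @param records read data.table (pre-deduplication; both mates per qname).
#' @param target_pairs number of pairs to keep.
#' @param seed integer seed.
#' @return read data.table with `target_pairs` pairs.
#' @export
downsample_reads <- function(records, target_pairs, seed = 1L) {
  r <- as.data.table(records)
  qn <- unique(r$qname)
  if (target_pairs > length(qn)) {
    stop_bg("target_pairs (%d) exceeds available pairs (%d)",
            target_pairs, length(qn))
  }
  if (target_pairs == length(qn)) return(r)
  keep <- withr::with_seed(derive_seed(seed, 6L), sample(qn, target_pairs))
  out <- r[qname %in% keep]
  setorder(out, pos, qname, mate)
  out[]
}

#' False-positive fraction as a function of unique coverage depth
#'
#' Emulates in-silico down-sampling of a sequencing library: for each target
#' pair count, a random subsample of read pairs is drawn from the
#' pre-deduplication read set, de-duplicated, piled up, and the observed
#' frequency of every background-eligible allele (taken from the full-depth
#' background call) is recomputed. The curve reports, per frequency
#' threshold and per realized unique-depth bin, the fraction of background
#' site-alleles whose observed frequency exceeds the threshold -- the false
#' positives a naive caller at that threshold would emit.
#'
#' The pair-level depth gate is deliberately not re-applied per subsample:
#' the point of the curve is the behaviour of frequencies at depths below
#' the standard gate.
#'
#' @param records pre-deduplication read data.table of the query sample.
#' @param table a `bg_background` table from the full-depth call.
#' @param ref a `ref_bundle`.
#' @param target_pairs integer vector of subsample sizes (pairs).
#' @param thresholds a [filter_thresholds()] (supplies `qmin` and the
#'   dedup/clipping rules).
#' @param freq_thresholds frequency thresholds (default 0.5%, 1%, 2%).
#' @param depth_bins bin edges for realized unique depth (default
#'   `c(0, 500, 1000, Inf)`, mirroring <500, 500-1000, >1000).
#' @param seed integer seed.
#' @return object of class `bg_fp_curve`: data.table `target_pairs`,
#'   `unique_depth_mean`, `threshold`, `depth_bin`, `n_alleles`,
#'   `n_exceed`, `fraction`.
#' @export
fp_curve <- function(records, table, ref, target_pairs,
                     thresholds = filter_thresholds(),
                     freq_thresholds = c(0.005, 0.01, 0.02),
                     depth_bins = c(0, 500, 1000, Inf),
                     seed = 1L) {
  stopifnot(inherits(table, "bg_background"))
  bgset <- table[category == "background", .(pos, alt)]
  if (nrow(bgset) == 0L) stop_bg("no background alleles in table")
  res <- vector("list", length(target_pairs))
  for (i in seq_along(target_pairs)) {
    sub <- downsample_reads(records, target_pairs[i], seed = derive_seed(seed, i))
    sub <- filter_reads(sub, thresholds)
    pu <- build_pileup(sub, ref, thresholds)
    cm <- pu$counts
    x <- merge(bgset, cm[, .(pos, A, C, G, T, depth)], by = "pos", all.x = TRUE)
    for (b in BASES) x[alt == b & !is.na(depth), count := get(b)]
    x[is.na(depth), `:=`(depth = 0L, count = 0L)]
    x[is.na(count), count := 0L]
    x[, vaf := fifelse(depth > 0L, count / depth, 0)]
    x[, depth_bin := cut(depth, breaks = depth_bins, include.lowest = TRUE, right = FALSE)]
    per <- rbindlist(lapply(freq_thresholds, function(t) {
      x[, .(threshold = t, n_alleles = .N, n_exceed = sum(vaf > t)),
        by = depth_bin]
    }))
    per[, `:=`(target_pairs = target_pairs[i],
               unique_depth_mean = mean(x$depth))]
    res[[i]] <- per
  }
  out <- rbindlist(res)
  out[, fraction := fifelse(n_alleles > 0L, n_exceed / n_alleles, NA_real_)]
  setcolorder(out, c("target_pairs", "unique_depth_mean", "threshold",
                     "depth_bin", "n_alleles", "n_exceed", "fraction"))
  setattr(out, "class", c("bg_fp_curve", class(out)))
  out[]
}

#' Exceedance fractions under a site-specific error rate model
#'
#' Model-level twin of the down-sampling experiment: per-site error rates
#' are drawn from a Gamma distribution (overdispersed across sites, the
#' empirical hallmark of background noise), allele counts are Binomial at a
#' fixed depth, and the fraction of site-alleles whose observed frequency
#' exceeds a threshold is returned. Useful for studying how a constant
#' error-rate model converts depth into false-positive risk without
#' simulating reads.
#'
#' All depths are evaluated on the same drawn site panel (as in a real
#' down-sampling experiment, where the sites are fixed and only the depth
#' changes), so depth comparisons are paired.
#'
#' @param n_sites number of site-alleles.
#' @param depths unique coverage depths (scalar or vector).
#' @param mean_rate mean per-site-allele error rate.
#' @param shape Gamma shape parameter (smaller = more overdispersed across
#'   sites).
#' @param threshold observed-frequency threshold.
#' @param seed integer seed.
#' @return named numeric vector: per depth, the fraction of site-alleles
#'   with observed frequency > threshold.
#' @export
fp_exceedance_model <- function(n_sites, depths, mean_rate = 7e-5,
                                shape = 0.08, threshold = 0.01, seed = 1L) {
  withr::with_seed(derive_seed(seed, 7L), {
    lam <- stats::rgamma(n_sites, shape = shape, rate = shape / mean_rate)
    lam <- pmin(lam, 1)
    out <- vapply(depths, function(d) {
      k <- stats::rbinom(n_sites, size = d, prob = lam)
      mean(k / d > threshold)
    }, numeric(1))
    names(out) <- as.character(depths)
    out
  })
}
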