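#' Filtering thresholds for background-error analysis
#'
#' The quality and depth gates applied throughout the pipeline: base quality
#' >= 30, pair depth >= 500x, germline cut at 5% allele frequency, tumor
#' (FNA) gates at 250x depth and 2.5% frequency.
#'
#' @param qmin minimum Phred base quality counted in pileups.
#' @param min_depth_pair minimum quality-filtered depth required in each of
#'   the paired (plasma, PBL) samples.
#' @param germline_af allele frequency at or above which an allele is called
#'   germline in either paired sample.
#' @param fna_min_depth positions with lower FNA depth are excluded.
#' @param fna_max_af alleles above this FNA frequency are excluded as
#'   candidate somatic variants.
#' @param exclude_clipped drop read pairs with any clipped alignment.
#' @param dedup remove PCR duplicate pairs.
#' @return object of class `bg_thresholds`.
#' @export
filter_thresholds <- function(qmin = 30L, min_depth_pair = 500L,
                              germline_af = 0.05, fna_min_depth = 250L,
                              fna_max_af = 0.025, exclude_clipped = TRUE,
                              dedup = TRUE) {
  stopifnot(germline_af >= 0, germline_af <= 1, fna_max_af >= 0, fna_max_af <= 1,
            min_depth_pair >= 0, fna_min_depth >= 0, qmin >= 0)
  structure(list(qmin = as.integer(qmin), min_depth_pair = min_depth_pair,
                 germline_af = germline_af, fna_min_depth = fna_min_depth,
                 fna_max_af = fna_max_af, exclude_clipped = exclude_clipped,
                 dedup = dedup),
            class = "bg_thresholds")
}

#' Filter aligned read pairs
#'
#' Removes unmapped records, non-proper pairs, clipped pairs (when
#' `exclude_clipped`) and PCR duplicates. Duplicates are defined by the
#' fragment key (start, end, orientation of read 1); within a duplicate set
#' the pair with the highest summed base quality survives, ties broken by
#' coordinate order. Counts removed per reason are attached as the
#' `"filter_stats"` attribute.
#'
#' @param records read data.table.
#' @param thresholds a [filter_thresholds()] object.
#' @return filtered read data.table.
#' @export
filter_reads <- function(records, thresholds = filter_thresholds()) {
  r <- as.data.table(records)
  n0 <- nrow(r)
  cnt <- r[, .N, by = qname]
  if (any(cnt$N != 2L)) {
    stop_bg("records without complete mate information: %d read name(s) do not form a pair",
            sum(cnt$N != 2L))
  }
  stats <- c(unmapped = 0L, not_proper = 0L, clipped = 0L, duplicate = 0L)

  bad_flag <- bitwAnd(r$flag, 4L) > 0L | bitwAnd(r$flag, 8L) > 0L
  bad_q <- unique(r$qname[bad_flag])
  stats["unmapped"] <- 2L * length(bad_q)
  r <- r[!qname %in% bad_q]

  notp <- bitwAnd(r$flag, 2L) == 0L
  bad_q <- unique(r$qname[notp])
  stats["not_proper"] <- 2L * length(bad_q)
  r <- r[!qname %in% bad_q]

  if (isTRUE(thresholds$exclude_clipped)) {
    clip <- has_clipping(r$cigar)
    bad_q <- unique(r$qname[clip])
    stats["clipped"] <- 2L * length(bad_q)
    r <- r[!qname %in% bad_q]
  }

  if (isTRUE(thresholds$dedup) && nrow(r) > 0L) {
    lens <- nchar(r$qual)
    csum <- cumsum(as.numeric(charToRaw(paste(r$qual, collapse = ""))))
    ends <- cumsum(lens)
    sumq <- csum[ends] - c(0, csum[ends])[seq_along(ends)] - 33 * lens
    rq <- data.table(qname = r$qname, pos = r$pos, end = r$pos + r$len,
                     mate = r$mate, strand = r$strand, sumq = sumq)
    pairs <- rq[, .(fstart = min(pos), fend = max(end),
                    orient = strand[mate == 1L][1], sumq = sum(sumq)), by = qname]
    setorder(pairs, fstart, fend, orient, -sumq, qname)
    keep <- pairs[!duplicated(pairs, by = c("fstart", "fend", "orient"))]$qname
    stats["duplicate"] <- 2L * (nrow(pairs) - length(keep))
    r <- r[qname %in% keep]
  }
  setorder(r, pos, qname, mate)
  setattr(r, "filter_stats", stats)
  r[]
}

#' Build a quality-filtered per-site allele count table
#'
#' Expands filtered reads into per-base calls over target positions, drops
#' bases below `qmin`, and tabulates A/C/G/T counts per position. Bases
#' overlapping within a mate pair are counted twice (per-base convention;
#' the overlap module analyzes mate concordance explicitly). Non-reference
#' high-quality calls are retained with per-read detail (mate, alignment
#' strand, distance of the base from the read's 5' end) for downstream use.
#'
#' @param records filtered read data.table.
#' @param ref a `ref_bundle` (supplies reference bases and default targets).
#' @param thresholds a [filter_thresholds()].
#' @param targets optional target intervals (data.table `start`, `end`,
#'   0-based half-open); defaults to `ref$targets`.
#' @return object of class `bg_pileup`: list with `counts` (data.table
#'   `pos`, `ref`, `A`, `C`, `G`, `T`, `depth` -- `depth` is the
#'   quality-filtered depth), `alt_detail`, `qmin`.
#' @export
build_pileup <- function(records, ref, thresholds = filter_thresholds(),
                         targets = NULL) {
  r <- as.data.table(records)
  if (nrow(r) > 0L && !all(r$rname == ref$name)) {
    stop_bg("contig mismatch: records on '%s' vs reference '%s'",
            paste(setdiff(unique(r$rname), ref$name), collapse = ","), ref$name)
  }
  tg <- if (is.null(targets)) ref$targets else as.data.table(targets)
  L <- nchar(ref$sequence)
  tmask <- logical(L)
  for (i in seq_len(nrow(tg))) tmask[(tg$start[i] + 1L):tg$end[i]] <- TRUE
  qmin <- thresholds$qmin
  refcode <- base_codes(ref$bytes)

  if (nrow(r) == 0L) {
    counts <- data.table(pos = integer(), ref = character(), A = integer(),
                         C = integer(), G = integer(), T = integer(), depth = integer())
    return(structure(list(counts = counts, alt_detail = empty_alt_detail(), qmin = qmin),
                     class = "bg_pileup"))
  }

  nr <- nrow(r)
  idx <- sequence(r$len, from = r$pos + 1L)          # 1-based reference index
  bcode <- base_codes(charToRaw(paste(r$seq, collapse = "")))
  qv <- as.integer(charToRaw(paste(r$qual, collapse = ""))) - 33L
  on_t <- tmask[idx]

  raw_cov <- tabulate(idx[on_t], nbins = L)
  hq <- on_t & qv >= qmin & bcode > 0L
  cnt <- tabulate((idx[hq] - 1L) * 4L + bcode[hq], nbins = 4L * L)
  covered <- which(raw_cov > 0L)
  counts <- data.table(
    pos = covered - 1L,
    ref = rawToChar(ref$bytes[covered], multiple = TRUE),
    A = cnt[(covered - 1L) * 4L + 1L],
    C = cnt[(covered - 1L) * 4L + 2L],
    G = cnt[(covered - 1L) * 4L + 3L],
    T = cnt[(covered - 1L) * 4L + 4L]
  )
  counts[, depth := A + C + G + T]

  # per-read detail for high-quality non-reference calls
  alt_i <- which(hq & bcode != refcode[idx])
  if (length(alt_i) > 0L) {
    rrow <- findInterval(alt_i - 1L, cumsum(r$len)) + 1L
    off0 <- c(0L, cumsum(r$len))[rrow]
    within <- alt_i - off0                            # 1..len along the alignment
    read_pos <- fifelse(r$strand[rrow] == "+", within, r$len[rrow] - within + 1L)
    alt_detail <- data.table(
      pos = idx[alt_i] - 1L,
      ref = BASES[refcode[idx[alt_i]]],
      alt = BASES[bcode[alt_i]],
      qname = r$qname[rrow],
      mate = r$mate[rrow],
      strand = r$strand[rrow],
      read_pos = as.integer(read_pos),
      qual = qv[alt_i]
    )
  } else {
    alt_detail <- empty_alt_detail()
  }
  structure(list(counts = counts, alt_detail = alt_detail, qmin = qmin),
            class = "bg_pileup")
}

empty_alt_detail <- function() {
  data.table(pos = integer(), ref = character(), alt = character(),
             qname = character(), mate = integer(), strand = character(),
             read_pos = integer(), qual = integer())
}

#' @export
print.bg_pileup <- function(x, ...) {
  cat(sprintf("<bg_pileup> %d positions, qmin=%d, total depth %.3g, %d high-quality non-reference calls\n",
              nrow(x$counts), x$qmin, sum(as.numeric(x$counts$depth)), nrow(x$alt_detail)))
  invisible(x)
}

#' Base quality distributions for total and non-reference bases
#'
#' Tabulates Phred quality counts for all aligned bases and for
#' non-reference (background-candidate) bases, optionally stratified by
#' distance from the read 5' end and/or by called base identity. No quality
#' gate is applied here: the biphasic shape of the raw distribution is the
#' point of this view.
#'
#' @param records read data.table.
#' @param ref a `ref_bundle`.
#' @param targets optional target intervals; `NULL` uses the whole reference.
#' @param by_position stratify by read position (distance from the 5' end).
#' @param by_base stratify by called base.
#' @return data.table with `category` (`"total"` or `"nonref"`), `qual`,
#'   optional `read_pos` / `base`, and `count`.
#' @export
quality_histogram <- function(records, ref, targets = NULL,
                              by_position = FALSE, by_base = FALSE) {
  r <- as.data.table(records)
  L <- nchar(ref$sequence)
  refcode <- base_codes(ref$bytes)
  idx <- sequence(r$len, from = r$pos + 1L)
  bcode <- base_codes(charToRaw(paste(r$seq, collapse = "")))
  qv <- as.integer(charToRaw(paste(r$qual, collapse = ""))) - 33L
  keep <- rep.int(TRUE, length(idx))
  if (!is.null(targets)) {
    tg <- as.data.table(targets)
    tmask <- logical(L)
    for (i in seq_len(nrow(tg))) tmask[(tg$start[i] + 1L):tg$end[i]] <- TRUE
    keep <- tmask[idx]
  }
  dt <- data.table(qual = qv[keep],
                   nonref = (bcode != refcode[idx])[keep])
  if (by_position) {
    rrow <- findInterval(which(keep) - 1L, cumsum(r$len)) + 1L
    off0 <- c(0L, cumsum(r$len))[rrow]
    within <- which(keep) - off0
    dt[, read_pos := as.integer(fifelse(r$strand[rrow] == "+", within,
                                        r$len[rrow] - within + 1L))]
  }
  if (by_base) dt[, base := BASES[bcode[keep]]]
  grp <- c(if (by_position) "read_pos", if (by_base) "base", "qual")
  tot <- dt[, .(count = .N), by = grp][, category := "total"]
  bg <- dt[nonref == TRUE, .(count = .N), by = grp][, category := "nonref"]
  out <- rbindlist(list(tot, bg), use.names = TRUE)
  setcolorder(out, c("category", grp, "count"))
  setorder(out, category, qual)
  out[]
}
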