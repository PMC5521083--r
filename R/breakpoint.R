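#' Break-point-anchored sequence windows
#'
#' Collects, for every unclipped read, the 100-base window around the
#' fragment break point at the read's 5' end: positions -50..-1 lie outside
#' the fragment (reference bases), +1..+50 inside (read bases, with bases
#' below `qmin` masked). Position +1 is the first sequenced base; there is
#' no position 0 -- the break point is the bond between -1 and +1.
#'
#' Two orientation conventions are provided. In `fragment` mode (default)
#' windows from reverse-strand reads are reverse-complemented so that +1 is
#' always the first sequenced base and the window reads in sequencing
#' direction -- the natural frame for break-point chemistry. In
#' `plus_strand` mode every window is reported in reference plus-strand
#' direction around the 5'-end bond.
#'
#' @param records filtered, unclipped read data.table.
#' @param ref a `ref_bundle`.
#' @param mode `"fragment"` or `"plus_strand"`.
#' @param qmin quality gate for read bases inside the fragment.
#' @param flank window half-width (default 50).
#' @return object of class `bg_end_windows`: a byte matrix (rows = windows,
#'   columns = positions -flank..-1, +1..+flank) with masked/unavailable
#'   bases as `N`; attributes `mode`, `flank`, `n_excluded` (windows dropped
#'   at reference edges or from clipped reads).
#' @export
end_windows <- function(records, ref, mode = c("fragment", "plus_strand"),
                        qmin = 30L, flank = 50L) {
  mode <- match.arg(mode)
  r <- as.data.table(records)
  n_clip <- sum(has_clipping(r$cigar))
  r <- r[!has_clipping(cigar)]
  L <- nchar(ref$sequence)

  # 5' end bond position b (0-based): bond between b-1 and b for forward
  # reads; for reverse reads the 5' end is the last aligned base, bond
  # between end-1 and end
  fwd <- r$strand == "+"
  b <- fifelse(fwd, r$pos, r$pos + r$len)
  ok <- (b - flank >= 0L) & (b + flank <= L)
  n_edge <- sum(!ok)
  r <- r[ok]; b <- b[ok]; fwd <- fwd[ok]
  n <- nrow(r)
  W <- matrix(charToRaw("N")[1], nrow = n, ncol = 2L * flank)
  if (n > 0L) {
    refb <- ref$bytes
    inlen <- pmin(r$len, flank)
    seq_big <- charToRaw(paste(r$seq, collapse = ""))
    qual_big <- as.integer(charToRaw(paste(r$qual, collapse = ""))) - 33L
    off0 <- c(0L, cumsum(r$len))[seq_len(n)]

    # inside the fragment: read bases in sequencing direction, q-masked
    rows_in <- rep.int(seq_len(n), inlen)
    k_in <- sequence(inlen)                      # 1..inlen = window position +k
    src <- fifelse(fwd[rows_in],
                   off0[rows_in] + k_in,                    # forward: k-th base
                   off0[rows_in] + r$len[rows_in] - k_in + 1L)  # reverse: from 3' of stored seq
    bbyte <- seq_big[src]
    if (mode == "fragment") {
      bbyte[!fwd[rows_in]] <- comp_bytes(bbyte[!fwd[rows_in]])
    }
    bbyte[qual_big[src] < qmin] <- charToRaw("N")[1]
    col_in <- if (mode == "fragment") flank + k_in else
      fifelse(fwd[rows_in], flank + k_in, flank - k_in + 1L)
    W[cbind(rows_in, col_in)] <- bbyte

    # outside the fragment: reference bases
    rows_out <- rep(seq_len(n), each = flank)
    j <- rep.int(seq_len(flank), n)              # 1..flank = window position -j
    rpos <- fifelse(fwd[rows_out], b[rows_out] - j, b[rows_out] + j - 1L)
    obyte <- refb[rpos + 1L]
    if (mode == "fragment") {
      obyte[!fwd[rows_out]] <- comp_bytes(obyte[!fwd[rows_out]])
    }
    col_out <- if (mode == "fragment") flank - j + 1L else
      fifelse(fwd[rows_out], flank - j + 1L, flank + j)
    W[cbind(rows_out, col_out)] <- obyte
  }
  structure(W, mode = mode, flank = flank,
            n_excluded = n_edge + n_clip, class = "bg_end_windows")
}

window_positions <- function(flank) c(-(flank:1), 1:flank)

#' Mononucleotide frequencies around the break point
#'
#' @param windows a `bg_end_windows` object.
#' @return data.table `position` (-flank..-1, +1..+flank), `base`, `freq`
#'   (per-position proportions over counted bases; masked bases excluded).
#' @export
mono_frequencies <- function(windows) {
  stopifnot(inherits(windows, "bg_end_windows"))
  flank <- attr(windows, "flank")
  posv <- window_positions(flank)
  out <- vector("list", ncol(windows))
  for (j in seq_len(ncol(windows))) {
    code <- base_codes(windows[, j])
    tab <- tabulate(code, nbins = 4L)
    tot <- sum(tab)
    out[[j]] <- data.table(position = posv[j], base = BASES,
                           count = tab,
                           freq = if (tot > 0) tab / tot else NA_real_)
  }
  rbindlist(out)
}

#' Dinucleotide frequencies around the break point
#'
#' Distance 0 is the bond-straddling dinucleotide: its first base sits
#' immediately before the 5' end of the read (-1), its second base is the
#' first read base (+1). Positive distances move into the fragment,
#' negative distances away from it.
#'
#' @param windows a `bg_end_windows` object.
#' @return data.table `distance`, `dinuc`, `count`, `freq` (per-distance
#'   proportions).
#' @export
di_frequencies <- function(windows) {
  stopifnot(inherits(windows, "bg_end_windows"))
  flank <- attr(windows, "flank")
  dinucs <- DINUCS
  out <- vector("list", ncol(windows) - 1L)
  for (j in seq_len(ncol(windows) - 1L)) {
    c1 <- base_codes(windows[, j]); c2 <- base_codes(windows[, j + 1L])
    keep <- c1 > 0L & c2 > 0L
    tab <- tabulate((c1[keep] - 1L) * 4L + c2[keep], nbins = 16L)
    tot <- sum(tab)
    out[[j]] <- data.table(distance = j - flank, dinuc = dinucs, count = tab,
                           freq = if (tot > 0) tab / tot else NA_real_)
  }
  rbindlist(out)
}

#' Position-resolved substitution rates along reads
#'
#' Computes, from read-1 records only (the mate whose early cycles carry the
#' highest base qualities), the background substitution rate of each
#' strand-resolved class at read positions 1..`max_pos` (distance from the
#' 5' end, i.e. from the fragment break point), and the fold change of each
#' position against the mean rate over positions 1..`max_pos`.
#'
#' @param records_R1 filtered read data.table restricted to read 1
#'   (rows with `mate != 1` are dropped with a message).
#' @param table a `bg_background` table defining eligible site/alleles.
#' @param ref a `ref_bundle`.
#' @param qmin base quality gate.
#' @param max_pos largest read position analyzed (default 50).
#' @return data.table `class`, `position`, `numerator`, `denominator`,
#'   `rate`, `fc` (fold change; the mean of `fc` over positions with
#'   defined rates is 1 by construction).
#' @export
positional_rates <- function(records_R1, table, ref, qmin = 30L, max_pos = 50L) {
  r <- as.data.table(records_R1)
  if (any(r$mate != 1L)) {
    r <- r[mate == 1L]
  }
  stopifnot(inherits(table, "bg_background"))
  refcode <- base_codes(ref$bytes)
  nr <- nrow(r)
  idx <- sequence(r$len, from = r$pos + 1L)
  bcode <- base_codes(charToRaw(paste(r$seq, collapse = "")))
  qv <- as.integer(charToRaw(paste(r$qual, collapse = ""))) - 33L
  rrow <- rep.int(seq_len(nr), r$len)
  within <- sequence(r$len)
  read_pos <- fifelse(r$strand[rrow] == "+", within, r$len[rrow] - within + 1L)

  keep <- qv >= qmin & read_pos <= max_pos & bcode > 0L
  dt <- data.table(pos = idx[keep] - 1L,
                   rp = as.integer(read_pos[keep]),
                   base = BASES[bcode[keep]],
                   refb = BASES[refcode[idx[keep]]])

  bgset <- table[category == "background", .(pos, alt)]
  # denominators: quality-filtered bases per (eligible site, read position),
  # attributed to each class whose specific allele is eligible at that site
  den_tab <- dt[, .(n = .N), by = .(pos, rp, refb)]
  den_tab <- merge(den_tab, bgset, by = "pos", allow.cartesian = TRUE)
  den <- den_tab[, .(denominator = sum(n)), by = .(refb, alt, rp)]
  # numerators: alt calls matching an eligible background allele
  num <- merge(dt[base != refb], bgset, by.x = c("pos", "base"),
               by.y = c("pos", "alt"))[, .(numerator = .N), by = .(refb, base, rp)]

  grid <- CJ(class = SUB_CLASSES, position = seq_len(max_pos))
  grid[, `:=`(refb = substr(class, 1, 1), alt = substr(class, 3, 3))]
  out <- merge(grid, den, by.x = c("refb", "alt", "position"),
               by.y = c("refb", "alt", "rp"), all.x = TRUE)
  out <- merge(out, num, by.x = c("refb", "alt", "position"),
               by.y = c("refb", "base", "rp"), all.x = TRUE)
  out[is.na(denominator), denominator := 0]
  out[is.na(numerator), numerator := 0]
  out[, rate := fifelse(denominator > 0, numerator / denominator, NA_real_)]
  out[, fc := rate / mean(rate, na.rm = TRUE), by = class]
  out <- out[, .(class, position, numerator, denominator, rate, fc)]
  setorder(out, class, position)
  out[]
}

#' Summary of positional fold changes
#'
#' Quartiles of the fold-change distribution over read positions
#' 1..`max_pos` for each class, with the first- and second-base fold changes
#' reported separately for comparison against the bulk distribution.
#'
#' @param pr output of [positional_rates()].
#' @return data.table `class`, `fc1`, `fc2`, `q1`, `median`, `q3`,
#'   `whisker_lo`, `whisker_hi` (Tukey whiskers at 1.5 IQR).
#' @export
fc_summary <- function(pr) {
  pr[, {
    q <- stats::quantile(fc, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[3] - q[1]
    .(fc1 = fc[position == 1L], fc2 = fc[position == 2L],
      q1 = q[1], median = q[2], q3 = q[3],
      whisker_lo = q[1] - 1.5 * iqr, whisker_hi = q[3] + 1.5 * iqr)
  }, by = class]
}
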