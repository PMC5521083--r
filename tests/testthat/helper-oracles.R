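# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive (per-read loops, plain string ops) and independent of
# the package's vectorized internals.

QCHR <- function(q) intToUtf8(q + 33L)
qs <- function(n, q = 37L) strrep(QCHR(q), n)

# build a read table row-by-row from plain arguments
mk_reads <- function(...) {
  rows <- list(...)
  dt <- data.table::rbindlist(lapply(rows, function(r) {
    len <- nchar(r$seq)
    data.table::data.table(
      qname = r$qname, flag = as.integer(r$flag %||dflt% 99L),
      rname = r$rname %||dflt% "chrS",
      pos = as.integer(r$pos), len = len, strand = r$strand %||dflt% "+",
      mate = as.integer(r$mate %||dflt% 1L),
      cigar = r$cigar %||dflt% paste0(len, "M"),
      seq = r$seq, qual = r$qual %||dflt% qs(len),
      mpos = as.integer(r$mpos %||dflt% r$pos),
      tlen = as.integer(r$tlen %||dflt% len)
    )
  }))
  dt
}
`%||dflt%` <- function(a, b) if (is.null(a)) b else a

# a proper pair with given coordinates; seq defaults to the reference
mk_pair <- function(qname, ref, s1, len1, s2, len2, seq1 = NULL, seq2 = NULL,
                    qual1 = NULL, qual2 = NULL, r1_forward = TRUE) {
  sub <- function(s, l) substr(ref$sequence, s + 1L, s + l)
  f1 <- if (r1_forward) 99L else 83L
  f2 <- if (r1_forward) 147L else 163L
  st1 <- if (r1_forward) "+" else "-"
  st2 <- if (r1_forward) "-" else "+"
  mk_reads(
    list(qname = qname, pos = s1, seq = seq1 %||dflt% sub(s1, len1),
         qual = qual1, flag = f1, strand = st1, mate = 1L, mpos = s2,
         tlen = max(s1 + len1, s2 + len2) - min(s1, s2)),
    list(qname = qname, pos = s2, seq = seq2 %||dflt% sub(s2, len2),
         qual = qual2, flag = f2, strand = st2, mate = 2L, mpos = s1,
         tlen = -(max(s1 + len1, s2 + len2) - min(s1, s2)))
  )
}

toy_ref <- function(seq, targets = NULL) {
  if (is.null(targets)) {
    targets <- data.table::data.table(start = 0L, end = nchar(seq))
  }
  structure(list(name = "chrS", sequence = seq, bytes = charToRaw(seq),
                 targets = data.table::as.data.table(targets)),
            class = "ref_bundle")
}

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# --- naive pileup oracle: parses SAM text with base string ops -------------
naive_pileup_sam <- function(sam_path, refseq, targets, qmin = 30L) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  L <- nchar(refseq)
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  covered <- integer(L)
  in_target <- logical(L)
  for (i in seq_len(nrow(targets))) {
    in_target[(targets$start[i] + 1L):targets$end[i]] <- TRUE
  }
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    pos1 <- as.integer(f[4])
    seq <- f[10]; qual <- f[11]
    for (k in seq_len(nchar(seq))) {
      p <- pos1 + k - 1L           # 1-based reference position
      if (!in_target[p]) next
      covered[p] <- covered[p] + 1L
      q <- utf8ToInt(substr(qual, k, k)) - 33L
      if (q < qmin) next
      b <- substr(seq, k, k)
      counts[p, b] <- counts[p, b] + 1L
    }
  }
  list(counts = counts, covered = covered)
}

# --- naive break-point window oracle (fragment mode) -----------------------
naive_windows <- function(reads, refseq, qmin = 30L, flank = 50L) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  L <- nchar(refseq)
  out <- list()
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (grepl("[SH]", r$cigar)) next
    fwd <- r$strand == "+"
    b <- if (fwd) r$pos else r$pos + r$len
    if (b - flank < 0L || b + flank > L) next
    w <- rep("N", 2L * flank)
    for (j in seq_len(flank)) {       # outside positions -j
      rp <- if (fwd) b - j else b + j - 1L
      base <- substr(refseq, rp + 1L, rp + 1L)
      if (!fwd) base <- comp(base)
      w[flank - j + 1L] <- base
    }
    for (k in seq_len(min(r$len, flank))) {   # inside positions +k
      src <- if (fwd) k else r$len - k + 1L
      q <- utf8ToInt(substr(r$qual, src, src)) - 33L
      base <- substr(r$seq, src, src)
      if (!fwd) base <- comp(base)
      if (q < qmin) base <- "N"
      w[flank + k] <- base
    }
    out[[length(out) + 1L]] <- w
  }
  do.call(rbind, out)
}

naive_mono_tally <- function(wmat) {
  t(apply(wmat, 2, function(col) {
    col <- col[col != "N"]
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    as.integer(tab)
  }))
}

naive_di_tally <- function(wmat) {
  dinucs <- paste0(rep(c("A", "C", "G", "T"), each = 4),
                   rep(c("A", "C", "G", "T"), 4))
  res <- matrix(0L, ncol(wmat) - 1L, 16L, dimnames = list(NULL, dinucs))
  for (j in seq_len(ncol(wmat) - 1L)) {
    d <- paste0(wmat[, j], wmat[, j + 1L])
    d <- d[!grepl("N", d)]
    tab <- table(factor(d, levels = dinucs))
    res[j, ] <- as.integer(tab)
  }
  res
}

# hand-built strand-resolved class-rate table for compare/profile unit tests
mk_rate_table <- function(rates, denom = 1e6) {
  cls <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
           "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")
  stopifnot(length(rates) == 12L)
  dt <- data.table::data.table(
    class = cls, ref = substr(cls, 1, 1), alt = substr(cls, 3, 3),
    numerator = rates * denom, denominator = denom, rate = rates
  )
  data.table::setattr(dt, "class", c("bg_class_rates", class(dt)))
  data.table::setattr(dt, "overall", mean(rates))
  data.table::setattr(dt, "sample", "manual")
  data.table::setattr(dt, "collapsed", FALSE)
  dt
}

# hand-built background table (plasma/pbl) from per-position specs
mk_background <- function(df) {
  dt <- data.table::as.data.table(df)
  data.table::setattr(dt, "class", c("bg_background", class(dt)))
  dt
}
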