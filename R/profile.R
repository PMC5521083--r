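#' Per-class background error rates
#'
#' Computes, for one sample of a background table, the error rate of each of
#' the 12 strand-resolved substitution classes: numerator = quality-filtered
#' background-category alt bases of that class; denominator = quality-filtered
#' bases at positions whose reference is the class's source base and where
#' that specific allele is background-eligible. The overall background allele
#' frequency (total background alt bases over total quality-filtered bases at
#' eligible positions) is attached as the `"overall"` attribute.
#'
#' @param table a `bg_background` table from [call_background()].
#' @param sample which sample's counts to use: `"plasma"`, `"pbl"` or `"fna"`.
#' @return object of class `bg_class_rates`: data.table `class`, `ref`,
#'   `alt`, `numerator`, `denominator`, `rate` (NA when the denominator is
#'   zero), with attributes `overall`, `sample` and `collapsed = FALSE`.
#' @export
class_rates <- function(table, sample = c("plasma", "pbl", "fna")) {
  stopifnot(inherits(table, "bg_background"))
  sample <- match.arg(sample)
  cn <- paste0(sample, "_count"); dn <- paste0(sample, "_depth")
  if (!cn %in% names(table)) stop_bg("no '%s' counts in background table", sample)
  bg <- table[category == "background"]
  agg <- bg[, .(numerator = sum(.SD[[cn]]), denominator = sum(.SD[[dn]])),
            by = .(ref, alt), .SDcols = c(cn, dn)]
  full <- data.table(ref = substr(SUB_CLASSES, 1, 1), alt = substr(SUB_CLASSES, 3, 3))
  out <- merge(full, agg, by = c("ref", "alt"), all.x = TRUE)
  out[is.na(numerator), `:=`(numerator = 0)]
  out[is.na(denominator), `:=`(denominator = 0)]
  out[, class := sub_class(ref, alt)]
  out[, rate := fifelse(denominator > 0, numerator / denominator, NA_real_)]
  setcolorder(out, c("class", "ref", "alt", "numerator", "denominator", "rate"))
  setorder(out, class)
  # overall rate: all background alt bases over depth at eligible positions
  elig <- unique(bg[, c("pos", dn), with = FALSE])
  overall <- sum(bg[[cn]]) / sum(elig[[dn]])
  setattr(out, "class", c("bg_class_rates", class(out)))
  setattr(out, "overall", overall)
  setattr(out, "sample", sample)
  setattr(out, "collapsed", FALSE)
  out[]
}

#' Collapse reciprocal substitution classes
#'
#' Pools the numerators and denominators of reciprocal-complement class
#' pairs (e.g. C>A with G>T) into the 6 strand-collapsed classes written
#' `C:G>A:T` etc.
#'
#' @param t a `bg_class_rates` table with the 12 strand-resolved classes.
#' @return a `bg_class_rates` table over the 6 collapsed classes
#'   (`collapsed = TRUE`).
#' @export
collapse_classes <- function(t) {
  stopifnot(inherits(t, "bg_class_rates"))
  if (isTRUE(attr(t, "collapsed"))) return(t)
  cm <- collapse_map()
  x <- copy(t)[, collapsed := cm[class]]
  out <- x[, .(numerator = sum(numerator), denominator = sum(denominator)),
           by = .(class = collapsed)]
  out[, rate := fifelse(denominator > 0, numerator / denominator, NA_real_)]
  out <- out[match(COLLAPSED_CLASSES, class)]
  setattr(out, "class", c("bg_class_rates", class(out)))
  setattr(out, "overall", attr(t, "overall"))
  setattr(out, "sample", attr(t, "sample"))
  setattr(out, "collapsed", TRUE)
  out[]
}

#' Fraction of error-free positions
#'
#' The fraction of background-eligible positions carrying zero
#' background-category alt bases in the given sample.
#'
#' @inheritParams class_rates
#' @return a proportion in `[0, 1]`.
#' @export
error_free_fraction <- function(table, sample = c("plasma", "pbl", "fna")) {
  stopifnot(inherits(table, "bg_background"))
  sample <- match.arg(sample)
  cn <- paste0(sample, "_count")
  bg <- table[category == "background"]
  if (nrow(bg) == 0L) stop_bg("no background-eligible positions")
  per_pos <- bg[, .(errors = sum(.SD[[cn]])), by = pos, .SDcols = cn]
  mean(per_pos$errors == 0)
}

#' Context-resolved background error rates
#'
#' Splits each collapsed class by the 16 immediate flanking contexts, read
#' on the strand carrying the pyrimidine of the class (so the oxidative
#' NCG:CGN context appears as a 3' G next to the mutated C). Positions at
#' the reference edges are excluded. Marginalizing the 16 contexts of a
#' class recovers that class's pooled counts exactly.
#'
#' @inheritParams class_rates
#' @param ref a `ref_bundle` supplying the flanking bases.
#' @return data.table `class` (collapsed), `ctx5`, `ctx3`, `context`
#'   (e.g. `"ACG"` for A-C-G around a C:G pair), `numerator`,
#'   `denominator`, `rate`.
#' @export
context_rates <- function(table, ref, sample = c("plasma", "pbl", "fna")) {
  stopifnot(inherits(table, "bg_background"))
  sample <- match.arg(sample)
  cn <- paste0(sample, "_count"); dn <- paste0(sample, "_depth")
  L <- nchar(ref$sequence)
  bg <- table[category == "background" & pos > 0L & pos < L - 1L]
  refch <- rawToChar(ref$bytes, multiple = TRUE)
  up <- refch[bg$pos]          # base at pos-1 (plus strand)
  dn_b <- refch[bg$pos + 2L]   # base at pos+1
  pyr <- bg$ref %in% c("C", "T")
  x <- data.table(
    class = collapse_map()[sub_class(bg$ref, bg$alt)],
    ctx5 = fifelse(pyr, up, comp_base(dn_b)),
    ctx3 = fifelse(pyr, dn_b, comp_base(up)),
    num = bg[[cn]], den = bg[[dn]]
  )
  out <- x[, .(numerator = sum(num), denominator = sum(den)),
           by = .(class, ctx5, ctx3)]
  grid <- CJ(class = COLLAPSED_CLASSES, ctx5 = BASES, ctx3 = BASES)
  out <- merge(grid, out, by = c("class", "ctx5", "ctx3"), all.x = TRUE)
  out[is.na(numerator), `:=`(numerator = 0)]
  out[is.na(denominator), `:=`(denominator = 0)]
  out[, context := paste0(ctx5, substr(class, 1, 1), ctx3)]
  out[, rate := fifelse(denominator > 0, numerator / denominator, NA_real_)]
  setorder(out, class, ctx5, ctx3)
  out[]
}

#' Ratio of reciprocal substitution class rates
#'
#' @param t a strand-resolved `bg_class_rates` table.
#' @param pair character pair `c(excess, baseline)`, e.g. `c("C>A", "G>T")`.
#' @return the rate ratio `f_excess / f_baseline` (NA if the baseline rate
#'   is zero or undefined).
#' @export
reciprocal_ratio <- function(t, pair = c("C>A", "G>T")) {
  stopifnot(inherits(t, "bg_class_rates"), length(pair) == 2L)
  f <- t$rate[match(pair, t$class)]
  if (anyNA(f) || f[2] == 0) return(NA_real_)
  f[1] / f[2]
}

#' Cohort aggregation of reciprocal ratios
#'
#' Per-sample ratios averaged across a cohort (mean and SD of per-sample
#' values), alongside the pooled-count estimate.
#'
#' @param tables list of strand-resolved `bg_class_rates` tables.
#' @inheritParams reciprocal_ratio
#' @return list with `mean`, `sd`, `n`, `per_sample`, `pooled`.
#' @export
reciprocal_ratio_cohort <- function(tables, pair = c("C>A", "G>T")) {
  rr <- vapply(tables, reciprocal_ratio, numeric(1), pair = pair)
  num <- Reduce(`+`, lapply(tables, function(t) t$numerator[match(pair, t$class)]))
  den <- Reduce(`+`, lapply(tables, function(t) t$denominator[match(pair, t$class)]))
  pooled <- (num[1] / den[1]) / (num[2] / den[2])
  list(mean = mean(rr, na.rm = TRUE), sd = stats::sd(rr, na.rm = TRUE),
       n = sum(!is.na(rr)), per_sample = rr, pooled = pooled)
}

#' Attribute class-rate excess to the fragmentation step
#'
#' Compares paired PBL-like (sheared) and plasma-like (unsheared) rate
#' tables: `shear_fraction = (r_PBL - r_plasma) / r_PBL` is the fraction of
#' the PBL rate attributable to shearing, and
#' `shear_increase = (r_PBL - r_plasma) / r_plasma` the relative increase
#' over the plasma baseline.
#'
#' @param t_pbl,t_plasma `bg_class_rates` tables for the paired samples
#'   (collapsed tables recommended; strand-resolved tables are collapsed
#'   first).
#' @return data.table `class`, `r_pbl`, `r_plasma`, `shear_fraction`,
#'   `shear_increase`.
#' @export
attribute_shear <- function(t_pbl, t_plasma) {
  a <- if (isTRUE(attr(t_pbl, "collapsed"))) t_pbl else collapse_classes(t_pbl)
  b <- if (isTRUE(attr(t_plasma, "collapsed"))) t_plasma else collapse_classes(t_plasma)
  out <- data.table(class = a$class, r_pbl = a$rate,
                    r_plasma = b$rate[match(a$class, b$class)])
  out[, shear_fraction := fifelse(!is.na(r_pbl) & r_pbl > 0,
                                  (r_pbl - r_plasma) / r_pbl, NA_real_)]
  out[, shear_increase := fifelse(!is.na(r_plasma) & r_plasma > 0,
                                  (r_pbl - r_plasma) / r_plasma, NA_real_)]
  out[]
}

#' Cohort aggregation of shear attribution
#'
#' @param pbl_tables,plasma_tables matched lists of per-subject
#'   `bg_class_rates` tables.
#' @return data.table with per-class cohort mean and SD of both attribution
#'   statistics.
#' @export
attribute_shear_cohort <- function(pbl_tables, plasma_tables) {
  stopifnot(length(pbl_tables) == length(plasma_tables))
  per <- Map(attribute_shear, pbl_tables, plasma_tables)
  all <- rbindlist(per, idcol = "subject")
  all[, .(
    shear_fraction_mean = mean(shear_fraction, na.rm = TRUE),
    shear_fraction_sd = stats::sd(shear_fraction, na.rm = TRUE),
    shear_increase_mean = mean(shear_increase, na.rm = TRUE),
    shear_increase_sd = stats::sd(shear_increase, na.rm = TRUE),
    n = sum(!is.na(shear_fraction))
  ), by = class]
}

#' Attribute strand asymmetry to the hybrid selection step
#'
#' For the reciprocal pairs (C>A, G>T) and (C>T, G>A), computes the
#' asymmetry fraction `(f_excess - f_baseline) / f_excess` and the ratio
#' `f_excess / f_baseline`, with the excess side fixed by the captured
#' strand (minus-strand baits put the excess on C>A / C>T).
#'
#' @param t a strand-resolved `bg_class_rates` table.
#' @param captured_strand `"minus"` or `"plus"`.
#' @return data.table `pair`, `excess_class`, `baseline_class`, `f_excess`,
#'   `f_baseline`, `asymmetry`, `ratio`.
#' @export
attribute_hybsel <- function(t, captured_strand = c("minus", "plus")) {
  stopifnot(inherits(t, "bg_class_rates"), !isTRUE(attr(t, "collapsed")))
  captured_strand <- match.arg(captured_strand)
  pairs <- if (captured_strand == "minus") {
    list(c("C>A", "G>T"), c("C>T", "G>A"))
  } else {
    list(c("G>T", "C>A"), c("G>A", "C>T"))
  }
  rows <- lapply(pairs, function(p) {
    fe <- t$rate[match(p[1], t$class)]
    fb <- t$rate[match(p[2], t$class)]
    data.table(
      pair = paste(p, collapse = "/"),
      excess_class = p[1], baseline_class = p[2],
      f_excess = fe, f_baseline = fb,
      asymmetry = if (!is.na(fe) && fe > 0) (fe - fb) / fe else NA_real_,
      ratio = if (!is.na(fb) && fb > 0) fe / fb else NA_real_
    )
  })
  rbindlist(rows)
}
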