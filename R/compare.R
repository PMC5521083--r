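#' Paired statistical comparison of class rates between groups
#'
#' Two-sided paired test per substitution class (Wilcoxon signed-rank by
#' default; paired t by flag) across matched subjects, with Bonferroni
#' correction over the number of classes tested.
#'
#' @param group_a,group_b matched lists of per-subject `bg_class_rates`
#'   tables (same subject order).
#' @param classes `"collapsed"` (6 classes) or `"resolved"` (12).
#' @param method `"wilcoxon"` or `"t"`.
#' @param alpha significance level applied to adjusted p values.
#' @return object of class `bg_comparison`: data.table `class`, `mean_a`,
#'   `mean_b`, `mean_diff`, `statistic`, `p`, `p_adj`
#'   (`min(1, n_classes * p)`), `significant`; attribute
#'   `bonferroni_factor`.
#' @export
paired_class_test <- function(group_a, group_b,
                              classes = c("collapsed", "resolved"),
                              method = c("wilcoxon", "t"), alpha = 0.05) {
  classes <- match.arg(classes)
  method <- match.arg(method)
  if (length(group_a) != length(group_b)) {
    stop_bg("unmatched subjects: %d vs %d tables", length(group_a), length(group_b))
  }
  prep <- function(t) if (classes == "collapsed") collapse_classes(t) else t
  ra <- vapply(lapply(group_a, prep), function(t) t$rate, numeric(if (classes == "collapsed") 6L else 12L))
  rb <- vapply(lapply(group_b, prep), function(t) t$rate, numeric(if (classes == "collapsed") 6L else 12L))
  cls <- if (classes == "collapsed") COLLAPSED_CLASSES else SUB_CLASSES
  k <- length(cls)
  rows <- lapply(seq_len(k), function(i) {
    a <- ra[i, ]; b <- rb[i, ]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 2L || all(a == b)) {
      st <- NA_real_; p <- 1
    } else if (method == "wilcoxon") {
      ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
      st <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- stats::t.test(a, b, paired = TRUE)
      st <- unname(ht$statistic); p <- ht$p.value
    }
    data.table(class = cls[i], mean_a = mean(a), mean_b = mean(b),
               mean_diff = mean(a - b), statistic = st, p = p)
  })
  out <- rbindlist(rows)
  out[, p_adj := pmin(1, k * p)]
  out[, significant := p_adj < alpha]
  setattr(out, "class", c("bg_comparison", class(out)))
  setattr(out, "bonferroni_factor", k)
  out[]
}

#' SNP allele-frequency concordance between paired samples
#'
#' Pearson correlation of germline allele frequencies between the paired
#' plasma and PBL samples -- the QC check that the two library types carry
#' no systematic allelic bias.
#'
#' @param snp_freqs data.table with `plasma_vaf` and `pbl_vaf` columns
#'   (e.g. from [snp_table()]), or a `bg_background` table.
#' @return list `r`, `p`, `n`.
#' @export
snp_concordance <- function(snp_freqs) {
  if (inherits(snp_freqs, "bg_background")) snp_freqs <- snp_table(snp_freqs)
  x <- snp_freqs$plasma_vaf; y <- snp_freqs$pbl_vaf
  if (length(x) < 3L) stop_bg("need >= 3 SNPs for concordance, got %d", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_bg("zero variance in allele frequencies; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
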