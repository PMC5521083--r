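#' Classify site/alleles into background error vs germline vs excluded
#'
#' Applies the background-allele definition to a paired sample set. For each
#' position co-covered by the paired plasma and PBL pileups, all three
#' non-reference alleles are classified:
#'
#' * `depth_excluded` -- the position has quality-filtered depth below
#'   `min_depth_pair` in either paired sample, or (when an FNA pileup is
#'   supplied) below `fna_min_depth` in the FNA sample; the whole position is
#'   removed.
#' * `germline` -- the allele frequency is at or above `germline_af` in
#'   either paired sample.
#' * `somatic_excluded` -- the allele frequency exceeds `fna_max_af` in the
#'   FNA sample (candidate true somatic variant).
#' * `background` -- everything else, including zero-count alleles, which
#'   define the error-free capacity of the assay.
#'
#' @param plasma,pbl `bg_pileup` objects for the paired samples.
#' @param fna optional `bg_pileup` for the matched tumor FNA, or `NULL`.
#' @param thresholds a [filter_thresholds()].
#' @return object of class `bg_background`: a data.table with one row per
#'   (position, alt allele): `pos`, `ref`, `alt`, `category`, and per-sample
#'   `*_count`, `*_depth`, `*_vaf` columns.
#' @export
call_background <- function(plasma, pbl, fna = NULL,
                            thresholds = filter_thresholds()) {
  stopifnot(inherits(plasma, "bg_pileup"), inherits(pbl, "bg_pileup"))
  pc <- plasma$counts; bc <- pbl$counts
  common <- intersect(pc$pos, bc$pos)
  if (length(common) == 0L) stop_bg("coordinate mismatch: no co-covered positions")
  pc <- pc[pos %in% common]; bc <- bc[pos %in% common]
  if (!identical(pc$ref, bc$ref)) stop_bg("coordinate mismatch: reference bases differ between pileups")

  long <- function(cnt, prefix) {
    m <- data.table(
      pos = rep(cnt$pos, each = 3L),
      ref = rep(cnt$ref, each = 3L),
      alt = unlist(ALT_LOOKUP[cnt$ref], use.names = FALSE),
      depth = rep(cnt$depth, each = 3L)
    )
    cm <- as.matrix(cnt[, .(A, C, G, T)])
    altidx <- match(m$alt, BASES)
    m[, count := cm[cbind(rep(seq_len(nrow(cnt)), each = 3L), altidx)]]
    m[, vaf := fifelse(depth > 0L, count / depth, 0)]
    setnames(m, c("count", "depth", "vaf"),
             paste0(prefix, c("_count", "_depth", "_vaf")))
    m
  }
  tab <- long(pc, "plasma")
  tab <- cbind(tab, long(bc, "pbl")[, .(pbl_count, pbl_depth, pbl_vaf)])

  has_fna <- !is.null(fna)
  if (has_fna) {
    fc <- fna$counts
    ftab <- long(fc, "fna")
    tab <- merge(tab, ftab[, .(pos, alt, fna_count, fna_depth, fna_vaf)],
                 by = c("pos", "alt"), all.x = TRUE, sort = FALSE)
    tab[is.na(fna_depth), `:=`(fna_count = 0L, fna_depth = 0L, fna_vaf = 0)]
  }

  tab[, category := "background"]
  depth_bad <- tab$plasma_depth < thresholds$min_depth_pair |
    tab$pbl_depth < thresholds$min_depth_pair
  if (has_fna) depth_bad <- depth_bad | tab$fna_depth < thresholds$fna_min_depth
  tab[depth_bad, category := "depth_excluded"]
  tab[category == "background" &
        (plasma_vaf >= thresholds$germline_af | pbl_vaf >= thresholds$germline_af),
      category := "germline"]
  if (has_fna) {
    tab[category == "background" & fna_vaf > thresholds$fna_max_af,
        category := "somatic_excluded"]
  }
  setorder(tab, pos, alt)
  setattr(tab, "class", c("bg_background", class(tab)))
  setattr(tab, "has_fna", has_fna)
  tab[]
}

#' Germline allele frequency pairs
#'
#' Extracts (plasma, PBL) allele frequency pairs for every germline-category
#' allele, the input to SNP concordance QC.
#'
#' @param table a `bg_background` table from [call_background()].
#' @return data.table `pos`, `ref`, `alt`, `plasma_vaf`, `pbl_vaf`.
#' @export
snp_table <- function(table) {
  stopifnot(inherits(table, "bg_background"))
  out <- table[category == "germline",
               .(pos, ref, alt, plasma_vaf, pbl_vaf)]
  setorder(out, pos, alt)
  out[]
}
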