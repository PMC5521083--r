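test_that("sim_config validates its inputs", {
  expect_error(sim_config(p_seq = 1.5), "probability")
  expect_error(sim_config(dup_mean = 0.5), "dup_mean")
  w <- cleavage_weight_table()
  w[] <- 0
  expect_error(sim_config(cleavage_weights = w), "zero")
  expect_error(sim_config(cpg_enrichment = -1), "cpg_enrichment")
  expect_error(sim_config(somatic_spikes = data.frame(pos = 1, alt = "X", af = 0.1)),
               "ACGT")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("reference composition matches gc_fraction and CpG enrichment", {
  cfg <- sim_config(seed = 11, ref_length = 2e5, gc_fraction = 0.5,
                    cpg_enrichment = 1)
  ref <- make_reference(cfg)
  ch <- strsplit(ref$sequence, "")[[1]]
  f <- table(ch) / length(ch)
  expect_lt(abs(f[["C"]] + f[["G"]] - 0.5), 0.01)
  di <- paste0(ch[-length(ch)], ch[-1])
  cg <- mean(di == "CG")
  expect_lt(abs(cg - 0.0625), 0.002)   # independence: 0.25 * 0.25

  cfg2 <- sim_config(seed = 11, ref_length = 2e5, gc_fraction = 0.4,
                     cpg_enrichment = 3)
  ref2 <- make_reference(cfg2)
  ch2 <- strsplit(ref2$sequence, "")[[1]]
  f2 <- table(ch2) / length(ch2)
  expect_lt(abs(f2[["C"]] + f2[["G"]] - 0.4), 0.01)
  cg2 <- mean(paste0(ch2[-length(ch2)], ch2[-1]) == "CG")
  expect_lt(abs(cg2 / (f2[["C"]] * f2[["G"]]) - 3), 0.35)
})

test_that("degenerate composition and determinism contracts hold", {
  cfg <- sim_config(seed = 4, ref_length = 5e4, gc_fraction = 0)
  ref <- make_reference(cfg)
  expect_true(all(strsplit(ref$sequence, "")[[1]] %in% c("A", "T")))
  expect_identical(make_reference(cfg)$sequence, ref$sequence)
  expect_error(make_reference(sim_config(ref_length = 500)), "ref_length")
})

test_that("fragment lengths follow the configured median", {
  ref <- make_reference(sim_config(seed = 2, ref_length = 5e4))
  cfg170 <- sim_config(seed = 2, ref_length = 5e4, fragment_median = 170)
  cfg300 <- sim_config(seed = 2, ref_length = 5e4, fragment_median = 300,
                       fragment_sd = 80)
  f170 <- draw_fragments(ref, cfg170, n = 5000)
  f300 <- draw_fragments(ref, cfg300, n = 5000)
  expect_lt(abs(median(f170$end - f170$start) - 170), 12)
  expect_gt(median(f300$end - f300$start), median(f170$end - f170$start))
})

test_that("cut-site dinucleotides recover the configured cleavage weights", {
  cfg <- sim_config(seed = 9, ref_length = 5e4)
  ref <- make_reference(cfg)
  enrich <- function(config) {
    fr <- draw_fragments(ref, config, n = 3e4)
    rc <- strsplit(ref$sequence, "")[[1]]
    d_start <- paste0(rc[fr$start], rc[fr$start + 1])
    # end bond read in minus orientation (its 5' end): revcomp of plus dinuc
    d_end <- chartr("ACGT", "TGCA", paste0(rc[fr$end], rc[fr$end + 1]))
    d_end <- vapply(strsplit(d_end, ""), function(x) paste(rev(x), collapse = ""), "")
    cut <- table(c(d_start, d_end))
    bg <- table(paste0(rc[-length(rc)], rc[-1]))
    (cut[names(bg)] / sum(cut)) / (bg / sum(bg))
  }
  # uniform weights are a no-op: cut-site composition = genomic background
  w_unif <- cleavage_weight_table(); w_unif[] <- 1
  e_unif <- enrich(sim_config(seed = 9, ref_length = 5e4, cleavage_weights = w_unif))
  expect_true(all(abs(e_unif - 1) < 0.15))
  # acoustic table: enrichment ranks CG > CA > TA ~ GA above the rest
  e_ac <- enrich(cfg)
  expect_gt(e_ac[["CG"]], e_ac[["CA"]])
  expect_gt(e_ac[["CA"]], e_ac[["TA"]])
  expect_lt(abs(e_ac[["TA"]] / e_ac[["GA"]] - 1), 0.2)
  expect_gt(min(e_ac[c("CG", "CA", "TA", "GA")]),
            max(e_ac[setdiff(names(e_ac), c("CG", "CA", "TA", "GA"))]))
})

test_that("zero-rate damage injects nothing and plasma mode disables shearing", {
  cfg <- sim_config(seed = 3, ref_length = 12000, n_fragments = 2000,
                    p_ox = 0, p_ox2 = 0, p_bp = 0, p_template = 0,
                    snp_density = 0)
  ref <- make_reference(cfg)
  fr <- draw_fragments(ref, cfg)
  dmg <- apply_damage(fr, ref, cfg, mode = "acoustic")
  expect_identical(nrow(dmg$lesions), 0L)
  # plasma mode forces shearing rates to zero even when configured positive
  cfg2 <- sim_config(seed = 3, ref_length = 12000, n_fragments = 2000,
                     p_ox = 1e-3, p_bp = 1e-2, p_template = 0, snp_density = 0)
  dmg2 <- apply_damage(draw_fragments(ref, cfg2), ref, cfg2, mode = "none")
  expect_false(any(dmg2$lesions$process %in%
                     c("oxidation_CA", "oxidation_CG", "breakpoint_AK")))
})

test_that("break-point A>K lesion count matches an independent A-end tally", {
  cfg <- sim_config(seed = 13, ref_length = 30000, n_fragments = 3e4,
                    p_bp = 0.01, p_ox = 0, p_ox2 = 0, p_template = 0,
                    snp_density = 0)
  ref <- make_reference(cfg)
  fr <- draw_fragments(ref, cfg)
  dmg <- apply_damage(fr, ref, cfg, mode = "acoustic")
  rc <- strsplit(ref$sequence, "")[[1]]
  n_a_ends <- sum(rc[fr$start + 1] == "A") + sum(rc[fr$end] == "T")
  nbp <- sum(dmg$lesions$process == "breakpoint_AK")
  expected <- 0.01 * n_a_ends
  expect_lt(abs(nbp - expected), 3 * sqrt(expected))
  expect_true(all(dmg$lesions[process == "breakpoint_AK" & strand == "+", injected] %in% c("G", "T")))
})

test_that("NCG-context oxidation multiplier is recovered from the ledger", {
  cfg <- sim_config(seed = 21, ref_length = 30000, n_fragments = 4e4,
                    p_ox = 3e-4, p_ox2 = 0, ncg_multiplier = 5, p_bp = 0,
                    p_template = 0, snp_density = 0, cpg_enrichment = 1)
  ref <- make_reference(cfg)
  fr <- draw_fragments(ref, cfg)
  dmg <- apply_damage(fr, ref, cfg, mode = "acoustic")
  les <- dmg$lesions[process == "oxidation_CA"]
  # independent context annotation from the reference string: flag both
  # bases of every CpG dinucleotide
  rc <- strsplit(ref$sequence, "")[[1]]
  cpgflag <- logical(length(rc))
  cs <- which(rc == "C" & c(rc[-1], "N") == "G")
  cpgflag[cs] <- TRUE; cpgflag[cs + 1L] <- TRUE
  in_cpg <- function(p) cpgflag[p + 1L]   # 0-based position lookup
  # independent exposure tally: eligible C/G bases in/out of CpG context
  cg <- rc %in% c("C", "G")
  cum_cpg <- c(0, cumsum(cg & cpgflag)); cum_non <- c(0, cumsum(cg & !cpgflag))
  expo_cpg <- sum(cum_cpg[fr$end + 1] - cum_cpg[fr$start + 1])
  expo_non <- sum(cum_non[fr$end + 1] - cum_non[fr$start + 1])
  r_cpg <- sum(in_cpg(les$pos)) / expo_cpg
  r_non <- sum(!in_cpg(les$pos)) / expo_non
  ratio <- r_cpg / r_non
  se <- sqrt(1 / sum(in_cpg(les$pos)) + 1 / sum(!in_cpg(les$pos)))
  expect_lt(abs(log(ratio / 5)), 3 * se)
})

test_that("error-free configuration emits reference-identical reads", {
  cfg <- sim_config(seed = 6, ref_length = 12000, n_fragments = 1500,
                    p_ox = 0, p_ox2 = 0, p_bp = 0, p_hs_CA = 0, p_hs_CT = 0,
                    p_template = 0, p_seq = 0, snp_density = 0,
                    q_low_given_correct = 0.2, dup_mean = 1)
  ref <- make_reference(cfg)
  s <- simulate_sample(ref, cfg, mode = "acoustic", seed = 5)
  same <- mapply(function(sq, p, l) sq == substr(ref$sequence, p + 1, p + l),
                 s$reads$seq, s$reads$pos, s$reads$len)
  expect_true(all(same))
  qv <- as.integer(charToRaw(paste(s$reads$qual, collapse = ""))) - 33L
  expect_true(all(qv %in% c(12L, 37L)))
  expect_lt(abs(mean(qv >= 30) - 0.8), 3 * sqrt(0.2 * 0.8 / length(qv)))
})

test_that("sequencing errors survive Q30 at the configured probability", {
  cfg <- sim_config(seed = 8, ref_length = 12000, n_fragments = 5000,
                    p_ox = 0, p_ox2 = 0, p_bp = 0, p_hs_CA = 0, p_hs_CT = 0,
                    p_template = 0, p_seq = 1e-3, q_high_given_error = 0.05,
                    snp_density = 0, dup_mean = 1)
  ref <- make_reference(cfg)
  s <- simulate_sample(ref, cfg, mode = "none", seed = 5)
  # all mismatching read bases are sequencing-run errors here; tally their
  # emitted qualities directly from the records
  refch <- strsplit(ref$sequence, "")[[1]]
  qv <- integer(0)
  big_seq <- strsplit(paste(s$reads$seq, collapse = ""), "")[[1]]
  big_q <- as.integer(charToRaw(paste(s$reads$qual, collapse = ""))) - 33L
  idx <- sequence(s$reads$len, from = s$reads$pos + 1L)
  mm <- big_seq != refch[idx]
  expect_equal(sum(mm), nrow(s$seq_errors))
  frac_hi <- mean(big_q[mm] >= 30)
  expect_lt(abs(frac_hi - 0.05), 3 * sqrt(0.05 * 0.95 / sum(mm)))
})

test_that("PCR duplication follows the configured law", {
  cfg <- sim_config(seed = 10, ref_length = 12000, n_fragments = 5000,
                    dup_mean = 1.5, p_template = 0, snp_density = 0)
  ref <- make_reference(cfg)
  s <- simulate_sample(ref, cfg, mode = "none", seed = 1)
  npairs <- nrow(s$reads) / 2
  expect_lt(abs(npairs - 1.5 * 5000), 3 * sqrt(5000 * 0.5))
  # duplicate copies share fragment coordinates with their parent molecule
  key <- s$reads[, paste(mol_id, pos, len, collapse = "|"), by = .(qname)]
  frag_keys <- unique(s$reads[, .(mol_id, frag = paste(min(pos), max(pos + len))),
                              by = qname][, .(mol_id, frag)])
  expect_identical(nrow(frag_keys), 5000L)
})

test_that("every read base is accounted for by the truth ledger", {
  cfg <- sim_config(seed = 14, ref_length = 10000, n_fragments = 1500,
                    p_ox = 2e-3, p_ox2 = 5e-4, p_bp = 5e-3, p_hs_CA = 1e-3,
                    p_hs_CT = 5e-4, p_template = 1e-3, p_seq = 2e-3,
                    snp_density = 2e-3, dup_mean = 1.3)
  ref <- make_reference(cfg)
  snps <- draw_snps(ref, cfg$snp_density, seed = 99)
  s <- simulate_sample(ref, cfg, mode = "acoustic", snps = snps, seed = 7)
  # reconstruct the expected sequence of every read from the ledger alone
  refch <- strsplit(ref$sequence, "")[[1]]
  vis <- s$lesions[visible == TRUE]
  serr <- s$seq_errors
  n_checked <- 0L
  ok <- logical(nrow(s$reads))
  for (i in seq_len(nrow(s$reads))) {
    r <- s$reads[i]
    expected <- refch[(r$pos + 1):(r$pos + r$len)]
    lv <- vis[mol_id == r$mol_id & pos >= r$pos & pos < r$pos + r$len]
    if (nrow(lv)) expected[lv$pos - r$pos + 1L] <- lv$proj_alt
    se <- serr[qname == r$qname & mate == r$mate &
                 pos >= r$pos & pos < r$pos + r$len]
    if (nrow(se)) expected[se$pos - r$pos + 1L] <- se$obs
    obs <- strsplit(r$seq, "")[[1]]
    n_checked <- n_checked + sum(obs != refch[(r$pos + 1):(r$pos + r$len)])
    ok[i] <- identical(paste(expected, collapse = ""), r$seq)
  }
  expect_identical(sum(!ok), 0L)
  expect_gt(n_checked, 50)  # the instance actually exercises every process
  # all configured processes are represented in the ledger
  expect_setequal(
    union(unique(s$lesions$process), "seqrun"),
    c("oxidation_CA", "oxidation_CG", "breakpoint_AK", "hybsel_CA",
      "hybsel_CT", "template", "snp", "seqrun")
  )
})

test_that("cohorts are deterministic and carry shared SNPs and spikes", {
  cfg <- sim_config(seed = 17, ref_length = 12000, n_fragments = 4000,
                    snp_density = 1e-3,
                    somatic_spikes = data.frame(pos = 6100, alt = "T", af = 0.1))
  coh1 <- simulate_cohort(cfg, n_pairs = 1)
  coh2 <- simulate_cohort(cfg, n_pairs = 1)
  expect_identical(coh1$subjects[[1]]$pbl$lesions, coh2$subjects[[1]]$pbl$lesions)
  expect_identical(coh1$subjects[[1]]$plasma$reads$seq,
                   coh2$subjects[[1]]$plasma$reads$seq)
  # somatic spike appears at the configured allele fraction in the FNA pileup
  fna <- coh1$subjects[[1]]$fna
  spos <- 6100L
  ref <- coh1$reference
  rb <- substr(ref$sequence, spos + 1, spos + 1)
  if (rb != "T") {
    th <- filter_thresholds(min_depth_pair = 0)
    pu <- build_pileup(filter_reads(fna$reads, th), ref, th)
    row <- pu$counts[pos == spos]
    expect_gt(nrow(row), 0)
    vaf <- row$T / row$depth
    expect_lt(abs(vaf - 0.1), 3 * sqrt(0.1 * 0.9 / row$depth))
  }
})
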