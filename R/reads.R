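#' Generate aligned paired-end reads from damaged molecules
#'
#' Turns a damaged molecule set into coordinate-sorted, all-match paired
#' 100-bp alignment records, applying the remaining protocol steps in
#' physical order: hybrid-selection damage (per captured molecule, on one
#' fixed reference strand, before duplication), PCR duplication
#' (`1 + Poisson(dup_mean - 1)` copies per molecule), and per-base
#' sequencing-run errors with a two-component base quality model (correct
#' bases Q37 with probability `1 - q_low_given_correct`, else Q12; error
#' bases Q12 with probability `1 - q_high_given_error`, else Q37).
#'
#' Each unique molecule descends from one original template strand (fair
#' coin): shearing-era strand lesions are visible only when they sit on that
#' strand, while duplex substitutions (SNPs, somatic spikes) and
#' hybrid-selection lesions (incurred after library amplification, on the
#' captured strand) are visible in every copy. Fragments shorter than the
#' read length yield reads truncated at the fragment end, so mates overlap
#' totally.
#'
#' @param molecules a `bg_molecules` object from [apply_damage()].
#' @param ref a `ref_bundle`.
#' @param config a [sim_config()].
#' @param sample_name sample identifier used in read names.
#' @param seed optional seed override.
#' @return object of class `bg_sample`: list with `reads` (data.table of
#'   alignment records, 0-based `pos`), `molecules` (with `template_strand`,
#'   `r1_forward`, `copies`), `lesions` (ledger with `visible` flag),
#'   `seq_errors` (read-level sequencing-run error ledger) and `sample_name`.
#' @export
generate_reads <- function(molecules, ref, config, sample_name = "sample", seed = NULL) {
  if (!inherits(molecules, "bg_molecules")) stop_bg("molecules must come from apply_damage()")
  if (nrow(molecules$molecules) == 0L) stop_bg("molecule set is empty")
  seed <- seed %||% config$seed
  withr::with_seed(derive_seed(seed, 5L), {
    generate_reads_impl(molecules, ref, config, sample_name)
  })
}

generate_reads_impl <- function(molecules, ref, config, sample_name) {
  mol <- copy(molecules$molecules)
  lesions <- copy(molecules$lesions)
  nmol <- nrow(mol)
  refch <- NULL

  mol[, template_strand := ifelse(stats::runif(nmol) < 0.5, "+", "-")]
  mol[, r1_forward := stats::runif(nmol) < 0.5]
  mol[, copies := 1L + stats::rpois(nmol, config$dup_mean - 1)]

  # hybrid-selection damage: per captured molecule, fixed reference strand
  hs <- hybsel_lesions(mol, ref, config)
  if (!is.null(hs)) lesions <- rbindlist(list(lesions, hs), use.names = TRUE)
  setorder(lesions, mol_id, pos)
  lesions <- unique(lesions, by = c("mol_id", "pos", "strand"))

  # visibility: duplex and post-capture lesions always; strand lesions only
  # when they sit on the molecule's original template strand
  tmpl <- mol$template_strand[match(lesions$mol_id, mol$mol_id)]
  lesions[, visible := strand == "*" |
            process %in% c("hybsel_CA", "hybsel_CT") |
            strand == tmpl]

  # one read-pair layout per molecule; duplicates replicate it
  rl <- config$read_length
  flen <- mol$end - mol$start
  lenF <- pmin(rl, flen)                      # forward read: fragment 5' (plus) end
  lenR <- pmin(rl, flen)                      # reverse read: fragment 3' (minus 5') end
  pair_idx <- rep.int(seq_len(nmol), mol$copies)
  copy_no <- sequence(mol$copies)
  npair <- length(pair_idx)

  reads <- data.table(
    mol_id = rep(mol$mol_id[pair_idx], each = 2L),
    copy = rep(copy_no, each = 2L),
    forward = rep(c(TRUE, FALSE), npair),
    pos = as.integer(rbind(mol$start[pair_idx], mol$end[pair_idx] - lenR[pair_idx])),
    len = as.integer(rbind(lenF[pair_idx], lenR[pair_idx])),
    frag_start = rep(mol$start[pair_idx], each = 2L),
    frag_end = rep(mol$end[pair_idx], each = 2L),
    r1fwd = rep(mol$r1_forward[pair_idx], each = 2L)
  )
  reads[, mate := fifelse(forward == r1fwd, 1L, 2L)]
  nr <- nrow(reads)

  # assemble all read bases as one byte vector
  offs0 <- c(0L, cumsum(reads$len))[seq_len(nr)]
  B <- sum(reads$len)
  idx <- sequence(reads$len, from = reads$pos + 1L)
  seq_bytes <- ref$bytes[idx]

  # project visible template-level lesions into covering reads
  vis <- lesions[visible == TRUE]
  if (nrow(vis) > 0L) {
    rm <- data.table(mol_id = reads$mol_id, row = seq_len(nr),
                     pos = reads$pos, len = reads$len, off = offs0)
    hit <- merge(vis[, .(mol_id, lpos = pos, proj_alt)], rm,
                 by = "mol_id", allow.cartesian = TRUE)
    hit <- hit[lpos >= pos & lpos < pos + len]
    if (nrow(hit) > 0L) {
      seq_bytes[hit$off + hit$lpos - hit$pos + 1L] <- charToRaw(paste(hit$proj_alt, collapse = ""))
    }
  }

  # sequencing-run errors, independent per read base
  seq_errors <- data.table(read_row = integer(), pos = integer(),
                           ref = character(), template = character(),
                           obs = character())
  nerr <- stats::rbinom(1L, B, config$p_seq)
  err_at <- integer(0)
  if (nerr > 0L) {
    err_at <- sort(sample.int(B, nerr))
    cur <- rawToChar(seq_bytes[err_at])
    cur_v <- strsplit(cur, "", fixed = TRUE)[[1]]
    obs <- random_other_base(cur_v)
    seq_bytes[err_at] <- charToRaw(paste(obs, collapse = ""))
    rrow <- findInterval(err_at - 1L, cumsum(reads$len)) + 1L
    rpos <- reads$pos[rrow] + (err_at - offs0[rrow] - 1L)
    seq_errors <- data.table(
      read_row = rrow, pos = as.integer(rpos),
      ref = rawToChar(ref$bytes[rpos + 1L], multiple = TRUE),
      template = cur_v, obs = obs
    )
  }

  # two-component quality model
  q <- rep.int(37L, B)
  q[stats::runif(B) < config$q_low_given_correct] <- 12L
  if (nerr > 0L) {
    q[err_at] <- fifelse(stats::runif(nerr) < config$q_high_given_error, 37L, 12L)
  }
  qual_big <- rawToChar(as.raw(q + 33L))
  seq_big <- rawToChar(seq_bytes)
  starts <- offs0 + 1L
  stops <- offs0 + reads$len
  reads[, seq := substring(seq_big, starts, stops)]
  reads[, qual := substring(qual_big, starts, stops)]

  # SAM bookkeeping
  reads[, qname := sprintf("%s.m%07d.%d", sample_name, mol_id, copy)]
  reads[, flag := 1L + 2L +
          fifelse(forward, 0L, 16L) + fifelse(forward, 32L, 0L) +
          fifelse(mate == 1L, 64L, 128L)]
  reads[, strand := fifelse(forward, "+", "-")]
  reads[, cigar := paste0(len, "M")]
  reads[, mpos := fifelse(forward, frag_end - len, frag_start)]
  # recompute mate start for truncated fragments (mate lengths are equal here)
  reads[, tlen := fifelse(forward, frag_end - frag_start, -(frag_end - frag_start))]
  reads[, rname := ref$name]
  seq_errors[, qname := reads$qname[read_row]]
  seq_errors[, mate := reads$mate[read_row]]
  seq_errors[, process := "seqrun"]

  setorder(reads, pos, qname, mate)
  out <- reads[, .(qname, flag, rname, pos, len, strand, mate, cigar,
                   seq, qual, mpos, tlen, mol_id, copy)]
  structure(
    list(reads = out, molecules = mol, lesions = lesions,
         seq_errors = seq_errors[, .(qname, mate, pos, ref, template, obs, process)],
         sample_name = sample_name),
    class = "bg_sample"
  )
}

hybsel_lesions <- function(mol, ref, config) {
  if (config$p_hs_CA <= 0 && config$p_hs_CT <= 0) return(NULL)
  codes <- base_codes(ref$bytes)
  refch <- rawToChar(ref$bytes, multiple = TRUE)
  src <- if (config$hs_strand == "minus") "C" else "G"
  mask <- refch == src
  L <- length(mask)
  cnt <- c(0L, cumsum(mask))
  P <- which(mask)
  lo <- cnt[mol$start + 1L]; hi <- cnt[mol$end + 1L]
  ni <- hi - lo
  N <- sum(ni)
  if (N == 0L) return(NULL)
  cum <- cumsum(ni)
  draw <- function(rate, proj_to, process) {
    k <- stats::rbinom(1L, N, rate)
    if (k == 0L) return(NULL)
    u <- sort(sample.int(N, k))
    fi <- findInterval(u - 1L, cum) + 1L
    off <- u - c(0L, cum)[fi]
    pos <- P[lo[fi] + off] - 1L
    data.table(
      mol_id = mol$mol_id[fi], pos = pos,
      strand = if (config$hs_strand == "minus") "-" else "+",
      ref = src, injected = if (config$hs_strand == "minus") comp_base(proj_to) else proj_to,
      proj_alt = proj_to, process = process
    )
  }
  proj_CA <- if (config$hs_strand == "minus") "A" else "T"  # C>A or G>T
  proj_CT <- if (config$hs_strand == "minus") "T" else "A"  # C>T or G>A
  rbindlist(list(
    draw(config$p_hs_CA, proj_CA, "hybsel_CA"),
    draw(config$p_hs_CT, proj_CT, "hybsel_CT")
  ), use.names = TRUE)
}

#' Simulate one sample end to end
#'
#' Convenience wrapper chaining [draw_fragments()], [apply_damage()] and
#' [generate_reads()] with deterministic per-stage seeds.
#'
#' @inheritParams generate_reads
#' @param mode `"acoustic"` or `"none"` (see [apply_damage()]).
#' @param snps,spikes optional variant tables (see [apply_damage()]).
#' @param n number of fragments.
#' @export
simulate_sample <- function(ref, config, mode = c("acoustic", "none"),
                            sample_name = "sample", snps = NULL, spikes = NULL,
                            n = config$n_fragments, seed = NULL) {
  mode <- match.arg(mode)
  seed <- seed %||% config$seed
  frags <- draw_fragments(ref, config, n = n, seed = seed)
  dmg <- apply_damage(frags, ref, config, mode = mode, snps = snps,
                      spikes = spikes, seed = seed)
  generate_reads(dmg, ref, config, sample_name = sample_name, seed = seed)
}
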