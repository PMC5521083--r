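#' Simulate a cohort of matched sample triplets
#'
#' For each subject, generates three libraries from one shared genotype:
#' a plasma-like sample (no shearing damage, nuclease cleavage preference),
#' a PBL-like sample (acoustic shearing: oxidative, break-point and cleavage
#' signatures active) and an FNA-like tumor sample (PBL protocol plus somatic
#' spike-ins). All samples of a subject share the same germline SNPs; the
#' reference and target panel are shared across the cohort.
#'
#' @param config a [sim_config()]; `config$somatic_spikes` (if set) is
#'   injected into the FNA-like samples.
#' @param n_pairs number of subjects.
#' @param out_dir optional directory; when given, writes FASTA, BED, one SAM
#'   per sample, truth TSVs and a YAML echo of the configuration.
#' @param fna whether to generate the FNA-like sample (default TRUE).
#' @return object of class `bg_cohort`: list with `reference`, `config` and
#'   `subjects`, a list of per-subject lists with elements `snps`, `plasma`,
#'   `pbl` and (optionally) `fna`, each a `bg_sample`.
#' @examples
#' \donttest{
#' cfg <- sim_config(seed = 7, ref_length = 20000, n_fragments = 5000)
#' coh <- simulate_cohort(cfg, n_pairs = 1)
#' names(coh$subjects[[1]])
#' }
#' @export
simulate_cohort <- function(config, n_pairs = 1L, out_dir = NULL, fna = TRUE) {
  if (n_pairs < 1L) stop_bg("n_pairs must be >= 1")
  ref <- make_reference(config)
  plasma_cfg <- config
  plasma_cfg$cleavage_weights <- cleavage_weight_table("plasma_nuclease")
  plasma_cfg$cleavage_mode <- "plasma_nuclease"

  subjects <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    sseed <- derive_seed(config$seed, 100L + k)
    snps <- draw_snps(ref, config$snp_density, seed = sseed)
    subj <- list(snps = snps)
    subj$plasma <- simulate_sample(
      ref, plasma_cfg, mode = "none",
      sample_name = sprintf("s%02d_plasma", k),
      snps = snps, seed = derive_seed(sseed, 1L)
    )
    subj$pbl <- simulate_sample(
      ref, config, mode = "acoustic",
      sample_name = sprintf("s%02d_pbl", k),
      snps = snps, seed = derive_seed(sseed, 2L)
    )
    if (fna) {
      subj$fna <- simulate_sample(
        ref, config, mode = "acoustic",
        sample_name = sprintf("s%02d_fna", k),
        snps = snps, spikes = config$somatic_spikes,
        seed = derive_seed(sseed, 3L)
      )
    }
    subjects[[k]] <- subj
  }

  out <- structure(list(reference = ref, config = config, subjects = subjects),
                   class = "bg_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tryCatch({
      write_reference(ref, file.path(out_dir, "reference.fa"),
                      file.path(out_dir, "targets.bed"))
      for (k in seq_len(n_pairs)) {
        for (s in intersect(c("plasma", "pbl", "fna"), names(subjects[[k]]))) {
          write_sample(subjects[[k]][[s]], out_dir, ref)
        }
        utils::write.table(subjects[[k]]$snps,
                           file.path(out_dir, sprintf("s%02d_snps.tsv", k)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      cfg_echo <- config
      cfg_echo$cleavage_weights <- as.list(cfg_echo$cleavage_weights)
      if (!is.null(cfg_echo$somatic_spikes)) {
        cfg_echo$somatic_spikes <- as.list(as.data.frame(cfg_echo$somatic_spikes))
      }
      yaml::write_yaml(unclass(cfg_echo), file.path(out_dir, "config.yaml"))
    }, error = function(e) {
      stop_bg("failed writing cohort files under '%s': %s", out_dir, conditionMessage(e))
    })
  }
  out
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat(sprintf("<bg_cohort> %d subject(s), samples per subject: %s\n",
              length(x$subjects),
              paste(setdiff(names(x$subjects[[1]]), "snps"), collapse = ", ")))
  print(x$reference)
  invisible(x)
}
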