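# Shared fixture builders. Everything is generated in code; no data files.

tiny_annotation <- function(n = 4L, chrom = "1") {
  snp_annotation(sprintf("rs%02d", seq_len(n)), rep(chrom, n),
                 seq_len(n) * 1000L, "A", "G")
}

# random intensity table with a missingness mask, for round-trip tests
random_intensity <- function(n_snps = 12L, n_samples = 5L, seed = 1L,
                             mask_frac = 0.1) {
  set.seed(seed)
  ann <- tiny_annotation(n_snps)
  samples <- sprintf("s%02d", seq_len(n_samples))
  s1 <- matrix(round(stats::rgamma(n_snps * n_samples, 4, 0.01), 3),
               n_snps, n_samples)
  s2 <- matrix(round(stats::rgamma(n_snps * n_samples, 4, 0.01), 3),
               n_snps, n_samples)
  mask <- matrix(stats::runif(n_snps * n_samples) < mask_frac,
                 n_snps, n_samples)
  s1[mask] <- NA_real_
  s2[mask] <- NA_real_
  intensity_table(ann, samples, s1, s2)
}

random_genotypes <- function(n_snps = 50L, n_samples = 10L, seed = 2L,
                             nocall_frac = 0.05) {
  set.seed(seed)
  ann <- tiny_annotation(n_snps)
  samples <- sprintf("s%02d", seq_len(n_samples))
  calls <- matrix(sample(c("AA", "Aa", "aa"), n_snps * n_samples,
                         replace = TRUE),
                  n_snps, n_samples)
  calls[stats::runif(n_snps * n_samples) < nocall_frac] <- "NoCall"
  genotype_matrix(ann, samples, calls)
}

# the standard simulated world used across aberration tests: one cohort with
# reference, control and patient blocks
scan_world <- function(seed, n_snps = 2000L, n_ref = 30L, n_ctl = 40L,
                       n_pat = 30L, aberrations = list()) {
  cfg <- sim_config(n_snps = n_snps, n_samples = n_ref + n_ctl + n_pat,
                    seed = seed)
  co <- simulate_cohort(cfg)
  for (ab in aberrations) {
    co <- inject_aberration(co, ab$sample, ab$start_snp, ab$end_snp,
                            ab$a, ab$b, ab$p)
  }
  cpa <- estimate_cpa(co$intensity, co$genotypes)
  fm <- freq_matrix(co$intensity, cpa)
  ref <- seq_len(n_ref)
  ctl <- n_ref + seq_len(n_ctl)
  pat <- n_ref + n_ctl + seq_len(n_pat)
  bands <- build_reference_bands(
    allele_freq_matrix(fm$annotation, fm$samples[ref],
                       fm$freq[, ref, drop = FALSE]),
    genotype_matrix(fm$annotation, fm$samples[ref],
                    co$genotypes$calls[, ref, drop = FALSE]))
  list(cohort = co, freqs = fm, bands = bands,
       ref_samples = fm$samples[ref], ctl_samples = fm$samples[ctl],
       pat_samples = fm$samples[pat])
}
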