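# Seeded synthetic-data generator.
#
# Emulates the statistical structure the estimators assume: Hardy-Weinberg
# genotypes with per-SNP allele frequencies drawn from a uniform range,
# per-SNP lognormal CPA, multiplicative lognormal intensity noise, optional
# aberrant segments following the tumor/normal mixture model, hemizygous
# male X panels, and DNA pools formed by summing individual intensities.
# Everything is reproducible from a single integer seed (R's default
# Mersenne-Twister generator).

#' Simulation configuration
#'
#' Defaults are the package's stated world: 1,000 SNPs x 100 samples, SNP
#' allele frequencies uniform on (0.05, 0.5), `ln CPA ~ Normal(0, 0.5^2)`,
#' 10% multiplicative intensity noise, and a 1% noise floor on zero-copy
#' channels so background signal is never exactly zero.
#'
#' @param n_snps,n_samples panel dimensions.
#' @param maf_range two-element range of the uniform SNP allele-frequency
#'   distribution.
#' @param cpa_log_sd SD of `ln CPA` (0 fixes CPA at 1).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   intensity noise (0 = noiseless).
#' @param base_signal mean single-copy-pair channel signal (arbitrary units).
#' @param noise_floor zero-copy channels emit `base_signal * noise_floor`
#'   times noise (default 0.01; 0 makes absent alleles exactly silent).
#' @param seed integer RNG seed.
#' @param chromosomes named integer vector: SNPs per chromosome (default all
#'   `n_snps` on chromosome 1). Positions are spaced `spacing_bp` apart.
#' @param spacing_bp inter-SNP spacing in bp (default 10,000).
#' @param aberrations optional list of aberration specs, each a list with
#'   `sample`, `start_snp`, `end_snp` (global SNP indices in annotation
#'   order), `a`, `b`, `p`; applied by [inject_aberration()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 1000L, n_samples = 100L,
                       maf_range = c(0.05, 0.5), cpa_log_sd = 0.5,
                       noise_cv = 0.1, base_signal = 1000,
                       noise_floor = 0.01, seed = 1L,
                       chromosomes = NULL, spacing_bp = 10000L,
                       aberrations = list()) {
  if (n_snps < 1L || n_samples < 1L) stop("counts must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (cpa_log_sd < 0) stop("cpa_log_sd must be >= 0")
  if (base_signal <= 0) stop("base_signal must be positive")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair inside (0, 1)")
  }
  if (is.null(chromosomes)) chromosomes <- c("1" = as.integer(n_snps))
  if (sum(chromosomes) != n_snps) stop("chromosomes must sum to n_snps")
  for (ab in aberrations) {
    if (ab$start_snp < 1L || ab$end_snp > n_snps || ab$start_snp > ab$end_snp) {
      stop("aberration range outside the panel")
    }
  }
  structure(list(n_snps = as.integer(n_snps), n_samples = as.integer(n_samples),
                 maf_range = maf_range, cpa_log_sd = cpa_log_sd,
                 noise_cv = noise_cv, base_signal = base_signal,
                 noise_floor = noise_floor, seed = as.integer(seed),
                 chromosomes = chromosomes, spacing_bp = as.integer(spacing_bp),
                 aberrations = aberrations),
            class = "sim_config")
}

lognorm_noise <- function(n, cv) {
  # multiplicative noise with mean exactly 1 and coefficient of variation cv
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

sim_annotation <- function(cfg) {
  chroms <- rep(names(cfg$chromosomes), cfg$chromosomes)
  pos <- unlist(lapply(cfg$chromosomes, function(n) seq_len(n) * cfg$spacing_bp),
                use.names = FALSE)
  snp_annotation(sprintf("snp%06d", seq_len(cfg$n_snps)), chroms, pos)
}

channels_from_copies <- function(copies_a, copies_b, kappa, cfg) {
  # expected signal proportional to copy number (diploid pair = base_signal);
  # zero-copy channels emit a noise floor so estimators face background
  r <- nrow(copies_a)
  c <- ncol(copies_a)
  e1 <- matrix(lognorm_noise(r * c, cfg$noise_cv), r, c)
  e2 <- matrix(lognorm_noise(r * c, cfg$noise_cv), r, c)
  base1 <- cfg$base_signal * pmax(copies_a / 2, cfg$noise_floor * (copies_a == 0))
  base2 <- cfg$base_signal * pmax(copies_b / 2, cfg$noise_floor * (copies_b == 0))
  list(s1 = kappa * base1 * e1, s2 = base2 * e2)
}

#' Simulate a cohort of individual genotyping experiments
#'
#' Per SNP: allele frequency `p_A ~ uniform(maf_range)`, genotype copy
#' counts `Binomial(2, p_A)` per sample (HWE), `CPA = exp(Normal(0,
#' cpa_log_sd^2))`; channel signals are `s1 = CPA * base * (copies_A / 2) *
#' noise`, `s2 = base * (copies_a / 2) * noise`, with the zero-copy noise
#' floor of [sim_config()]. Aberrations listed in the config are injected
#' afterwards within the same seeded stream. Identical seeds give identical
#' output.
#'
#' @param cfg a [sim_config()].
#' @return List of class `sim_cohort`: `annotation`, `genotypes`
#'   ([genotype_matrix()]), `intensity` ([intensity_table()]), `truth`
#'   (list: `p_a`, `cpa`, `copies_a` matrix, `aberrations`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ann <- sim_annotation(cfg)
  r <- cfg$n_snps
  n <- cfg$n_samples
  samples <- sprintf("sample%03d", seq_len(n))
  p_a <- stats::runif(r, cfg$maf_range[1], cfg$maf_range[2])
  copies_a <- matrix(stats::rbinom(r * n, 2L, rep(p_a, n)), r, n)
  kappa <- if (cfg$cpa_log_sd > 0) {
    exp(stats::rnorm(r, 0, cfg$cpa_log_sd))
  } else rep(1, r)
  ch <- channels_from_copies(copies_a, 2L - copies_a, kappa, cfg)
  calls <- matrix(c("aa", "Aa", "AA")[copies_a + 1L], r, n,
                  dimnames = list(ann$snp_id, samples))
  cohort <- structure(
    list(annotation = ann,
         genotypes = genotype_matrix(ann, samples, calls),
         intensity = intensity_table(ann, samples, ch$s1, ch$s2),
         truth = list(p_a = stats::setNames(p_a, ann$snp_id),
                      cpa = stats::setNames(kappa, ann$snp_id),
                      copies_a = `dimnames<-`(copies_a, list(ann$snp_id, samples)),
                      aberrations = list()),
         config = cfg),
    class = "sim_cohort")
  for (ab in cfg$aberrations) {
    cohort <- inject_aberration(cohort, ab$sample, ab$start_snp, ab$end_snp,
                                ab$a, ab$b, ab$p)
  }
  cohort
}

#' Inject an aberrant segment into one sample
#'
#' Within the region the sample becomes a mixture of `100 * p`% normal cells
#' (germline copies) and `100 * (1 - p)`% tumor cells carrying `a:b` copies
#' of its two germline alleles. For germline heterozygotes the tumor's `a`
#' copies go to a uniformly chosen allele (labelling is arbitrary); germline
#' homozygotes carry `a + b` copies of their single allele. Channel signals
#' are regenerated from the mixture copy numbers with fresh noise, so
#' expected frequencies follow [mixture_freqs()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param sample sample id to modify.
#' @param start_snp,end_snp global SNP index bounds (annotation order,
#'   1-based inclusive).
#' @param a,b tumor copy numbers.
#' @param p normal-cell fraction.
#' @return The modified `sim_cohort` (truth records the aberration).
#' @export
inject_aberration <- function(cohort, sample, start_snp, end_snp, a, b, p) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  j <- match(sample, cohort$intensity$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  if (start_snp < 1L || end_snp > cfg$n_snps || start_snp > end_snp) {
    stop("aberration range outside the panel")
  }
  rows <- start_snp:end_snp
  germ_a <- cohort$truth$copies_a[rows, j]
  germ_b <- 2L - germ_a
  # tumor copies per allele
  tum_a <- ifelse(germ_a == 2L, a + b, ifelse(germ_a == 0L, 0, NA))
  tum_b <- ifelse(germ_b == 2L, a + b, ifelse(germ_b == 0L, 0, NA))
  het <- germ_a == 1L
  if (any(het)) {
    first_is_a <- stats::runif(sum(het)) < 0.5
    tum_a[het] <- ifelse(first_is_a, a, b)
    tum_b[het] <- ifelse(first_is_a, b, a)
  }
  mix_a <- p * germ_a + (1 - p) * tum_a
  mix_b <- p * germ_b + (1 - p) * tum_b
  ch <- channels_from_copies(cbind(mix_a), cbind(mix_b),
                             cohort$truth$cpa[rows], cfg)
  cohort$intensity$s1[rows, j] <- ch$s1
  cohort$intensity$s2[rows, j] <- ch$s2
  cohort$truth$aberrations[[length(cohort$truth$aberrations) + 1L]] <-
    list(sample = sample, start_snp = start_snp, end_snp = end_snp,
         a = a, b = b, p = p)
  cohort
}

#' Pool intensities across samples
#'
#' The pooled channel signal is the sum of the member samples' signals
#' (mixing DNA adds material); optional pool-level multiplicative noise can
#' be re-drawn on top.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param samples nonempty character vector of member sample ids.
#' @param pool_noise_cv extra pool-level noise CV (default 0 = none).
#' @return A [pooled_intensity()] with one row per SNP.
#' @export
simulate_pool <- function(cohort, samples, pool_noise_cv = 0) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (length(samples) < 1L) stop("pool must contain at least one sample")
  j <- match(samples, cohort$intensity$samples)
  if (anyNA(j)) stop("unknown sample: ", samples[is.na(j)][1L])
  s1 <- rowSums(cohort$intensity$s1[, j, drop = FALSE])
  s2 <- rowSums(cohort$intensity$s2[, j, drop = FALSE])
  if (pool_noise_cv > 0) {
    s1 <- s1 * lognorm_noise(length(s1), pool_noise_cv)
    s2 <- s2 * lognorm_noise(length(s2), pool_noise_cv)
  }
  pooled_intensity(cohort$annotation$snp_id, s1, s2, length(samples))
}

#' Simulate an X-chromosome panel with hemizygous males
#'
#' Females follow standard HWE with two X copies; males carry a single X
#' allele per SNP, so the present allele's channel gets a single-copy
#' (half-dose) signal and the absent allele only the noise floor
#' (individual frequencies near 0/1, no true heterozygotes).
#'
#' @param cfg a [sim_config()]; `n_samples` is split `n_males` /
#'   `n_samples - n_males`.
#' @param n_males number of male samples (default half).
#' @return A `sim_cohort` on chromosome X whose truth gains a `sex` vector
#'   (`"M"`/`"F"`). Male genotype calls report the hemizygous allele as
#'   homozygous, as array callers do.
#' @export
simulate_sex_panel <- function(cfg, n_males = cfg$n_samples %/% 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_males < 0L || n_males > cfg$n_samples) stop("invalid n_males")
  set.seed(cfg$seed)
  cfg$chromosomes <- c(X = cfg$n_snps)
  ann <- sim_annotation(cfg)
  r <- cfg$n_snps
  n <- cfg$n_samples
  samples <- sprintf("sample%03d", seq_len(n))
  sex <- c(rep("M", n_males), rep("F", n - n_males))
  p_a <- stats::runif(r, cfg$maf_range[1], cfg$maf_range[2])
  copies_a <- matrix(0L, r, n)
  for (k in seq_len(n)) {
    copies_a[, k] <- if (sex[k] == "M") {
      stats::rbinom(r, 1L, p_a)          # one X
    } else {
      stats::rbinom(r, 2L, p_a)
    }
  }
  total <- ifelse(matrix(sex == "M", r, n, byrow = TRUE), 1L, 2L)
  kappa <- if (cfg$cpa_log_sd > 0) exp(stats::rnorm(r, 0, cfg$cpa_log_sd)) else rep(1, r)
  # hemizygous DNA is half the diploid dose: a male's present allele gets a
  # single-copy signal, so male frequencies sit slightly less extreme than
  # female homozygotes (larger relative background)
  ch <- channels_from_copies(copies_a, total - copies_a, kappa, cfg)
  calls <- ifelse(copies_a == total, "AA", ifelse(copies_a == 0L, "aa", "Aa"))
  dimnames(calls) <- list(ann$snp_id, samples)
  structure(list(annotation = ann,
                 genotypes = genotype_matrix(ann, samples, calls),
                 intensity = intensity_table(ann, samples, ch$s1, ch$s2),
                 truth = list(p_a = stats::setNames(p_a, ann$snp_id),
                              cpa = stats::setNames(kappa, ann$snp_id),
                              copies_a = `dimnames<-`(copies_a,
                                                      list(ann$snp_id, samples)),
                              sex = stats::setNames(sex, samples),
                              aberrations = list()),
                 config = cfg),
            class = "sim_cohort")
}

#' Simulate diverged populations for classification tests
#'
#' Draws an ancestral allele frequency per SNP, then population-specific
#' frequencies from the Balding-Nichols beta model with divergence `fst`,
#' and simulates one cohort per population on a shared panel and shared CPA
#' field.
#'
#' @param cfg a [sim_config()]; `n_samples` applies per population.
#' @param n_pops number of populations (default 2).
#' @param fst divergence parameter in `(0, 1)` (default 0.1).
#' @return List: `cohorts` (list of `sim_cohort`), `population` (named
#'   vector mapping sample id to population), with sample ids made unique
#'   across populations.
#' @export
simulate_populations <- function(cfg, n_pops = 2L, fst = 0.1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  set.seed(cfg$seed)
  r <- cfg$n_snps
  anc <- stats::runif(r, cfg$maf_range[1], cfg$maf_range[2])
  kappa <- if (cfg$cpa_log_sd > 0) exp(stats::rnorm(r, 0, cfg$cpa_log_sd)) else rep(1, r)
  shape <- (1 - fst) / fst
  cohorts <- vector("list", n_pops)
  pops <- character(0)
  for (k in seq_len(n_pops)) {
    p_k <- stats::rbeta(r, anc * shape, (1 - anc) * shape)
    p_k <- pmin(pmax(p_k, 1e-4), 1 - 1e-4)
    ann <- sim_annotation(cfg)
    n <- cfg$n_samples
    samples <- sprintf("pop%d_sample%03d", k, seq_len(n))
    copies_a <- matrix(stats::rbinom(r * n, 2L, rep(p_k, n)), r, n)
    ch <- channels_from_copies(copies_a, 2L - copies_a, kappa, cfg)
    calls <- matrix(c("aa", "Aa", "AA")[copies_a + 1L], r, n,
                    dimnames = list(ann$snp_id, samples))
    cohorts[[k]] <- structure(
      list(annotation = ann,
           genotypes = genotype_matrix(ann, samples, calls),
           intensity = intensity_table(ann, samples, ch$s1, ch$s2),
           truth = list(p_a = stats::setNames(p_k, ann$snp_id),
                        cpa = stats::setNames(kappa, ann$snp_id),
                        copies_a = `dimnames<-`(copies_a,
                                                list(ann$snp_id, samples)),
                        aberrations = list()),
           config = cfg),
      class = "sim_cohort")
    pops <- c(pops, stats::setNames(rep(paste0("pop", k), n), samples))
  }
  list(cohorts = cohorts, population = pops)
}

#' Bind the intensity tables of several cohorts on a shared panel
#'
#' @param cohorts list of `sim_cohort` objects sharing one annotation.
#' @return List with combined `intensity` and `genotypes`.
#' @export
combine_cohorts <- function(cohorts) {
  ann <- cohorts[[1L]]$annotation
  for (co in cohorts[-1L]) check_panel_alignment(ann, co$annotation)
  samples <- unlist(lapply(cohorts, function(co) co$intensity$samples))
  s1 <- do.call(cbind, lapply(cohorts, function(co) co$intensity$s1))
  s2 <- do.call(cbind, lapply(cohorts, function(co) co$intensity$s2))
  calls <- do.call(cbind, lapply(cohorts, function(co) co$genotypes$calls))
  list(intensity = intensity_table(ann, samples, s1, s2),
       genotypes = genotype_matrix(ann, samples, calls))
}
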