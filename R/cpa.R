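# Coefficient of preferential amplification/hybridization (CPA).
#
# On a two-channel SNP array the two alleles of a heterozygote are present in
# a true 1:1 ratio, so any systematic departure of the channel signals from
# 1:1 measures preferential amplification/hybridization. The per-SNP CPA is
# estimated as the ratio of channel means over heterozygous individuals and
# is later used to adjust intensity-based allele frequencies.

#' Estimate per-SNP CPA from heterozygotes
#'
#' For each SNP, the CPA estimate is the mean allele-A signal divided by the
#' mean allele-a signal over unmasked heterozygous samples. SNPs with fewer
#' than `min_het` usable heterozygotes fall back to `cpa = 1` (no adjustment)
#' with `fallback = TRUE`, so downstream frequency estimates always exist.
#' A zero heterozygote mean in the second channel yields a missing (never
#' infinite) estimate, flagged as fallback.
#'
#' The dispersion column `cv` is the coefficient of variation of the
#' per-heterozygote signal ratios `s1/s2` (SD of the ratios divided by the
#' ratio-of-means estimate), reported when `n_het >= 2`.
#'
#' @param intens an [intensity_table()].
#' @param genos a [genotype_matrix()] aligned with `intens` (same SNPs and
#'   samples).
#' @param min_het minimum heterozygote count for a direct estimate
#'   (default 3).
#' @return A [cpa_table()].
#' @examples
#' ann <- snp_annotation("rs1", "1", 100L)
#' it <- intensity_table(ann, c("a", "b"),
#'                       matrix(c(2, 4), 1), matrix(c(1, 2), 1))
#' gm <- genotype_matrix(ann, c("a", "b"), matrix("Aa", 1, 2))
#' estimate_cpa(it, gm, min_het = 1)$cpa  # 2
#' @export
estimate_cpa <- function(intens, genos, min_het = 3L) {
  stopifnot(inherits(intens, "intensity_table"),
            inherits(genos, "genotype_matrix"))
  if (min_het < 1L) stop("min_het must be >= 1")
  check_panel_alignment(intens$annotation, genos$annotation)
  if (!identical(intens$samples, genos$samples)) {
    stop("intensity and genotype tables carry different samples")
  }
  het <- genos$calls == "Aa" & !is.na(intens$s1)
  n_het <- rowSums(het)
  sum1 <- rowSums(intens$s1 * het, na.rm = TRUE)
  sum2 <- rowSums(intens$s2 * het, na.rm = TRUE)
  cpa <- ifelse(n_het > 0 & sum2 > 0 & sum1 > 0, sum1 / sum2, NA_real_)
  fallback <- n_het < min_het | is.na(cpa)
  # per-heterozygote ratio dispersion
  ratio <- intens$s1 / intens$s2
  ratio[!het | !is.finite(ratio)] <- NA_real_
  n_r <- rowSums(!is.na(ratio))
  mu_r <- rowSums(ratio, na.rm = TRUE) / pmax(n_r, 1L)
  ss <- rowSums((ratio - mu_r)^2, na.rm = TRUE)
  sd_r <- sqrt(ss / pmax(n_r - 1L, 1L))
  cv <- ifelse(n_r >= 2L & !is.na(cpa), sd_r / cpa, NA_real_)
  # too few heterozygotes -> no adjustment; inestimable at n_het >= min_het
  # (degenerate channel mean) stays missing but flagged
  cpa[n_het < min_het] <- 1
  cv[fallback] <- NA_real_
  cpa_table(intens$annotation$snp_id, cpa, n_het, cv, fallback)
}

check_panel_alignment <- function(a, b) {
  if (!identical(a$snp_id, b$snp_id)) {
    bad <- which(a$snp_id != b$snp_id | is.na(match(a$snp_id, b$snp_id)))
    first <- if (nrow(a) != nrow(b)) a$snp_id[1L] else a$snp_id[bad[1L]]
    stop("SNP panels are not aligned; first mismatching SNP: ", first)
  }
  invisible(TRUE)
}

#' Fit a lognormal distribution to genome-wide CPA
#'
#' Maximum-likelihood lognormal fit to the non-fallback CPA estimates
#' (equivalently a normal fit to `ln cpa`); the goodness of fit is the
#' Kolmogorov-Smirnov distance between the empirical CPA distribution and
#' the fitted CDF.
#'
#' @param cpa a [cpa_table()] with at least 10 non-fallback SNPs.
#' @return A list of class `lognormal_fit`: `mu`, `sigma` (parameters of the
#'   normal on the log scale), `n`, `gof`.
#' @export
fit_lognormal <- function(cpa) {
  stopifnot(inherits(cpa, "cpa_table"))
  x <- cpa$cpa[!cpa$fallback & !is.na(cpa$cpa)]
  if (length(x) < 10L) {
    stop("need >= 10 non-fallback CPA values to fit, got ", length(x))
  }
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))  # ML variant
  if (sigma == 0) stop("degenerate CPA sample: all values identical")
  gof <- unname(suppressWarnings(
    stats::ks.test(x, stats::plnorm, meanlog = mu, sdlog = sigma)$statistic))
  structure(list(mu = mu, sigma = sigma, n = length(x), gof = gof),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("lognormal CPA fit: mu = %.4f, sigma = %.4f (n = %d, KS = %.4f)\n",
              x$mu, x$sigma, x$n, x$gof))
  invisible(x)
}

#' Compare CPA tables between cohorts
#'
#' Pearson correlation of `log2(cpa)` over SNPs shared by the two tables
#' (fallback SNPs excluded from both sides). CPA is platform- and
#' cohort-specific, so this is the statistic used to judge whether one
#' cohort's CPA database is transferable to another.
#'
#' @param a,b [cpa_table()] objects with at least 3 shared non-fallback SNPs.
#' @return A list: `r` (Pearson correlation on log2 scale), `n_shared`.
#' @export
compare_cpa <- function(a, b) {
  stopifnot(inherits(a, "cpa_table"), inherits(b, "cpa_table"))
  au <- a[!a$fallback & !is.na(a$cpa), ]
  bu <- b[!b$fallback & !is.na(b$cpa), ]
  shared <- intersect(au$snp_id, bu$snp_id)
  if (length(shared) < 3L) {
    stop("need >= 3 shared non-fallback SNPs, got ", length(shared))
  }
  x <- au$log2_cpa[match(shared, au$snp_id)]
  y <- bu$log2_cpa[match(shared, bu$snp_id)]
  list(r = stats::cor(x, y), n_shared = length(shared))
}
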