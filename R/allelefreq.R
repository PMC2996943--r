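# Allele-frequency estimation.
#
# Individual-level frequency of allele A: 0, 0.5 or 1 from a genotype call
# (allele counting), or s1 / (s1 + cpa * s2) from CPA-adjusted channel
# intensities (intensity measuring). Population-level frequency: the average
# of individual-level frequencies over a cohort, or the adjusted relative
# intensity of a DNA pool.

#' Allele-counting individual frequency
#'
#' Maps a genotype call to the within-individual frequency of allele A:
#' `AA -> 1`, `Aa -> 0.5`, `aa -> 0`, `NoCall -> NA`. Vectorized.
#'
#' @param call character vector over `AA`, `Aa`, `aa`, `NoCall`.
#' @return Numeric vector in `{0, 0.5, 1, NA}`.
#' @export
freq_counting <- function(call) {
  map <- c(AA = 1, Aa = 0.5, aa = 0, NoCall = NA_real_)
  bad <- !(call %in% names(map))
  if (any(bad)) stop("unknown genotype call '", call[bad][1L], "'")
  unname(map[call])
}

#' Intensity-measuring individual frequency
#'
#' CPA-adjusted relative intensity of allele A:
#' `f = s1 / (s1 + cpa * s2)`, always in `[0, 1]`. Both channels zero gives
#' a missing value. Strictly increasing in `s1`, strictly decreasing in `s2`
#' and in `cpa` when both channels are positive.
#'
#' @param s1,s2 nonnegative channel intensities (vectorized).
#' @param cpa positive CPA value(s).
#' @return Numeric vector in `[0, 1]` (`NA` where both channels are zero or
#'   either is `NA`).
#' @examples
#' freq_intensity(2, 2, 2)  # 1/3
#' @export
freq_intensity <- function(s1, s2, cpa) {
  if (any(cpa <= 0, na.rm = TRUE)) stop("cpa must be positive")
  if (any(s1 < 0, na.rm = TRUE) || any(s2 < 0, na.rm = TRUE)) {
    stop("intensities must be nonnegative")
  }
  out <- s1 / (s1 + cpa * s2)
  out[!is.na(s1) & !is.na(s2) & s1 == 0 & s2 == 0] <- NA_real_
  out
}

#' Adjusted allele-frequency matrix
#'
#' Applies [freq_intensity()] element-wise using each SNP's CPA. Fallback
#' CPAs (`cpa = 1`) are used as-is; SNPs whose CPA is missing produce a
#' missing row with a warning. The missingness mask of the intensity table
#' is propagated.
#'
#' @param intens an [intensity_table()].
#' @param cpa a [cpa_table()] covering the same SNPs.
#' @return An [allele_freq_matrix()].
#' @export
freq_matrix <- function(intens, cpa) {
  stopifnot(inherits(intens, "intensity_table"), inherits(cpa, "cpa_table"))
  k <- cpa$cpa[match(intens$annotation$snp_id, cpa$snp_id)]
  if (anyNA(k)) {
    warning(sum(is.na(k)), " SNP(s) with missing CPA: frequencies set missing")
  }
  f <- intens$s1 / (intens$s1 + k * intens$s2)
  f[!is.na(intens$s1) & intens$s1 == 0 & intens$s2 == 0] <- NA_real_
  allele_freq_matrix(intens$annotation, intens$samples, f)
}

#' Population-level frequency from genotype calls
#'
#' Mean of allele-counting frequencies over called samples; the variance is
#' the binomial `p(1-p) / (2 n)` under Hardy-Weinberg equilibrium.
#'
#' @param calls character vector of genotype calls for one SNP.
#' @return List: `value`, `variance`, `n`, `method = "counting"`.
#' @export
popfreq_from_genotypes <- function(calls) {
  f <- freq_counting(calls)
  n <- sum(!is.na(f))
  if (n == 0L) {
    return(list(value = NA_real_, variance = NA_real_, n = 0L,
                method = "counting"))
  }
  p <- mean(f, na.rm = TRUE)
  list(value = p, variance = p * (1 - p) / (2 * n), n = n, method = "counting")
}

#' Population-level frequency from individual intensity-based frequencies
#'
#' Mean of the unmasked individual-level frequencies; the variance is the
#' empirical cross-sample variance of the mean (`var / n`, missing at
#' `n = 1`).
#'
#' @param freqs numeric vector of individual-level frequencies for one SNP.
#' @return List: `value`, `variance`, `n`, `method = "intensity"`.
#' @export
popfreq_from_intensities <- function(freqs) {
  x <- freqs[!is.na(freqs)]
  n <- length(x)
  if (n == 0L) {
    return(list(value = NA_real_, variance = NA_real_, n = 0L,
                method = "intensity"))
  }
  v <- if (n >= 2L) stats::var(x) / n else NA_real_
  list(value = mean(x), variance = v, n = n, method = "intensity")
}

#' Population-level frequency from a DNA pool
#'
#' Adjusted relative intensity of allele A in a pooled allelotyping
#' experiment: `s1_pool / (s1_pool + cpa * s2_pool)`.
#'
#' @param s1_pool,s2_pool nonnegative pooled channel intensities.
#' @param cpa positive CPA value(s).
#' @return List: `value`, `variance` (missing: a single pool carries no
#'   replicate information), `n = pool`, `method = "pooled"`. Vectorized over
#'   SNPs, in which case `value` is a vector.
#' @export
popfreq_pooled <- function(s1_pool, s2_pool, cpa) {
  v <- freq_intensity(s1_pool, s2_pool, cpa)
  list(value = v, variance = NA_real_, method = "pooled")
}

#' Per-SNP population frequencies for a whole panel
#'
#' Convenience wrapper applying [popfreq_from_genotypes()] or
#' [popfreq_from_intensities()] row-wise.
#'
#' @param x a [genotype_matrix()] or [allele_freq_matrix()].
#' @return data.frame: `snp_id`, `freq`, `variance`, `n`.
#' @export
popfreq_table <- function(x) {
  if (inherits(x, "genotype_matrix")) {
    f <- matrix(freq_counting(x$calls), nrow(x$calls))
  } else if (inherits(x, "allele_freq_matrix")) {
    f <- x$freq
  } else stop("x must be a genotype_matrix or allele_freq_matrix")
  n <- rowSums(!is.na(f))
  p <- rowMeans(f, na.rm = TRUE)
  p[n == 0L] <- NA_real_
  if (inherits(x, "genotype_matrix")) {
    v <- ifelse(n > 0L, p * (1 - p) / (2 * n), NA_real_)
  } else {
    ss <- rowSums((f - p)^2, na.rm = TRUE)
    v <- ifelse(n >= 2L, ss / (n - 1L) / n, NA_real_)
  }
  data.frame(snp_id = x$annotation$snp_id, freq = p, variance = v, n = n,
             stringsAsFactors = FALSE)
}
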