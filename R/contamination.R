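# Normal-cell contamination of tumor samples.
#
# A tumor sample is modelled as 100(1-p)% tumor cells, in which the two
# alleles of a germline-heterozygous SNP are present in ratio a:b, mixed
# with 100p% normal cells (ratio 1:1). The expected frequency of the first
# allele in the mixture is
#   f1 = (p + a (1-p)) / ((2 - (a+b)) p + (a+b)),
# and inverting gives
#   p = (a (1-f1) - b f1) / ((1-b) f1 - (1-a) f2),  f2 = 1 - f1,
# valid whenever (1-a) f2 != (1-b) f1. The hemizygous-deletion special case
# (a = 0, b = 1) reduces to f1 = p/(1+p) and p = f1/(1-f1).

#' Expected allele frequencies of a tumor/normal mixture
#'
#' @param a,b nonnegative tumor copy numbers of the first and second allele.
#' @param p normal-cell fraction in `[0, 1]`; `a`, `b`, `p` must not all be
#'   zero.
#' @return List: `f1`, `f2` (`f1 + f2 = 1`).
#' @examples
#' mixture_freqs(0, 1, 0.2)$f1  # 0.2/1.2, hemizygous deletion
#' @export
mixture_freqs <- function(a, b, p) {
  if (any(a < 0) || any(b < 0)) stop("copy numbers must be nonnegative")
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  if (any(a == 0 & b == 0 & p == 0)) stop("a, b and p cannot all be zero")
  den <- (2 - (a + b)) * p + (a + b)
  if (any(den <= 0)) stop("degenerate mixture: zero total copy number")
  list(f1 = (p + a * (1 - p)) / den,
       f2 = ((1 - b) * p + b) / den)
}

#' Invert the mixture model for the contamination fraction
#'
#' Closed-form inversion
#' `p = (a (1 - f1) - b f1) / ((1 - b) f1 - (1 - a) f2)` given the tumor
#' copy model `a:b` and the observed segment-average allele frequencies.
#' The raw estimate is reported alongside an in-range flag; values outside
#' `[0, 1]` are clipped only in the `p` element, never silently.
#'
#' @param f1 observed frequency of the first allele.
#' @param f2 observed frequency of the second allele (default `1 - f1`;
#'   must satisfy `f1 + f2 = 1` within `1e-6`).
#' @param a,b tumor copy numbers of the two alleles.
#' @return List: `p` (clipped to `[0, 1]`), `p_raw`, `in_range`.
#' @examples
#' estimate_contamination(0.190, a = 0, b = 1)$p  # 0.2346..., prints 0.235
#' @export
estimate_contamination <- function(f1, f2 = 1 - f1, a, b) {
  if (abs(f1 + f2 - 1) > 1e-6) stop("f1 + f2 must equal 1 (within 1e-6)")
  den <- (1 - b) * f1 - (1 - a) * f2
  if (abs(den) < 1e-12) {
    stop("degenerate model: (1 - a) * f2 equals (1 - b) * f1, ",
         "the inversion is undefined")
  }
  p_raw <- (a * (1 - f1) - b * f1) / den
  list(p = min(1, max(0, p_raw)), p_raw = p_raw,
       in_range = p_raw >= 0 && p_raw <= 1)
}

#' Contamination from a called aberrant segment
#'
#' Averages the folded allele frequencies (`min(f, 1 - f)`, keeping values
#' below 0.5 so the per-SNP arbitrary allele labelling cancels) over
#' germline-heterozygous SNPs inside the segment, then inverts the mixture
#' model. Needs at least `min_snps` usable SNPs, otherwise missing.
#'
#' @param freqs patient [allele_freq_matrix()].
#' @param calls germline [genotype_matrix()] on the same panel.
#' @param sample sample id to analyse.
#' @param chromosome,start,end segment bounds (1-based inclusive positions).
#' @param a,b tumor copy model (default `0:1`, hemizygous deletion).
#' @param min_snps minimum usable heterozygous SNPs (default 10).
#' @return List: `p`, `p_raw`, `in_range`, `f1`, `n_snps`; all `NA` with
#'   `n_snps` when too few SNPs qualify.
#' @export
segment_contamination <- function(freqs, calls, sample, chromosome, start, end,
                                  a = 0L, b = 1L, min_snps = 10L) {
  stopifnot(inherits(freqs, "allele_freq_matrix"),
            inherits(calls, "genotype_matrix"))
  check_panel_alignment(freqs$annotation, calls$annotation)
  j <- match(sample, freqs$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  ann <- freqs$annotation
  in_seg <- ann$chromosome == chromosome & ann$position >= start &
    ann$position <= end
  het <- calls$calls[, match(sample, calls$samples)] == "Aa"
  f <- freqs$freq[in_seg & het, j]
  f <- f[!is.na(f)]
  folded <- pmin(f, 1 - f)
  folded <- folded[folded < 0.5]
  if (length(folded) < min_snps) {
    return(list(p = NA_real_, p_raw = NA_real_, in_range = NA,
                f1 = NA_real_, n_snps = length(folded)))
  }
  # folding keeps the lower band; orient it to whichever allele the copy
  # model a:b predicts below 0.5 (per-SNP allele labelling is arbitrary)
  f_low <- mean(folded)
  f1 <- if (a <= b) f_low else 1 - f_low
  est <- estimate_contamination(f1, 1 - f1, a, b)
  c(est, list(f1 = f1, n_snps = length(folded)))
}
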