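#' @keywords internal
"_PACKAGE"

CHROM_LEVELS <- c(as.character(1:22), "X")
GENO_LEVELS <- c("AA", "Aa", "aa", "NoCall")

#' SNP annotation table
#'
#' Builds the per-SNP annotation used by every container in the package:
#' identifier, chromosome (autosomes 1-22 and X), 1-based physical position,
#' and the two allele labels. Records are sorted deterministically by
#' chromosome (natural order 1..22, X), position, then `snp_id` as a stable
#' tie-break.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chromosome character vector, values in `1..22` or `"X"`.
#' @param position integer vector of base-pair positions, all `>= 1`.
#' @param allele_a,allele_b single-character nucleotide labels for the A
#'   (first-channel) and a (second-channel) allele.
#' @return A `data.frame` of class `snp_annotation` with columns `snp_id`,
#'   `chromosome`, `position`, `allele_a`, `allele_b`, sorted as above.
#' @examples
#' snp_annotation(c("rs2", "rs1"), c("1", "1"), c(200L, 100L), "A", "G")
#' @export
snp_annotation <- function(snp_id, chromosome, position,
                           allele_a = "A", allele_b = "B") {
  snp_id <- as.character(snp_id)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  n <- length(snp_id)
  allele_a <- rep_len(as.character(allele_a), n)
  allele_b <- rep_len(as.character(allele_b), n)
  if (anyDuplicated(snp_id)) {
    stop("snp_id values must be unique; first duplicate: ",
         snp_id[duplicated(snp_id)][1L])
  }
  bad <- !(chromosome %in% CHROM_LEVELS)
  if (any(bad)) {
    stop("unsupported chromosome '", chromosome[bad][1L],
         "' (supported: 1-22, X)")
  }
  if (any(is.na(position)) || any(position < 1L)) {
    stop("positions must be integers >= 1")
  }
  ann <- data.frame(snp_id = snp_id, chromosome = chromosome,
                    position = position, allele_a = allele_a,
                    allele_b = allele_b, stringsAsFactors = FALSE)
  ord <- order(match(ann$chromosome, CHROM_LEVELS), ann$position, ann$snp_id)
  ann <- ann[ord, , drop = FALSE]
  rownames(ann) <- NULL
  class(ann) <- c("snp_annotation", "data.frame")
  ann
}

as_annotation_order <- function(x, annotation) {
  # reorder a snp_id-named matrix/frame into annotation order
  idx <- match(annotation$snp_id, rownames(x))
  if (anyNA(idx)) {
    stop("SNPs missing from data: ", annotation$snp_id[is.na(idx)][1L])
  }
  x[idx, , drop = FALSE]
}

check_matrix_vs_annotation <- function(m, annotation, samples, what) {
  if (!is.matrix(m)) stop(what, " must be a matrix")
  if (nrow(m) != nrow(annotation)) {
    stop(what, ": ", nrow(m), " rows but annotation has ",
         nrow(annotation), " SNPs")
  }
  if (ncol(m) != length(samples)) {
    stop(what, ": ", ncol(m), " columns but ", length(samples), " samples")
  }
  dimnames(m) <- list(annotation$snp_id, samples)
  m
}

#' Two-channel intensity table
#'
#' Container for per-(SNP, sample) allele-A and allele-a signals from an
#' individual genotyping experiment. Missing entries are `NA` in both
#' channels simultaneously (an explicit mask); a zero intensity is data,
#' not missingness.
#'
#' @param annotation a [snp_annotation()].
#' @param samples character vector of sample identifiers.
#' @param s1,s2 numeric matrices (SNPs x samples) of nonnegative allele-A and
#'   allele-a intensities. `NA` marks a masked entry and must coincide in the
#'   two channels.
#' @return An object of class `intensity_table` (list with elements
#'   `annotation`, `samples`, `s1`, `s2`).
#' @export
intensity_table <- function(annotation, samples, s1, s2) {
  stopifnot(inherits(annotation, "snp_annotation"))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  s1 <- check_matrix_vs_annotation(s1, annotation, samples, "s1")
  s2 <- check_matrix_vs_annotation(s2, annotation, samples, "s2")
  if (!identical(is.na(s1), is.na(s2))) {
    stop("mask mismatch: s1 and s2 must be NA at the same entries")
  }
  if (any(s1 < 0, na.rm = TRUE) || any(s2 < 0, na.rm = TRUE)) {
    stop("negative intensities are not allowed")
  }
  if (any(is.infinite(s1)) || any(is.infinite(s2))) {
    stop("intensities must be finite")
  }
  structure(list(annotation = annotation, samples = samples, s1 = s1, s2 = s2),
            class = "intensity_table")
}

#' Genotype call matrix
#'
#' @param annotation a [snp_annotation()].
#' @param samples character vector of sample ids.
#' @param calls character matrix over `AA`, `Aa`, `aa`, `NoCall`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(annotation, samples, calls) {
  stopifnot(inherits(annotation, "snp_annotation"))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  calls <- check_matrix_vs_annotation(calls, annotation, samples, "calls")
  bad <- !(calls %in% GENO_LEVELS)
  if (any(bad)) {
    stop("unknown genotype code '", calls[bad][1L],
         "' (expected AA/Aa/aa/NoCall)")
  }
  structure(list(annotation = annotation, samples = samples, calls = calls),
            class = "genotype_matrix")
}

#' Individual-level allele-frequency matrix
#'
#' @param annotation a [snp_annotation()].
#' @param samples character vector of sample ids.
#' @param freq numeric matrix in `[0, 1]`; `NA` marks missing entries.
#' @return An object of class `allele_freq_matrix`.
#' @export
allele_freq_matrix <- function(annotation, samples, freq) {
  stopifnot(inherits(annotation, "snp_annotation"))
  samples <- as.character(samples)
  freq <- check_matrix_vs_annotation(freq, annotation, samples, "freq")
  if (any(!is.na(freq))) {
    rng <- range(freq, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) stop("allele frequencies must lie in [0, 1]")
  }
  structure(list(annotation = annotation, samples = samples, freq = freq),
            class = "allele_freq_matrix")
}

#' Per-SNP CPA table
#'
#' Holds the coefficient of preferential amplification/hybridization (CPA)
#' for each SNP: the signal produced per copy of allele A relative to allele
#' a, estimated from heterozygotes (true allele ratio 1:1).
#'
#' @param snp_id character vector.
#' @param cpa positive CPA estimates (`NA` when inestimable).
#' @param n_het integer count of heterozygotes used per SNP.
#' @param cv coefficient of variation of the per-heterozygote signal ratios
#'   (`NA` when `n_het < 2`).
#' @param fallback logical; `TRUE` where the estimate fell back to `cpa = 1`
#'   (too few heterozygotes) or is missing.
#' @return A `data.frame` of class `cpa_table` with columns `snp_id`, `cpa`,
#'   `log2_cpa`, `n_het`, `cv`, `fallback`.
#' @export
cpa_table <- function(snp_id, cpa, n_het, cv = NA_real_, fallback = FALSE) {
  snp_id <- as.character(snp_id)
  n <- length(snp_id)
  out <- data.frame(snp_id = snp_id,
                    cpa = as.numeric(cpa),
                    log2_cpa = log2(as.numeric(cpa)),
                    n_het = as.integer(rep_len(n_het, n)),
                    cv = as.numeric(rep_len(cv, n)),
                    fallback = rep_len(as.logical(fallback), n),
                    stringsAsFactors = FALSE)
  if (any(out$cpa <= 0, na.rm = TRUE)) stop("CPA values must be positive")
  class(out) <- c("cpa_table", "data.frame")
  out
}

#' Pooled-allelotyping intensity pairs
#'
#' One row per SNP: the two channel intensities measured on a DNA pool of
#' `pool_size` individuals.
#'
#' @param snp_id character vector.
#' @param s1_pool,s2_pool nonnegative pooled intensities (`NA` = missing).
#' @param pool_size integer `>= 1`, recycled.
#' @return A `data.frame` of class `pooled_intensity`.
#' @export
pooled_intensity <- function(snp_id, s1_pool, s2_pool, pool_size) {
  out <- data.frame(snp_id = as.character(snp_id),
                    s1_pool = as.numeric(s1_pool),
                    s2_pool = as.numeric(s2_pool),
                    pool_size = as.integer(rep_len(pool_size, length(snp_id))),
                    stringsAsFactors = FALSE)
  if (any(out$pool_size < 1L)) stop("pool_size must be >= 1")
  if (any(out$s1_pool < 0, na.rm = TRUE) || any(out$s2_pool < 0, na.rm = TRUE)) {
    stop("pooled intensities must be nonnegative")
  }
  class(out) <- c("pooled_intensity", "data.frame")
  out
}

#' @export
print.intensity_table <- function(x, ...) {
  cat("intensity_table:", nrow(x$annotation), "SNPs x",
      length(x$samples), "samples;",
      sum(is.na(x$s1)), "masked entries\n")
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$annotation), "SNPs x",
      length(x$samples), "samples;",
      sum(x$calls == "NoCall"), "NoCall\n")
  invisible(x)
}

#' @export
print.allele_freq_matrix <- function(x, ...) {
  cat("allele_freq_matrix:", nrow(x$annotation), "SNPs x",
      length(x$samples), "samples;",
      sum(is.na(x$freq)), "missing\n")
  invisible(x)
}
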