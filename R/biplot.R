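# Rank-2 allele-frequency biplot.
#
# The SNPs x samples frequency matrix A is row-centred (each SNP's mean
# across samples subtracted) and decomposed by a thin SVD, F = P D Q'. The
# first two columns of the SNP-effect and sample-effect matrices place SNPs
# and samples on one plane: with R = P, C = Q D' (SNP-effect flavor) or
# R = P D, C = Q (sample-effect flavor), F ~ R2 C2' is the best rank-2
# approximation. Samples with similar allele-frequency profiles cluster
# together, which supports population classification, sex grouping and
# outlier screening.

#' Row-centre an allele-frequency matrix
#'
#' Computes `F = A - rowMeans(A)`: every SNP row gets mean zero across
#' samples. Missing entries are imputed by the SNP's cross-sample mean
#' first (they become exact zeros in `F`, neutral under the SVD); SNPs
#' missing in all samples are dropped with a warning.
#'
#' @param freqs an [allele_freq_matrix()] (or bare numeric matrix) with at
#'   least 2 SNPs and 2 samples.
#' @return A numeric matrix with zero row means, row/column names kept.
#' @export
center_matrix <- function(freqs) {
  a <- if (inherits(freqs, "allele_freq_matrix")) freqs$freq else as.matrix(freqs)
  if (nrow(a) < 2L || ncol(a) < 2L) stop("need >= 2 SNPs and >= 2 samples")
  all_na <- rowSums(!is.na(a)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " SNP(s) missing in all samples dropped")
    a <- a[!all_na, , drop = FALSE]
  }
  rm <- rowMeans(a, na.rm = TRUE)
  idx <- which(is.na(a), arr.ind = TRUE)
  if (nrow(idx)) a[idx] <- rm[idx[, 1L]]
  a - rm
}

#' Rank-2 allele-frequency biplot decomposition
#'
#' Thin SVD of the row-centred matrix with a deterministic sign convention
#' (the largest-magnitude entry of each left singular vector is made
#' positive). Coordinates follow the requested flavor: `snp_effect` scales
#' the sample side by the singular values, `sample_effect` scales the SNP
#' side, so in both cases `snp_coords %*% t(sample_coords)` is the best
#' rank-2 approximation of `F`.
#'
#' @param freqs an [allele_freq_matrix()] or an already-centred matrix.
#' @param flavor `"sample_effect"` (default) or `"snp_effect"`.
#' @return Object of class `af_biplot`: `singular_values`, `snp_coords`
#'   (R x 2), `sample_coords` (C x 2), `flavor`, `explained` (fraction of
#'   squared Frobenius norm in rank 2), `rank_deficient` flag.
#' @export
af_biplot <- function(freqs, flavor = c("sample_effect", "snp_effect")) {
  flavor <- match.arg(flavor)
  f <- if (is.matrix(freqs) && !inherits(freqs, "allele_freq_matrix")) {
    freqs
  } else {
    center_matrix(freqs)
  }
  if (any(!is.finite(f))) stop("centred matrix must be finite")
  sv <- svd(f)
  # reproducible sign convention
  for (k in seq_along(sv$d)) {
    i <- which.max(abs(sv$u[, k]))
    if (sv$u[i, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  d <- sv$d
  rank_deficient <- sum(d > max(d[1L], 0) * 1e-12) < 2L
  take <- function(m, scale = NULL) {
    out <- m[, 1:2, drop = FALSE]
    if (ncol(out) < 2L) out <- cbind(out, 0)
    if (!is.null(scale)) out <- sweep(out, 2L, scale[1:2], `*`)
    out
  }
  if (flavor == "snp_effect") {
    snp_coords <- take(sv$u)
    sample_coords <- take(sv$v, d)
  } else {
    snp_coords <- take(sv$u, d)
    sample_coords <- take(sv$v)
  }
  rownames(snp_coords) <- rownames(f)
  rownames(sample_coords) <- colnames(f)
  colnames(snp_coords) <- colnames(sample_coords) <- c("dim1", "dim2")
  tot <- sum(d^2)
  structure(list(singular_values = d,
                 snp_coords = snp_coords,
                 sample_coords = sample_coords,
                 flavor = flavor,
                 explained = if (tot > 0) sum(d[1:2]^2) / tot else 0,
                 rank_deficient = rank_deficient),
            class = "af_biplot")
}

#' @export
print.af_biplot <- function(x, ...) {
  cat(sprintf("af_biplot (%s): %d SNPs x %d samples, rank-2 explains %.1f%%\n",
              x$flavor, nrow(x$snp_coords), nrow(x$sample_coords),
              100 * x$explained))
  invisible(x)
}

#' Robust biplot outlier detection
#'
#' Each sample's 2-D coordinate is standardised coordinate-wise by the
#' median and MAD; samples whose squared robust distance exceeds the
#' `1 - alpha` chi-square(2) quantile are flagged. Degenerate inputs (all
#' samples at one point) yield no outliers.
#'
#' @param result an [af_biplot()] with at least 5 samples.
#' @param alpha flagging level (default 0.01).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
detect_outliers <- function(result, alpha = 0.01) {
  stopifnot(inherits(result, "af_biplot"))
  x <- result$sample_coords
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (nrow(x) < 5L) stop("need >= 5 samples for outlier detection")
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (all(apply(x, 2L, function(c) diff(range(c)) == 0))) return(character())
  d2 <- rep(0, nrow(x))
  for (k in 1:2) {
    med <- stats::median(x[, k])
    s <- stats::mad(x[, k])
    if (s == 0) s <- stats::sd(x[, k])
    if (s == 0) next
    d2 <- d2 + ((x[, k] - med) / s)^2
  }
  thr <- stats::qchisq(1 - alpha, df = 2)
  rownames(x)[d2 >= thr]
}

#' Classify samples from biplot coordinates
#'
#' K-means on the 2-D sample coordinates with a fixed seed and 10 restarts,
#' reported with the mean silhouette width.
#'
#' @param result an [af_biplot()].
#' @param k number of clusters, `2 <= k <= n_samples`.
#' @param seed RNG seed for the k-means restarts (default 1).
#' @return List: `labels` (named integer vector), `silhouette` (mean
#'   silhouette width, `NA` when `k == n`), `centers`.
#' @export
classify_samples <- function(result, k, seed = 1L) {
  stopifnot(inherits(result, "af_biplot"))
  x <- result$sample_coords
  n <- nrow(x)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  if (k == n) {                      # each sample its own cluster
    return(list(labels = stats::setNames(seq_len(n), rownames(x)),
                silhouette = NA_real_, centers = x))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 10L)
  labels <- stats::setNames(km$cluster, rownames(x))
  list(labels = labels, silhouette = mean_silhouette(x, km$cluster),
       centers = km$centers)
}

mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1L)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
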