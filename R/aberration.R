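# Chromosomal-aberration detection.
#
# Normal controls define, per SNP and per genotype, a reference band
# mean +/- z * sd for the individual-level allele frequency. A patient SNP is
# an allelic-imbalance (AI) point when its frequency falls outside all three
# genotype bands, and an LOH/LCSH point when it falls outside the
# heterozygote band. Sliding windows turn the 0/1 point flags into AI and
# LOH indices in [0, 1]; smoothed patient indices are compared against the
# per-anchor 95% quantile of normal-control indices and sufficiently long
# runs of exceedance become called segments.

GENO3 <- c("AA", "Aa", "aa")

#' Genotype-specific reference bands from normal controls
#'
#' For every SNP and genotype class present in at least two reference
#' samples, computes the reference mean and standard deviation of the
#' individual-level allele frequency. The band is `mean +/- z * sd` with the
#' SD floored at `sd_floor` so constant reference values still yield a band
#' of positive width.
#'
#' @param freqs an [allele_freq_matrix()] of normal controls.
#' @param calls the matching [genotype_matrix()].
#' @param z band half-width in SD units (default 3).
#' @param sd_floor minimum SD after flooring (default 0.01).
#' @return An object of class `reference_bands`: `annotation`, `mean`, `sd`,
#'   `n` (each a SNPs x 3 matrix with columns `AA`, `Aa`, `aa`), `z`,
#'   `sd_floor`. Missing bands are `NA`.
#' @export
build_reference_bands <- function(freqs, calls, z = 3, sd_floor = 0.01) {
  stopifnot(inherits(freqs, "allele_freq_matrix"),
            inherits(calls, "genotype_matrix"))
  check_panel_alignment(freqs$annotation, calls$annotation)
  if (z <= 0) stop("z must be positive")
  if (sd_floor <= 0) stop("sd_floor must be positive")
  r <- nrow(freqs$freq)
  mean_m <- sd_m <- matrix(NA_real_, r, 3L,
                           dimnames = list(freqs$annotation$snp_id, GENO3))
  n_m <- matrix(0L, r, 3L, dimnames = dimnames(mean_m))
  for (g in GENO3) {
    use <- calls$calls == g & !is.na(freqs$freq)
    n_g <- rowSums(use)
    f0 <- freqs$freq
    f0[!use] <- 0
    s <- rowSums(f0)
    mu <- ifelse(n_g > 0L, s / n_g, NA_real_)
    ss <- rowSums((f0 - ifelse(is.na(mu), 0, mu))^2 * use)
    sdev <- ifelse(n_g >= 2L, sqrt(ss / (n_g - 1L)), NA_real_)
    ok <- n_g >= 2L
    mean_m[ok, g] <- mu[ok]
    sd_m[ok, g] <- pmax(sdev[ok], sd_floor)
    n_m[, g] <- n_g
  }
  structure(list(annotation = freqs$annotation, mean = mean_m, sd = sd_m,
                 n = n_m, z = z, sd_floor = sd_floor),
            class = "reference_bands")
}

#' Single-point AI and LOH flags
#'
#' `ai = 1` where the patient frequency lies outside every available
#' genotype band; `loh = 1` where it lies outside the heterozygote (`Aa`)
#' band. Flags are `NA` where the frequency is masked, where a SNP has no
#' bands at all (AI), or where the `Aa` band is missing (LOH).
#'
#' @param freqs patient [allele_freq_matrix()] on the reference panel.
#' @param bands a [build_reference_bands()] result.
#' @return An object of class `point_flags`: `annotation`, `samples`, `ai`
#'   and `loh` (0/1/NA matrices).
#' @export
flag_points <- function(freqs, bands) {
  stopifnot(inherits(freqs, "allele_freq_matrix"),
            inherits(bands, "reference_bands"))
  check_panel_alignment(freqs$annotation, bands$annotation)
  f <- freqs$freq
  inside_any <- matrix(FALSE, nrow(f), ncol(f))
  n_bands <- rowSums(!is.na(bands$mean))
  lo_aa <- bands$mean[, "Aa"] - bands$z * bands$sd[, "Aa"]
  hi_aa <- bands$mean[, "Aa"] + bands$z * bands$sd[, "Aa"]
  for (g in GENO3) {
    lo <- bands$mean[, g] - bands$z * bands$sd[, g]
    hi <- bands$mean[, g] + bands$z * bands$sd[, g]
    ins <- f >= lo & f <= hi
    ins[is.na(ins)] <- FALSE
    inside_any <- inside_any | ins
  }
  ai <- (!inside_any) * 1
  ai[is.na(f)] <- NA_real_
  ai[n_bands == 0L, ] <- NA_real_
  loh <- (f < lo_aa | f > hi_aa) * 1
  loh[is.na(f)] <- NA_real_
  loh[is.na(lo_aa), ] <- NA_real_
  dimnames(ai) <- dimnames(loh) <- dimnames(f)
  structure(list(annotation = freqs$annotation, samples = freqs$samples,
                 ai = ai, loh = loh),
            class = "point_flags")
}

chrom_blocks <- function(annotation) {
  split(seq_len(nrow(annotation)), factor(annotation$chromosome,
                                          levels = CHROM_LEVELS), drop = TRUE)
}

window_mean_matrix <- function(x, rows, half) {
  # sliding mean of 0/1 flags over a symmetric window, NA-aware:
  # missing flags leave both numerator and denominator
  v <- x[rows, , drop = FALSE]
  obs <- !is.na(v)
  v0 <- v
  v0[!obs] <- 0
  n <- length(rows)
  cs_v <- apply(rbind(0, v0), 2L, cumsum)
  cs_n <- apply(rbind(0, obs), 2L, cumsum)
  m <- seq_len(n)
  h <- pmin(half, m - 1L, n - m)   # symmetric truncation at chromosome ends
  lo <- m - h
  hi <- m + h
  num <- cs_v[hi + 1L, , drop = FALSE] - cs_v[lo, , drop = FALSE]
  den <- cs_n[hi + 1L, , drop = FALSE] - cs_n[lo, , drop = FALSE]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Sliding-window AI and LOH indices
#'
#' For each anchor SNP `m`, the AI index is the fraction of flagged AI points
#' among non-missing flags in the window centred on `m`, and likewise for the
#' LOH index; windows slide one SNP at a time and are truncated symmetrically
#' at chromosome ends (the half-width shrinks so the window stays centred).
#'
#' @param flags a [flag_points()] result (SNPs position-sorted, which the
#'   annotation guarantees).
#' @param window_size odd window size in SNPs (default 51).
#' @return An object of class `window_track`: `annotation`, `samples`,
#'   `ai`, `loh` (index matrices), `window_size`, and `NULL` smoothed slots.
#' @export
window_indices <- function(flags, window_size = 51L) {
  stopifnot(inherits(flags, "point_flags"))
  window_size <- as.integer(window_size)
  if (window_size < 1L || window_size %% 2L == 0L) {
    stop("window_size must be a positive odd integer")
  }
  half <- (window_size - 1L) %/% 2L
  ai <- flags$ai
  loh <- flags$loh
  ai_idx <- loh_idx <- matrix(NA_real_, nrow(ai), ncol(ai),
                              dimnames = dimnames(ai))
  for (rows in chrom_blocks(flags$annotation)) {
    ai_idx[rows, ] <- window_mean_matrix(ai, rows, half)
    loh_idx[rows, ] <- window_mean_matrix(loh, rows, half)
  }
  structure(list(annotation = flags$annotation, samples = flags$samples,
                 ai = ai_idx, loh = loh_idx, window_size = window_size,
                 ai_smooth = NULL, loh_smooth = NULL),
            class = "window_track")
}

smooth_one <- function(pos, y, spar) {
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y)
  if (sum(ok) < 10L) {            # too few anchors: fall back to raw
    return(y)
  }
  fit <- if (is.null(spar)) {
    stats::smooth.spline(pos[ok], y[ok], cv = FALSE)   # GCV penalty
  } else {
    stats::smooth.spline(pos[ok], y[ok], spar = spar)
  }
  out[ok] <- pmin(1, pmax(0, stats::predict(fit, pos[ok])$y))
  out
}

#' Smooth window-index tracks
#'
#' Cubic smoothing spline of each index against physical position, fitted
#' per chromosome and per sample; the penalty is chosen by generalized
#' cross-validation unless `smoothing_param` (the `spar` of
#' [stats::smooth.spline()]) is given. Chromosomes with fewer than 10
#' non-missing anchors keep the raw track. Smoothed values are clipped to
#' `[0, 1]`.
#'
#' @param track a [window_indices()] result.
#' @param smoothing_param optional spline `spar` in `(0, 1]`.
#' @return The track with `ai_smooth` and `loh_smooth` filled in.
#' @export
smooth_track <- function(track, smoothing_param = NULL) {
  stopifnot(inherits(track, "window_track"))
  ai_s <- loh_s <- matrix(NA_real_, nrow(track$ai), ncol(track$ai),
                          dimnames = dimnames(track$ai))
  pos <- track$annotation$position
  for (rows in chrom_blocks(track$annotation)) {
    for (j in seq_along(track$samples)) {
      ai_s[rows, j] <- smooth_one(pos[rows], track$ai[rows, j], smoothing_param)
      loh_s[rows, j] <- smooth_one(pos[rows], track$loh[rows, j], smoothing_param)
    }
  }
  track$ai_smooth <- ai_s
  track$loh_smooth <- loh_s
  track
}

control_quantile <- function(m, prob = 0.95) {
  # per-anchor empirical quantile across control columns; with fewer than
  # 20 controls the quantile is the control maximum
  if (ncol(m) < 20L) {
    apply(m, 1L, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  } else {
    apply(m, 1L, function(x) {
      if (all(is.na(x))) NA_real_ else
        stats::quantile(x, prob, na.rm = TRUE, type = 7, names = FALSE)
    })
  }
}

segments_from_runs <- function(exceed, rows, annotation, index, min_run,
                               whole_chrom_frac, label, sample) {
  e <- exceed[rows]
  e[is.na(e)] <- FALSE
  r <- rle(e)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  if (!any(keep)) return(NULL)
  n_chr <- length(rows)
  out <- lapply(which(keep), function(k) {
    i0 <- rows[starts[k]]
    i1 <- rows[ends[k]]
    data.frame(sample = sample,
               chromosome = annotation$chromosome[i0],
               start = annotation$position[i0],
               end = annotation$position[i1],
               label = label,
               mean_index = mean(index[rows[starts[k]:ends[k]]], na.rm = TRUE),
               n_snps = r$lengths[k],
               whole_chromosome = r$lengths[k] >= whole_chrom_frac * n_chr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

empty_calls <- function() {
  structure(data.frame(sample = character(), chromosome = character(),
                       start = integer(), end = integer(),
                       label = character(), mean_index = numeric(),
                       n_snps = integer(), whole_chromosome = logical(),
                       stringsAsFactors = FALSE),
            class = c("aberration_calls", "data.frame"))
}

#' Call aberrant regions against normal-control quantiles
#'
#' Per anchor SNP, a patient exceeds when its smoothed index is strictly
#' greater than the smoothed per-anchor 95% empirical quantile of the
#' control raw indices (the envelope is the quantile track of the raw
#' control indices, spline-smoothed along the chromosome exactly like the
#' patient track). Maximal runs of at least `min_run` consecutive
#' exceeding anchors become segments spanning the first to last anchor
#' position; a segment covering at least `whole_chrom_frac` of a
#' chromosome's SNPs is labelled whole-chromosome. AI and LOH are called
#' independently.
#'
#' Computing the quantile on the raw indices before smoothing (rather than
#' on the controls' smoothed tracks) keeps the window-scale sampling noise
#' of the control cohort inside the envelope, which is what gives the
#' caller its specificity: a patient drawn from the same model as the
#' controls has a smoothed track well below the raw-index quantile almost
#' everywhere.
#'
#' @param patient a [window_track()] for one or more patient samples
#'   (smoothed automatically if needed).
#' @param controls a `window_track` of at least 5 normal controls on the
#'   same panel.
#' @param min_run minimum run length in anchors (default
#'   `2 * window_size + 1`). The window index is a moving average, so
#'   exceedance events are correlated over about one window; a minimum run
#'   below the window size lets single window-scale fluctuations qualify as
#'   segments, while a run of twice the window cannot be produced by one
#'   such fluctuation.
#' @param whole_chrom_frac fraction of a chromosome's SNPs above which a
#'   segment is whole-chromosome (default 0.9).
#' @param smoothing_param passed to [smooth_track()] when tracks are raw.
#' @return An `aberration_calls` data.frame: `sample`, `chromosome`, `start`,
#'   `end`, `label` (`AI`/`LOH`), `mean_index`, `n_snps`, `whole_chromosome`.
#' @export
call_regions <- function(patient, controls, min_run = NULL,
                         whole_chrom_frac = 0.9, smoothing_param = NULL) {
  stopifnot(inherits(patient, "window_track"), inherits(controls, "window_track"))
  check_panel_alignment(patient$annotation, controls$annotation)
  if (length(controls$samples) < 5L) {
    stop("need >= 5 control tracks for a stable 95% quantile, got ",
         length(controls$samples))
  }
  if (is.null(min_run)) min_run <- 2L * patient$window_size + 1L
  if (min_run < 1L) stop("min_run must be >= 1")
  if (is.null(patient$ai_smooth)) patient <- smooth_track(patient, smoothing_param)
  blocks <- chrom_blocks(patient$annotation)
  # envelope: per-anchor 95% quantile of the RAW control indices, then
  # smoothed along each chromosome like any other track
  q_ai <- control_quantile(controls$ai)
  q_loh <- control_quantile(controls$loh)
  pos <- patient$annotation$position
  for (rows in blocks) {
    q_ai[rows] <- smooth_one(pos[rows], q_ai[rows], smoothing_param)
    q_loh[rows] <- smooth_one(pos[rows], q_loh[rows], smoothing_param)
  }
  segs <- list()
  for (j in seq_along(patient$samples)) {
    ex_ai <- patient$ai_smooth[, j] > q_ai
    ex_loh <- patient$loh_smooth[, j] > q_loh
    for (rows in blocks) {
      segs[[length(segs) + 1L]] <-
        segments_from_runs(ex_ai, rows, patient$annotation, patient$ai[, j],
                           min_run, whole_chrom_frac, "AI", patient$samples[j])
      segs[[length(segs) + 1L]] <-
        segments_from_runs(ex_loh, rows, patient$annotation, patient$loh[, j],
                           min_run, whole_chrom_frac, "LOH", patient$samples[j])
    }
  }
  segs <- segs[!vapply(segs, is.null, logical(1L))]
  if (!length(segs)) return(empty_calls())
  out <- do.call(rbind, segs)
  out <- out[order(out$sample, match(out$chromosome, CHROM_LEVELS),
                   out$start, out$label), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aberration_calls", "data.frame")
  out
}

#' Subset a window track by sample
#'
#' @param track a `window_track`.
#' @param samples sample ids to keep.
#' @return A `window_track` restricted to `samples`.
#' @export
track_subset <- function(track, samples) {
  stopifnot(inherits(track, "window_track"))
  j <- match(samples, track$samples)
  if (anyNA(j)) stop("unknown sample: ", samples[is.na(j)][1L])
  track$samples <- track$samples[j]
  for (f in c("ai", "loh", "ai_smooth", "loh_smooth")) {
    if (!is.null(track[[f]])) track[[f]] <- track[[f]][, j, drop = FALSE]
  }
  track
}

#' Cohort aberration summary
#'
#' Per-sample AI/LOH presence and whole-chromosome counts, with cohort
#' fractions as percentages (two decimals, matching conventional reporting).
#'
#' @param calls an `aberration_calls` object.
#' @param samples complete character vector of scanned samples (samples with
#'   no calls must be counted in the denominators).
#' @return List: `n_samples`, `n_ai`, `pct_ai`, `n_loh`, `pct_loh`,
#'   `n_whole_chrom_ai`, `pct_whole_chrom_ai_of_ai`, `per_sample`
#'   (data.frame, deterministic sample order).
#' @export
aberration_report <- function(calls, samples) {
  stopifnot(inherits(calls, "aberration_calls"))
  if (length(samples) < 1L) stop("need >= 1 sample")
  samples <- sort(unique(as.character(samples)))
  per <- data.frame(sample = samples,
                    has_ai = samples %in% calls$sample[calls$label == "AI"],
                    has_loh = samples %in% calls$sample[calls$label == "LOH"],
                    has_whole_chrom_ai = samples %in%
                      calls$sample[calls$label == "AI" & calls$whole_chromosome],
                    stringsAsFactors = FALSE)
  n <- length(samples)
  n_ai <- sum(per$has_ai)
  n_loh <- sum(per$has_loh)
  n_wc <- sum(per$has_whole_chrom_ai)
  pct <- function(num, den) if (den == 0L) 0 else round(100 * num / den, 2)
  list(n_samples = n, n_ai = n_ai, pct_ai = pct(n_ai, n),
       n_loh = n_loh, pct_loh = pct(n_loh, n),
       n_whole_chrom_ai = n_wc,
       pct_whole_chrom_ai_of_ai = pct(n_wc, n_ai),
       per_sample = per)
}
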