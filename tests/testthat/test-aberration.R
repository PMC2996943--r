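# aberration: reference bands, point flags, window indices, smoothing,
# region calling, cohort report

band_fixture <- function(freq, calls, z = 3, sd_floor = 0.01) {
  n <- ncol(freq)
  ann <- tiny_annotation(nrow(freq))
  samples <- sprintf("s%02d", seq_len(n))
  build_reference_bands(allele_freq_matrix(ann, samples, freq),
                        genotype_matrix(ann, samples, calls),
                        z = z, sd_floor = sd_floor)
}

test_that("reference bands reproduce hand-computed mean and sd", {
  b <- band_fixture(rbind(c(0.49, 0.51)), rbind(c("Aa", "Aa")))
  expect_equal(b$mean[1, "Aa"], 0.5)
  expect_equal(b$sd[1, "Aa"], sd(c(0.49, 0.51)))
  expect_equal(b$n[1, "Aa"], 2L)
  expect_true(is.na(b$mean[1, "AA"]))      # class absent -> band missing

  # constant reference values floor at sd_floor
  b2 <- band_fixture(rbind(c(0.5, 0.5, 0.5)), rbind(c("Aa", "Aa", "Aa")))
  expect_equal(b2$sd[1, "Aa"], 0.01)

  # single sample in a class -> band missing
  b3 <- band_fixture(rbind(c(0.5, 0.98)), rbind(c("Aa", "AA")))
  expect_true(is.na(b3$mean[1, "Aa"]))
  expect_true(is.na(b3$mean[1, "AA"]))
})

make_bands <- function(centers = c(aa = 0.02, Aa = 0.5, AA = 0.98),
                       halfwidth = 0.06, n_snps = 1L) {
  # bands centered as given with z * sd = halfwidth (z = 3, sd = hw / 3)
  freq <- NULL
  calls <- NULL
  for (g in c("aa", "Aa", "AA")) {
    freq <- cbind(freq, matrix(rep(centers[g] + c(-1, 1) * halfwidth / 3 / 2,
                                   n_snps),
                               n_snps, 2, byrow = TRUE))
    calls <- cbind(calls, matrix(g, n_snps, 2))
  }
  # two reference samples per genotype, sd = halfwidth/3 by construction
  sdv <- sd(c(-1, 1) * halfwidth / 3 / 2)
  b <- band_fixture(freq, calls, z = halfwidth / sdv, sd_floor = 1e-6)
  b
}

test_that("point flags follow the three-band interval logic", {
  b <- make_bands()
  ann <- tiny_annotation(1)
  f <- function(v) allele_freq_matrix(ann, "p", matrix(v))
  # outside all three bands -> AI and LOH
  fl <- flag_points(f(0.25), b)
  expect_equal(unname(fl$ai[1, 1]), 1)
  expect_equal(unname(fl$loh[1, 1]), 1)
  # inside the heterozygote band -> neither
  fl <- flag_points(f(0.5), b)
  expect_equal(unname(fl$ai[1, 1]), 0)
  expect_equal(unname(fl$loh[1, 1]), 0)
  # inside AA band, outside Aa band -> LOH-compatible, not AI
  fl <- flag_points(f(0.99), b)
  expect_equal(unname(fl$ai[1, 1]), 0)
  expect_equal(unname(fl$loh[1, 1]), 1)
  # masked frequency -> missing flags
  fl <- flag_points(f(NA_real_), b)
  expect_true(is.na(fl$ai[1, 1]))
  expect_true(is.na(fl$loh[1, 1]))
})

test_that("window indices equal direct arithmetic and respect bounds", {
  ann <- tiny_annotation(5)
  flags <- structure(list(annotation = ann, samples = "p",
                          ai = matrix(c(1, 1, 0, 0, 0)),
                          loh = matrix(c(1, 1, 1, 1, 1))),
                     class = "point_flags")
  dimnames(flags$ai) <- dimnames(flags$loh) <- list(ann$snp_id, "p")
  tr <- window_indices(flags, window_size = 5L)
  expect_equal(unname(tr$ai[3, 1]), 0.4)        # (1+1+0+0+0)/5
  expect_equal(unname(tr$loh[, 1]), rep(1, 5))  # all ones -> 1 everywhere
  zero <- flags
  zero$loh[] <- 0
  expect_equal(unname(window_indices(zero, 5L)$loh[, 1]), rep(0, 5))
  expect_error(window_indices(flags, 4L), "odd")
})

test_that("window indices match a brute-force recount with NAs and chromosomes", {
  set.seed(71)
  for (rep in 1:30) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    w <- sample(c(3L, 5L, 9L, 21L), 1)
    ann <- snp_annotation(sprintf("m%03d", seq_len(n1 + n2)),
                          rep(c("3", "11"), c(n1, n2)),
                          c(seq_len(n1), seq_len(n2)) * 100L)
    a <- matrix(sample(c(0, 1, NA), (n1 + n2) * 2, TRUE, c(.4, .4, .2)),
                ncol = 2, dimnames = list(ann$snp_id, c("x", "y")))
    flags <- structure(list(annotation = ann, samples = c("x", "y"),
                            ai = a, loh = a),
                       class = "point_flags")
    got <- window_indices(flags, w)$ai
    half <- (w - 1L) %/% 2L
    want <- a
    for (block in split(seq_len(n1 + n2), rep(1:2, c(n1, n2)))) {
      nn <- length(block)
      for (m in seq_len(nn)) {
        h <- min(half, m - 1L, nn - m)
        vals <- a[block[(m - h):(m + h)], , drop = FALSE]
        want[block[m], ] <- colMeans(vals, na.rm = TRUE)
      }
    }
    want[is.nan(want)] <- NA
    expect_equal(got, want)
  }
})

test_that("smoothing reproduces constants, falls back when short, stays in [0,1]", {
  n <- 60L
  ann <- snp_annotation(sprintf("m%03d", 1:n), rep("2", n), (1:n) * 1000L)
  const <- structure(list(annotation = ann, samples = "p",
                          ai = matrix(0.3, n, 1, dimnames = list(ann$snp_id, "p")),
                          loh = matrix(0.3, n, 1, dimnames = list(ann$snp_id, "p")),
                          window_size = 5L, ai_smooth = NULL, loh_smooth = NULL),
                     class = "window_track")
  sm <- smooth_track(const)
  expect_equal(unname(sm$ai_smooth[, 1]), rep(0.3, n), tolerance = 1e-6)

  # 9-anchor chromosome: smoothed equals raw
  short <- const
  short$annotation <- snp_annotation(sprintf("m%03d", 1:9), rep("2", 9),
                                     (1:9) * 1000L)
  short$ai <- short$ai[1:9, , drop = FALSE]
  short$loh <- short$loh[1:9, , drop = FALSE]
  short$ai[5, 1] <- 0.9
  expect_equal(smooth_track(short)$ai_smooth, short$ai)

  # step input: smoothed stays within [0, 1] and rises across the step
  step <- const
  step$ai[] <- rep(c(0.02, 0.95), each = n / 2)
  out <- smooth_track(step)$ai_smooth[, 1]
  expect_true(all(out >= 0 & out <= 1))
  expect_lt(mean(out[1:20]), 0.2)
  expect_gt(mean(out[41:60]), 0.8)
})

test_that("a patient identical to a control is never called", {
  w <- scan_world(81, n_snps = 600, n_ref = 20, n_ctl = 6, n_pat = 0)
  flags <- flag_points(w$freqs, w$bands)
  tr <- smooth_track(window_indices(flags, 21L))
  ctl <- track_subset(tr, w$ctl_samples)
  pat <- track_subset(tr, w$ctl_samples[1])   # one of the controls itself
  calls <- call_regions(pat, ctl, min_run = 11L)
  expect_equal(nrow(calls), 0L)
  expect_error(call_regions(pat, track_subset(tr, w$ctl_samples[1:4])),
               ">= 5 control")
})

test_that("an embedded deletion yields AI and LOH segments near the truth", {
  w <- scan_world(91, n_snps = 1200, n_ref = 30, n_ctl = 40, n_pat = 10,
                  aberrations = list(list(sample = "sample071",
                                          start_snp = 400, end_snp = 700,
                                          a = 0, b = 1, p = 0.2)))
  flags <- flag_points(w$freqs, w$bands)
  tr <- smooth_track(window_indices(flags, 51L))
  calls <- call_regions(track_subset(tr, "sample071"),
                        track_subset(tr, w$ctl_samples))
  ts <- 400 * 10000
  te <- 700 * 10000
  for (lab in c("AI", "LOH")) {
    g <- calls[calls$label == lab, ]
    ov <- pmax(0, pmin(g$end, te) - pmax(g$start, ts))
    expect_true(any(ov > 0), label = paste(lab, "segment found"))
    best <- which.max(ov)
    expect_lt(abs(g$start[best] - ts) / 10000, 51)
    expect_lt(abs(g$end[best] - te) / 10000, 51)
  }
})

test_that("whole-chromosome trisomy-like imbalance is labelled whole_chromosome", {
  w <- scan_world(101, n_snps = 1200, n_ref = 30, n_ctl = 40, n_pat = 5,
                  aberrations = list(list(sample = "sample071",
                                          start_snp = 1, end_snp = 1200,
                                          a = 2, b = 1, p = 0)))
  flags <- flag_points(w$freqs, w$bands)
  tr <- smooth_track(window_indices(flags, 51L))
  calls <- call_regions(track_subset(tr, "sample071"),
                        track_subset(tr, w$ctl_samples))
  ai <- calls[calls$label == "AI", ]
  expect_gt(nrow(ai), 0)
  expect_true(any(ai$whole_chromosome))
})

test_that("aberration report computes printed-style percentages", {
  calls <- structure(
    data.frame(sample = c("s1", "s1"), chromosome = "1",
               start = c(1L, 500L), end = c(400L, 900L),
               label = c("AI", "LOH"), mean_index = 0.5, n_snps = 40L,
               whole_chromosome = c(TRUE, FALSE), stringsAsFactors = FALSE),
    class = c("aberration_calls", "data.frame"))
  rep2 <- aberration_report(calls, samples = c("s1", "s2"))
  expect_equal(rep2$pct_ai, 50)
  expect_equal(rep2$pct_loh, 50)
  expect_equal(rep2$n_whole_chrom_ai, 1L)
  empty <- aberration_report(calls[0, ], samples = c("s1", "s2"))
  expect_equal(empty$pct_ai, 0)
})
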