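# Static plots: three-band allele-frequency plot, three-panel chromosomal
# aberration plot (frequency / AI / LOH), and the rank-2 biplot. Plotting is
# decorative relative to the analysis: CLI callers wrap these in tryCatch and
# only warn on failure.

#' Individual-level allele-frequency plot
#'
#' Frequencies against physical position (Mb) with guide lines at the three
#' normal bands 0, 0.5 and 1; AI points can be highlighted.
#'
#' @param freqs an [allele_freq_matrix()].
#' @param sample sample id to plot.
#' @param chromosome optional chromosome to restrict to.
#' @param flags optional [flag_points()] result; AI points drawn in red.
#' @export
plot_allele_freq <- function(freqs, sample, chromosome = NULL, flags = NULL) {
  j <- match(sample, freqs$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  ann <- freqs$annotation
  keep <- if (is.null(chromosome)) rep(TRUE, nrow(ann)) else
    ann$chromosome == chromosome
  x <- ann$position[keep] / 1e6
  y <- freqs$freq[keep, j]
  col <- rep("steelblue", length(y))
  if (!is.null(flags)) {
    a <- flags$ai[keep, j]
    col[!is.na(a) & a == 1] <- "red"
  }
  graphics::plot(x, y, pch = 20, cex = 0.4, col = col, ylim = c(0, 1),
                 xlab = "Physical position (Mb)", ylab = "Allele frequency",
                 main = paste0(sample,
                               if (!is.null(chromosome)) paste0(" chr", chromosome)))
  graphics::abline(h = c(0, 0.5, 1), lty = 3, col = "grey50")
  invisible(NULL)
}

#' Three-panel chromosomal aberration plot
#'
#' Top: extended allele-frequency plot (AI SNPs red). Middle: AI window index
#' of the patient (red) with the control 95% quantile (blue). Bottom: the
#' same for the LOH index.
#'
#' @param freqs patient [allele_freq_matrix()].
#' @param sample patient sample id.
#' @param patient_track smoothed patient `window_track`.
#' @param control_track smoothed control `window_track`.
#' @param flags [flag_points()] result for the patient panel.
#' @param chromosome chromosome to display.
#' @export
plot_aberration <- function(freqs, sample, patient_track, control_track,
                            flags, chromosome) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(old))
  plot_allele_freq(freqs, sample, chromosome, flags)
  ann <- patient_track$annotation
  keep <- ann$chromosome == chromosome
  x <- ann$position[keep] / 1e6
  j <- match(sample, patient_track$samples)
  for (what in c("ai", "loh")) {
    y <- patient_track[[paste0(what, "_smooth")]][keep, j]
    q <- smooth_one(ann$position[keep],
                    control_quantile(control_track[[what]][keep, , drop = FALSE]),
                    NULL)
    graphics::plot(x, y, type = "l", col = "red", ylim = c(0, 1),
                   xlab = "Physical position (Mb)",
                   ylab = paste(toupper(what), "index"))
    graphics::lines(x, q, col = "blue")
  }
  invisible(NULL)
}

#' Rank-2 allele-frequency biplot plot
#'
#' Samples as labelled points over a faint SNP layer, coloured by optional
#' group labels.
#'
#' @param result an [af_biplot()].
#' @param groups optional named vector of group labels per sample.
#' @export
plot_biplot <- function(result, groups = NULL) {
  s <- result$sample_coords
  g <- result$snp_coords
  # put both layers on comparable scales
  sc <- max(abs(g)) / max(max(abs(s)), .Machine$double.eps)
  graphics::plot(g[, 1], g[, 2], pch = 20, cex = 0.3, col = "grey80",
                 xlab = "Component 1", ylab = "Component 2",
                 main = paste0("Allele-frequency biplot (", result$flavor, ")"))
  col <- if (is.null(groups)) "red" else
    as.integer(factor(groups[rownames(s)])) + 1L
  graphics::points(s[, 1] * sc, s[, 2] * sc, pch = 19, col = col)
  invisible(NULL)
}
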