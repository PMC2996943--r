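# Tab-delimited readers/writers for every table the tool consumes or emits.
# All formats are plain text; internal coordinates are 1-based inclusive and
# only the BED export converts to 0-based half-open.

read_tsv_base <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

write_tsv_base <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read / write SNP annotation
#'
#' Annotation TSV columns: `snp_id`, `chr`, `pos`, `alleleA`, `alleleB`.
#'
#' @param path file path.
#' @return [read_snp_annotation()] returns a [snp_annotation()].
#' @export
read_snp_annotation <- function(path) {
  df <- read_tsv_base(path)
  need <- c("snp_id", "chr", "pos", "alleleA", "alleleB")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  snp_annotation(df$snp_id, df$chr, df$pos, df$alleleA, df$alleleB)
}

#' @rdname read_snp_annotation
#' @param annotation a [snp_annotation()] to write.
#' @export
write_snp_annotation <- function(annotation, path) {
  write_tsv_base(data.frame(snp_id = annotation$snp_id,
                            chr = annotation$chromosome,
                            pos = annotation$position,
                            alleleA = annotation$allele_a,
                            alleleB = annotation$allele_b), path)
  invisible(path)
}

#' Read a two-channel intensity table
#'
#' Two dialects are supported. `"long"`: columns `snp_id`, `sample_id`, `s1`,
#' `s2`, one row per (SNP, sample) pair; pairs absent from the file are
#' masked. `"wide"`: a `snp_id` column followed by paired `<sample>.s1` /
#' `<sample>.s2` columns; `NA` cells are masked.
#'
#' @param path file path.
#' @param annotation a [snp_annotation()] covering every SNP in the file.
#' @param dialect `"long"` or `"wide"`.
#' @return An [intensity_table()] sorted by (chromosome, position, snp_id).
#' @export
read_intensity_table <- function(path, annotation, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  df <- read_tsv_base(path)
  if (dialect == "long") {
    need <- c("snp_id", "sample_id", "s1", "s2")
    if (!all(need %in% names(df))) {
      stop("long-form intensity file must have columns: ",
           paste(need, collapse = ", "))
    }
    key <- paste(df$snp_id, df$sample_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- df[duplicated(key), ][1L, ]
      stop("duplicate (snp, sample) row: ", d$snp_id, " / ", d$sample_id)
    }
    neg <- which(df$s1 < 0 | df$s2 < 0)
    if (length(neg)) {
      stop("negative intensity in row for SNP ", df$snp_id[neg[1L]],
           ", sample ", df$sample_id[neg[1L]])
    }
    unknown <- setdiff(df$snp_id, annotation$snp_id)
    if (length(unknown)) stop("SNP not in annotation: ", unknown[1L])
    samples <- sort(unique(df$sample_id))
    r <- nrow(annotation)
    s1 <- matrix(NA_real_, r, length(samples),
                 dimnames = list(annotation$snp_id, samples))
    s2 <- s1
    i <- match(df$snp_id, annotation$snp_id)
    j <- match(df$sample_id, samples)
    s1[cbind(i, j)] <- df$s1
    s2[cbind(i, j)] <- df$s2
  } else {
    if (names(df)[1L] != "snp_id") stop("wide form must start with snp_id")
    cols <- names(df)[-1L]
    is_s1 <- grepl("\\.s1$", cols)
    is_s2 <- grepl("\\.s2$", cols)
    if (!all(is_s1 | is_s2)) stop("wide columns must end in .s1 or .s2")
    samples <- unique(sub("\\.s[12]$", "", cols))
    unknown <- setdiff(df$snp_id, annotation$snp_id)
    if (length(unknown)) stop("SNP not in annotation: ", unknown[1L])
    rn <- df$snp_id
    s1 <- as.matrix(df[, paste0(samples, ".s1"), drop = FALSE])
    s2 <- as.matrix(df[, paste0(samples, ".s2"), drop = FALSE])
    dimnames(s1) <- dimnames(s2) <- list(rn, samples)
    if (any(s1 < 0, na.rm = TRUE) || any(s2 < 0, na.rm = TRUE)) {
      bad <- which(s1 < 0 | s2 < 0, arr.ind = TRUE)
      stop("negative intensity for SNP ", rn[bad[1L, 1L]])
    }
    s1 <- as_annotation_order(s1, annotation)
    s2 <- as_annotation_order(s2, annotation)
  }
  # a half-masked pair is promoted to fully masked
  m <- is.na(s1) | is.na(s2)
  s1[m] <- NA_real_
  s2[m] <- NA_real_
  intensity_table(annotation, samples, s1, s2)
}

#' @rdname read_intensity_table
#' @param x an [intensity_table()] to write.
#' @export
write_intensity_table <- function(x, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    keep <- !is.na(x$s1)
    idx <- which(keep, arr.ind = TRUE)
    df <- data.frame(snp_id = rownames(x$s1)[idx[, 1L]],
                     sample_id = colnames(x$s1)[idx[, 2L]],
                     s1 = x$s1[keep], s2 = x$s2[keep])
    df <- df[order(match(df$snp_id, x$annotation$snp_id), df$sample_id), ]
    write_tsv_base(df, path)
  } else {
    out <- data.frame(snp_id = x$annotation$snp_id)
    for (s in x$samples) {
      out[[paste0(s, ".s1")]] <- x$s1[, s]
      out[[paste0(s, ".s2")]] <- x$s2[, s]
    }
    write_tsv_base(out, path)
  }
  invisible(path)
}

#' Read / write a genotype matrix
#'
#' File layout: a `snp_id` column followed by one column per sample with
#' codes `AA`, `AB`, `BB`, `NC` (mapped internally to `AA`, `Aa`, `aa`,
#' `NoCall`). Round trips are lossless.
#'
#' @param path file path.
#' @param annotation a [snp_annotation()].
#' @return [read_genotype_matrix()] returns a [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, annotation) {
  df <- read_tsv_base(path)
  if (names(df)[1L] != "snp_id") stop("genotype file must start with snp_id")
  unknown <- setdiff(df$snp_id, annotation$snp_id)
  if (length(unknown)) stop("SNP not in annotation: ", unknown[1L])
  samples <- names(df)[-1L]
  m <- as.matrix(df[, -1L, drop = FALSE])
  code_map <- c(AA = "AA", AB = "Aa", BB = "aa", NC = "NoCall")
  bad <- !(m %in% names(code_map))
  if (any(bad)) {
    row <- which(bad)[1L] %% nrow(m)
    row <- if (row == 0L) nrow(m) else row
    stop("unknown genotype code '", m[bad][1L], "' at SNP ", df$snp_id[row])
  }
  calls <- matrix(code_map[m], nrow(m), ncol(m),
                  dimnames = list(df$snp_id, samples))
  calls <- as_annotation_order(calls, annotation)
  genotype_matrix(annotation, samples, calls)
}

#' @rdname read_genotype_matrix
#' @param x a [genotype_matrix()] to write.
#' @export
write_genotype_matrix <- function(x, path) {
  rev_map <- c(AA = "AA", Aa = "AB", aa = "BB", NoCall = "NC")
  out <- data.frame(snp_id = x$annotation$snp_id)
  coded <- matrix(rev_map[x$calls], nrow(x$calls), ncol(x$calls))
  for (k in seq_along(x$samples)) out[[x$samples[k]]] <- coded[, k]
  write_tsv_base(out, path)
  invisible(path)
}

#' Read / write an allele-frequency matrix
#'
#' Layout: `snp_id` column plus one numeric column per sample; empty/`NA`
#' cells are missing.
#'
#' @param path file path.
#' @param annotation a [snp_annotation()].
#' @export
read_allele_freq_matrix <- function(path, annotation) {
  df <- read_tsv_base(path)
  if (names(df)[1L] != "snp_id") stop("frequency file must start with snp_id")
  unknown <- setdiff(df$snp_id, annotation$snp_id)
  if (length(unknown)) stop("SNP not in annotation: ", unknown[1L])
  samples <- names(df)[-1L]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$snp_id
  m <- as_annotation_order(m, annotation)
  allele_freq_matrix(annotation, samples, m)
}

#' @rdname read_allele_freq_matrix
#' @param x an [allele_freq_matrix()] to write.
#' @export
write_allele_freq_matrix <- function(x, path) {
  out <- data.frame(snp_id = x$annotation$snp_id)
  for (k in seq_along(x$samples)) out[[x$samples[k]]] <- x$freq[, k]
  write_tsv_base(out, path)
  invisible(path)
}

#' Read / write a CPA database table
#'
#' TSV columns: `snp_id`, `chr`, `pos`, `cpa`, `log2_cpa`, `n_het`, `cv`,
#' `fallback` (the genomic columns come from the annotation; `fallback` is
#' tolerated absent on read, defaulting to `FALSE`).
#'
#' @param path file path.
#' @export
read_cpa_table <- function(path) {
  df <- read_tsv_base(path)
  need <- c("snp_id", "cpa", "n_het")
  if (!all(need %in% names(df))) {
    stop("CPA file must have columns: ", paste(need, collapse = ", "))
  }
  fb <- if ("fallback" %in% names(df)) as.logical(df$fallback) else FALSE
  cv <- if ("cv" %in% names(df)) df$cv else NA_real_
  cpa_table(df$snp_id, df$cpa, df$n_het, cv, fb)
}

#' @rdname read_cpa_table
#' @param x a [cpa_table()].
#' @param annotation optional [snp_annotation()] supplying `chr`/`pos`.
#' @export
write_cpa_table <- function(x, path, annotation = NULL) {
  out <- data.frame(snp_id = x$snp_id)
  if (!is.null(annotation)) {
    i <- match(x$snp_id, annotation$snp_id)
    out$chr <- annotation$chromosome[i]
    out$pos <- annotation$position[i]
  }
  out$cpa <- x$cpa
  out$log2_cpa <- x$log2_cpa
  out$n_het <- x$n_het
  out$cv <- x$cv
  out$fallback <- x$fallback
  write_tsv_base(out, path)
  invisible(path)
}

#' Read / write pooled-allelotyping intensities
#'
#' TSV columns: `snp_id`, `s1_pool`, `s2_pool`, `pool_size`.
#'
#' @param path file path.
#' @export
read_pooled_intensity <- function(path) {
  df <- read_tsv_base(path)
  need <- c("snp_id", "s1_pool", "s2_pool", "pool_size")
  if (!all(need %in% names(df))) {
    stop("pool file must have columns: ", paste(need, collapse = ", "))
  }
  pooled_intensity(df$snp_id, df$s1_pool, df$s2_pool, df$pool_size)
}

#' @rdname read_pooled_intensity
#' @param x a [pooled_intensity()].
#' @export
write_pooled_intensity <- function(x, path) {
  write_tsv_base(as.data.frame(x), path)
  invisible(path)
}

#' Export aberration calls as BED
#'
#' Internal segments are 1-based inclusive; BED output is 0-based half-open.
#' The name field is `<label>|<sample>`. Overlapping or abutting segments
#' with the same label and sample are merged with a warning. Output is
#' sorted by chromosome (natural order), then start.
#'
#' @param calls an `aberration_calls` object (see [call_regions()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(calls, path) {
  segs <- as.data.frame(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tstart\tend\tname\tscore\tstrand", con)
  if (nrow(segs) == 0L) return(invisible(path))
  merged <- list()
  did_merge <- FALSE
  for (key in unique(paste(segs$sample, segs$label, segs$chromosome, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    g <- segs[segs$sample == parts[1L] & segs$label == parts[2L] &
                segs$chromosome == parts[3L], , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    cur <- g[1L, , drop = FALSE]
    for (r in seq_len(nrow(g))[-1L]) {
      if (g$start[r] <= cur$end + 1L) {           # overlap or abutting
        cur$end <- max(cur$end, g$end[r])
        cur$mean_index <- mean(c(cur$mean_index, g$mean_index[r]))
        did_merge <- TRUE
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- g[r, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  if (did_merge) warning("overlapping same-label segments merged in BED export")
  out <- do.call(rbind, merged)
  out <- out[order(match(out$chromosome, CHROM_LEVELS), out$start), , drop = FALSE]
  bed <- data.frame(chrom = paste0("chr", out$chromosome),
                    start = out$start - 1L,       # to 0-based half-open
                    end = out$end,
                    name = paste(out$label, out$sample, sep = "|"),
                    score = pmin(1000L, as.integer(round(out$mean_index * 1000))),
                    strand = ".")
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
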