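# core_io: domain types, annotation ordering, TSV readers/writers, BED export

test_that("annotation sorts by natural chromosome order, position, snp_id", {
  ann <- snp_annotation(c("b", "a", "c", "d"),
                        c("10", "2", "X", "2"),
                        c(500L, 900L, 100L, 900L))
  expect_equal(ann$snp_id, c("a", "d", "b", "c"))  # chr2 (tie on pos -> id), 10, X
  expect_equal(ann$chromosome, c("2", "2", "10", "X"))
  expect_error(snp_annotation(c("a", "a"), "1", c(1L, 2L)), "unique")
  expect_error(snp_annotation("a", "chrMT", 1L), "chromosome")
  expect_error(snp_annotation("a", "1", 0L), ">= 1")
})

test_that("intensity table validates shape, mask coincidence and sign", {
  ann <- tiny_annotation(2)
  s <- matrix(1:4, 2, 2)
  expect_error(intensity_table(ann, "x", s, s), "columns")
  m1 <- matrix(c(1, NA, 3, 4), 2, 2)
  m2 <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_error(intensity_table(ann, c("x", "y"), m1, m2), "mask")
  expect_error(intensity_table(ann, c("x", "y"), -m2, m2), "negative")
})

test_that("long-form intensity reader round-trips and validates", {
  it <- random_intensity(seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(it, path, dialect = "long")
  back <- read_intensity_table(path, it$annotation, dialect = "long")
  expect_equal(back$s1, it$s1)
  expect_equal(back$s2, it$s2)
  expect_identical(back$samples, it$samples)

  # duplicate row rejected, negative intensity named
  df <- utils::read.delim(path)
  utils::write.table(rbind(df, df[1, ]), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_intensity_table(path, it$annotation, "long"), "duplicate")
  df$s1[3] <- -1
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_intensity_table(path, it$annotation, "long"),
               "negative intensity")
})

test_that("wide-form intensity reader round-trips with masks", {
  it <- random_intensity(seed = 9, mask_frac = 0.25)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(it, path, dialect = "wide")
  back <- read_intensity_table(path, it$annotation, dialect = "wide")
  expect_equal(back$s1, it$s1)
  expect_equal(back$s2, it$s2)
})

test_that("genotype matrix codes map losslessly, unknown codes rejected", {
  gm <- random_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_matrix(gm, path)
  raw <- utils::read.delim(path, check.names = FALSE)
  expect_true(all(unlist(raw[, -1]) %in% c("AA", "AB", "BB", "NC")))
  back <- read_genotype_matrix(path, gm$annotation)
  expect_identical(back$calls, gm$calls)

  raw[2, 3] <- "XY"
  utils::write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_genotype_matrix(path, gm$annotation), "unknown genotype")
})

test_that("AB and NC map to Aa and NoCall", {
  ann <- tiny_annotation(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\ts01\ts02", "rs01\tAB\tNC"), path)
  gm <- read_genotype_matrix(path, ann)
  expect_identical(unname(gm$calls[1, ]), c("Aa", "NoCall"))
})

test_that("allele-frequency and CPA tables round-trip", {
  ann <- tiny_annotation(6)
  set.seed(3)
  f <- matrix(runif(18), 6, 3)
  f[2, 2] <- NA
  fm <- allele_freq_matrix(ann, c("a", "b", "c"), f)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_allele_freq_matrix(fm, path)
  back <- read_allele_freq_matrix(path, ann)
  expect_equal(back$freq, fm$freq)

  cpa <- cpa_table(ann$snp_id, c(0.5, 1, 2, 1, 4, 1), 5:10,
                   cv = 0.1, fallback = c(FALSE, TRUE, rep(FALSE, 4)))
  write_cpa_table(cpa, path, ann)
  back <- read_cpa_table(path)
  expect_equal(back$cpa, cpa$cpa)
  expect_equal(back$log2_cpa, log2(cpa$cpa))
  expect_identical(back$fallback, cpa$fallback)
})

test_that("pooled intensity round-trips and validates pool size", {
  pi <- pooled_intensity(c("rs1", "rs2"), c(10, 0), c(5, 7), 240L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pooled_intensity(pi, path)
  expect_equal(read_pooled_intensity(path), pi)
  expect_error(pooled_intensity("rs1", 1, 1, 0L), "pool_size")
})

test_that("BED export converts coordinates and merges abutting segments", {
  calls <- structure(
    data.frame(sample = "s1", chromosome = "9",
               start = c(100001L, 200001L, 500001L),
               end = c(200000L, 300000L, 600000L),
               label = "AI", mean_index = c(0.5, 0.7, 0.9),
               n_snps = 10L, whole_chromosome = FALSE,
               stringsAsFactors = FALSE),
    class = c("aberration_calls", "data.frame"))
  path <- withr::local_tempfile(fileext = ".bed")
  expect_warning(write_regions_bed(calls, path), "merged")
  bed <- utils::read.delim(path, header = FALSE, comment.char = "#")
  # two abutting records merged into one 0-based half-open interval
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$V2[1], 100000L)
  expect_equal(bed$V3[1], 300000L)
  expect_equal(bed$V1[1], "chr9")
  expect_equal(bed$V4[1], "AI|s1")

  # empty call set -> header-only file
  write_regions_bed(empty <- structure(calls[0, ],
                                       class = class(calls)), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_true(startsWith(lines, "#"))
})

test_that("annotation round-trips through its TSV form", {
  ann <- tiny_annotation(8, chrom = "X")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_annotation(ann, path)
  expect_equal(read_snp_annotation(path), ann)
})
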