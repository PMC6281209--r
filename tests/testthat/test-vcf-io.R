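write_lines_vcf <- function(body, samples = c("S1", "S2", "S3")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

test_that("read_vcf imports dosages, applies the depth mask, flags multi-allelic sites and skips indels", {
  path <- write_lines_vcf(c(
    "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT:DP\t0/0:30\t0/0:30\t0/0:30",
    "chr1\t200\tv2\tA\tG\t.\t.\t.\tGT:DP\t0/0:30\t0/0:9\t0/0:30",
    "chr1\t300\tv3\tA\tT,G\t.\t.\t.\tGT:DP\t0/1:30\t1/2:30\t0/0:30",
    "chr1\t400\tv4\tA\tAT\t.\t.\t.\tGT:DP\t0/1:30\t0/0:30\t0/0:30",
    "chr1\t500\tv5\tA\tG\t.\t.\t.\tGT:DP\t0|1:30\t./0:30\t1|1:30"
  ))
  gm <- read_vcf(path)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(gm$samples, c("S1", "S2", "S3"))
  expect_equal(gm$variants$id, c("v1", "v2", "v3", "v5"))  # indel skipped
  expect_equal(gm$variants$biallelic, c(TRUE, TRUE, FALSE, TRUE))
  # phased separator identical to unphased; half-missing is fully missing
  expect_equal(unname(gm$calls[, "v5"]), c(1L, NA, 2L))
  # multi-allelic dosage counts non-reference alleles
  expect_equal(unname(gm$calls[, "v3"]), c(1L, 2L, 0L))

  # no mask requested: low-depth call survives
  expect_equal(unname(gm$calls[, "v2"]), c(0L, 0L, 0L))
  gm10 <- read_vcf(path, min_depth_to_keep = 10)
  expect_equal(unname(gm10$calls[, "v2"]), c(0L, NA, 0L))
  expect_equal(sum(is.na(gm10$calls[, "v1"])), 0L)
})

test_that("read_vcf treats unknown depth per policy when masking is requested", {
  path <- write_lines_vcf(
    "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT:DP\t0/0:.\t0/1:30\t1/1:12")
  strict <- read_vcf(path, min_depth_to_keep = 10)
  expect_true(is.na(strict$calls[1, 1]))
  lenient <- read_vcf(path, min_depth_to_keep = 10, depth_policy = "lenient")
  expect_equal(unname(lenient$calls[, 1]), c(0L, 1L, 2L))
})

test_that("malformed input fails with a line number; absent GT is fatal", {
  bad <- write_lines_vcf(c(
    "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT:DP\t0/0:30\t0/0:30\t0/0:30",
    "chr1\t200\tv2\tA\tG\t.\t.\t.\tGT:DP\t0/0:30\t0/0:30"
  ))
  expect_error(read_vcf(bad), "line 6")
  nogt <- write_lines_vcf(
    "chr1\t100\tv1\tA\tG\t.\t.\t.\tDP\t30\t30\t30")
  expect_error(read_vcf(nogt), "GT absent")
  expect_error(read_vcf(withr::local_tempfile()), "no such file|cannot")
})

test_that("write_vcf round-trips calls, depths and ordering exactly", {
  set.seed(42)
  gm <- random_gm(6, 30, miss = 0.15)
  gm$depths[] <- matrix(sample(c(NA, 5:60), length(gm$depths), TRUE),
                        nrow(gm$depths))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(back$calls, gm$calls)
  expect_identical(back$depths, gm$depths)
  expect_identical(back$samples, gm$samples)
  expect_identical(back$variants$pos, gm$variants$pos)
  # missing calls appear as ./. at exactly those cells
  lines <- readLines(path)
  body <- lines[grep("^chr", lines)]
  n_missing_written <- sum(vapply(
    body, function(l) sum(grepl("^\\./\\.", strsplit(l, "\t")[[1]][-(1:9)])),
    numeric(1)))
  expect_equal(n_missing_written, sum(is.na(gm$calls)))
})

test_that("write_vcf refuses empty input", {
  gm <- random_gm(3, 4)
  expect_error(write_vcf(gm[integer(0), ], tempfile()), "empty")
})

test_that("depth masking is idempotent", {
  set.seed(7)
  gm <- random_gm(5, 40, miss = 0)
  gm$depths[] <- sample(0:40, length(gm$depths), TRUE)
  once <- mask_low_depth(gm, 10)
  twice <- mask_low_depth(once, 10)
  expect_identical(once$calls, twice$calls)
  expect_gt(sum(is.na(once$calls)), 0)
})

test_that("merge_on_panel stacks samples, projects onto the panel and rejects duplicates", {
  td <- withr::local_tempdir()
  p <- make_toy_vcf_fixtures(td)
  exp <- jsonlite::read_json(p$merge_expected, simplifyVector = TRUE)
  a <- read_vcf(p$merge_a)
  b <- read_vcf(p$merge_b)
  merged <- merge_on_panel(list(a, b), a$variants)
  expect_equal(n_samples(merged), n_samples(a) + n_samples(b))
  expect_equal(merged$variants$id, exp$panel_ids)
  expect_equal(sum(is.na(merged$calls)), exp$expected_missing_cells)
  absent <- merged$variants$id %in% exp$absent_in_b
  expect_true(all(is.na(merged$calls[b$samples, absent])))
  expect_false(anyNA(merged$calls[a$samples, ]))

  # shared panel across both inputs: no new missingness
  both <- merge_on_panel(list(a[1:2, ], a[3, ]), a$variants)
  expect_false(anyNA(both$calls))

  expect_error(merge_on_panel(list(a, a), a$variants), "duplicate sample")
  expect_error(merge_on_panel(list(a), a$variants[0, ]), "empty panel")
})

test_that("merged output always has exactly the panel's columns", {
  set.seed(11)
  for (k in 1:5) {
    gm <- random_gm(4, 10)
    sub <- gm[, sort(sample(10, sample(3:9, 1)))]
    sub$samples <- paste0("T", 1:4)
    rownames(sub$calls) <- rownames(sub$depths) <- sub$samples
    panel <- gm$variants[sort(sample(10, sample(2:10, 1))), ]
    merged <- merge_on_panel(list(gm, sub), panel)
    expect_equal(n_variants(merged), nrow(panel))
    expect_equal(merged$variants$pos, panel$pos)
  }
})

test_that("sample metadata reader validates set and subpopulation labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tset_label\tsubpop_label\tlatitude\tlongitude",
               "c1\tcultivar\tEastern\t25.3\t51.5",
               "c2\tcultivar\t\t\t",
               "o1\toutgroup\t\t\t",
               "t1\tsurvey\t\t25.2\t51.4"), path)
  info <- read_sample_info(path)
  expect_equal(nrow(info), 4)
  expect_true(is.na(info$subpop_label[2]))
  writeLines(c("sample_id\tset_label\tsubpop_label",
               "o1\toutgroup\tEastern"), path)
  expect_error(read_sample_info(path), "outgroup")
})
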