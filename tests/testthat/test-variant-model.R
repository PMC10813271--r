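test_that("read_vcf parses biallelic sites, dosages and missingness", {
  path <- write_vcf_text(c(
    vcf_line("chr14", 91942196, "C", "T", c("0/1", "0/0")),
    vcf_line("chr2", 100, "G", "A", c("1/1", "./.")),
    vcf_line("chr3", 200, "A", "G", c("0|1", "1|1"))
  ))
  x <- read_vcf(path)
  expect_equal(nrow(x$variants), 3)
  expect_equal(x$variants$vid[1], "14:91942196:C:T")
  expect_equal(x$genotypes$S1, c(1L, 2L, 1L))
  expect_equal(x$genotypes$S2, c(0L, NA_integer_, 2L))
  # missing stays NA, never 0
  expect_true(is.na(x$genotypes$S2[2]))
})

test_that("read_vcf matches a character-level reference parse", {
  set.seed(42)
  gts <- c("0/0", "0/1", "1/0", "1/1", "./.")
  body <- vapply(1:10, function(i) {
    vcf_line("chr1", i * 10, "A", "T", sample(gts, 3, replace = TRUE))
  }, character(1))
  path <- write_vcf_text(body, samples = c("A1", "A2", "A3"))
  got <- read_vcf(path)$genotypes
  ref <- naive_parse_vcf(path)
  expect_equal(as.data.frame(got), as.data.frame(ref))
})

test_that("read_vcf rejects multiallelic sites, absent GT and duplicate ids", {
  p1 <- write_vcf_text(vcf_line("chr1", 5, "A", "T,G", c("0/1", "0/0")))
  expect_error(read_vcf(p1), "multiallelic")
  p2 <- write_vcf_text(vcf_line("chr1", 5, "A", "T", c("12", "10"),
                                fmt = "DP"))
  expect_error(read_vcf(p2), "GT")
  p3 <- write_vcf_text(c(vcf_line("chr1", 5, "A", "T", c("0/1", "0/0")),
                         vcf_line("1", 5, "A", "T", c("0/1", "0/0"))))
  expect_error(read_vcf(p3), "duplicate")
})

test_that("variant id construction validates alleles and normalizes chrom", {
  expect_equal(make_vid("chr14", 91942196, "C", "T"), "14:91942196:C:T")
  expect_equal(make_vid("14", 91942196, "C", "T"), "14:91942196:C:T")
  expect_error(make_vid("1", 10, "A", "A"), "differ")
  expect_error(make_vid("1", 10, "", "T"), "non-empty")
})

test_that("read_ped resolves links and encodes affection", {
  path <- tempfile(fileext = ".ped")
  writeLines(c(
    "FAM1 II2 0 0 2 1",
    "FAM1 II3 0 0 2 2",
    "FAM1 II4 0 0 1 1",
    "FAM1 III3 II4 II3 2 2",
    "FAM1 III5 II4 II3 2 2",
    "FAM1 III7 II4 II3 1 2",
    "FAM1 III9 II4 II3 1 1"
  ), path)
  ped <- read_ped(path)
  expect_s3_class(ped, "fampri_pedigree")
  expect_equal(sum(ped$affection == "affected"), 4)
  expect_equal(sum(ped$affection == "unaffected"), 3)
  expect_true(is.na(ped$father[ped$id == "II3"]))
  expect_equal(ped$mother[ped$id == "III5"], "II3")
})

test_that("pedigree validation catches structural errors", {
  single <- pedigree(tibble::tibble(id = "X", father = NA, mother = NA,
                                    sex = "male", affection = "unknown"))
  expect_equal(nrow(single), 1)
  expect_error(
    pedigree(tibble::tibble(id = c("A", "B"), father = c("B", "A"),
                            mother = c(NA, NA), sex = "male",
                            affection = "unknown")),
    "cyclic"
  )
  path <- tempfile(fileext = ".ped")
  writeLines("FAM1 A GHOST 0 1 1", path)
  expect_error(read_ped(path), "unresolvable")
  writeLines(c("FAM1 A 0 0 1 1", "FAM1 A 0 0 1 1"), path)
  expect_error(read_ped(path), "duplicate")
})

test_that("annotation reader parses the worked example and validates fields", {
  ann <- fnmtc_annotations()
  path <- tempfile(fileext = ".tsv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(nrow(back), 12)
  pp <- back[back$gene == "PPP4R3A", ]
  expect_true(is.na(pp$af_1000g_eas))
  expect_equal(pp$sift_score, 0.24)
  expect_equal(pp$sift_pred, "T")
  expect_equal(pp$pp2_hdiv_pred, "D")
  expect_equal(pp$mt_pred, "D")

  bad <- ann
  bad$pp2_hdiv_pred[1] <- "X"
  expect_error(write_annotations(bad, tempfile()), "pp2_hdiv_pred")
  bad2 <- ann
  bad2$af_exac_eas[2] <- 1.5
  expect_error(write_annotations(bad2, tempfile()), "outside")
  # out-of-range AF caught on read too
  txt <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), na = character())
  txt$af_exac_all[3] <- "2"
  p2 <- tempfile(fileext = ".tsv")
  readr::write_tsv(txt, p2, na = "NA")
  expect_error(read_annotations(p2), "outside")
})

test_that("annotation TSV round-trips randomized records exactly", {
  for (seed in c(1, 2, 3)) {
    ann <- random_annotations(sprintf("1:%d:A:C", 1:40), seed)
    path <- tempfile(fileext = ".tsv")
    write_annotations(ann, path)
    expect_equal(as.data.frame(read_annotations(path)), as.data.frame(ann))
  }
})

test_that("candidate tables round-trip through TSV plus audit sidecar", {
  res <- run_cascade(fnmtc_genotypes(), fnmtc_annotations(), fnmtc_pedigree(),
                     fnmtc_config())
  path <- tempfile(fileext = ".tsv")
  write_candidates(res, path)
  back <- read_candidates(path)
  expect_equal(as.data.frame(tidy(back)), as.data.frame(tidy(res)))
  expect_equal(stage_counts(back)$n, stage_counts(res)$n)
  expect_equal(segregation_results(back)$segregates,
               segregation_results(res)$segregates)

  # empty table still writes a header and its audit counts
  gt0 <- fnmtc_genotypes()
  gt0$II2 <- 1L  # every variant now carried by the control
  empty <- run_cascade(gt0, fnmtc_annotations(), fnmtc_pedigree(),
                       fnmtc_config())
  expect_equal(nrow(empty), 0)
  p0 <- tempfile(fileext = ".tsv")
  write_candidates(empty, p0)
  expect_equal(nrow(read_candidates(p0)), 0)
  expect_equal(stage_counts(read_candidates(p0))$n[1], 12)
})
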