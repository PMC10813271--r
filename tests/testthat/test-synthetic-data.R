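test_that("the built-in pedigree template matches the study family design", {
  ped <- simulate_pedigree(simulation_config())
  genotyped <- ped[ped$genotyped, ]
  expect_equal(nrow(genotyped), 6)
  expect_setequal(genotyped$id, c("II2", "II3", "III3", "III5", "III7", "III9"))
  expect_equal(sum(genotyped$affection == "affected"), 4)
  expect_equal(sum(genotyped$affection == "unaffected"), 2)

  custom <- simulate_pedigree(simulation_config(
    pedigree_template = tibble::tibble(
      id = c("F", "M", "K1", "K2", "K3"),
      father = c(NA, NA, "F", "F", "F"),
      mother = c(NA, NA, "M", "M", "M"),
      sex = c("male", "female", "male", "female", "male"),
      affection = "unknown"
    )
  ))
  expect_equal(nrow(custom), 5)

  expect_error(simulate_pedigree(simulation_config(
    pedigree_template = tibble::tibble(
      id = "K", father = "GHOST", mother = NA_character_,
      sex = "male", affection = "unknown"
    )
  )), "unresolvable")
})

test_that("simulated variant sets have unique ids and the configured mixture", {
  cfg <- simulation_config(n_background = 2000)
  v <- simulate_variants(cfg, 4)
  expect_equal(nrow(v), 2001)
  expect_false(anyDuplicated(v$vid) > 0)
  expect_equal(sum(v$is_causal), 1)
  expect_true(is.na(v$af_catalog[v$is_causal]))
  # mixture classes roughly match their weights
  tab <- table(v$af_class[!v$is_causal]) / 2000
  expect_lt(abs(tab[["common"]] - 0.6), 0.05)
  rare <- v$af_catalog[v$af_class == "rare"]
  expect_true(all(rare <= 0.001 & rare > 0))
  common <- v$af_catalog[v$af_class == "common"]
  expect_true(all(common > 0.001 & common <= 0.2))
})

test_that("fully penetrant causal transmission matches the template affections", {
  cfg <- simulation_config(n_background = 20)
  ped <- simulate_pedigree(cfg)
  v <- simulate_variants(cfg, 2)
  sim <- simulate_genotypes(ped, v, cfg, 2)
  gt <- sim$genotypes
  cv <- sim$truth$causal_vid
  row <- gt[gt$vid == cv, ]
  expect_equal(unlist(row[, c("II3", "III3", "III5", "III7")]),
               c(II3 = 1L, III3 = 1L, III5 = 1L, III7 = 1L))
  expect_equal(unlist(row[, c("II2", "III9")]), c(II2 = 0L, III9 = 0L))
  expect_true(sim$truth$expected_segregation)
  expect_setequal(intersect(sim$truth$carrier_ids,
                            c("II2", "II3", "III3", "III5", "III7", "III9")),
                  c("II3", "III3", "III5", "III7"))

  # repeated seed reproduces the matrix exactly
  sim2 <- simulate_genotypes(ped, v, cfg, 2)
  expect_identical(sim$genotypes, sim2$genotypes)
})

test_that("founder genotypes follow Hardy-Weinberg at the simulated frequency", {
  n_f <- 10000
  ped <- pedigree(tibble::tibble(
    id = sprintf("F%05d", seq_len(n_f)),
    father = NA_character_, mother = NA_character_,
    sex = "unknown", affection = "unknown", genotyped = TRUE
  ))
  variants <- tibble::tibble(
    chrom = "1", pos = 100L, ref = "A", alt = "C", vid = "1:100:A:C",
    gene = "G1", is_causal = FALSE, af_class = "common",
    af_catalog = 0.5, af_founder = 0.5
  )
  cfg <- simulation_config(n_background = 1, causal_present = FALSE)
  sim <- simulate_genotypes(ped, variants, cfg, 13)
  doses <- unlist(sim$genotypes[1, -1])
  expect_lt(abs(mean(doses) / 2 - 0.5), 0.01)
})

test_that("simulated annotations respect construction guarantees", {
  cfg <- simulation_config(n_background = 1500)
  v <- simulate_variants(cfg, 9)
  ann <- simulate_annotations(v, cfg, 9)
  cv <- v$vid[v$is_causal]
  crow <- ann[ann$vid == cv, ]
  expect_equal(crow$region, "exonic")
  expect_equal(crow$`function`, "nonsynonymous_SNV")
  expect_true(all(is.na(unlist(crow[, c("af_1000g_all", "af_1000g_eas",
                                        "af_exac_all", "af_exac_eas")]))))
  # causal passes region, function and frequency filters by construction
  expect_true(cv %in% filter_region(ann, cv))
  expect_true(cv %in% filter_function(ann, cv))
  expect_true(cv %in% filter_af(ann, cv))
  # a common background variant fails the frequency filter
  common_vid <- v$vid[v$af_class == "common" & v$af_catalog > 0.01][1]
  expect_false(common_vid %in% filter_af(ann, common_vid))
  # fixed seed reproduces the table
  expect_identical(ann, simulate_annotations(v, cfg, 9))
})

test_that("generated studies are complete, runnable and byte-deterministic", {
  cfg <- simulation_config(n_background = 300)
  d1 <- generate_study(cfg, 31, dir = tempfile("study_a_"))
  d2 <- generate_study(cfg, 31, dir = tempfile("study_b_"))
  for (f in c("vcf", "ped", "annotations", "truth", "cohort")) {
    expect_identical(readLines(d1$paths[[f]]), readLines(d2$paths[[f]]))
  }
  d3 <- generate_study(cfg, 32, dir = tempfile("study_c_"))
  expect_false(identical(readLines(d1$paths$vcf), readLines(d3$paths$vcf)))

  # the written study runs end-to-end and retains the causal variant
  x <- read_vcf(d1$paths$vcf)
  ped <- read_ped(d1$paths$ped)
  ann <- read_annotations(d1$paths$annotations)
  res <- run_cascade(x$genotypes, ann, ped, fnmtc_config())
  expect_true(d1$truth$causal_vid %in% res$vid)
  seg <- segregation_results(res)
  expect_true(seg$segregates[seg$vid == d1$truth$causal_vid])
  cohort <- read_vcf(d1$paths$cohort)$genotypes
  expect_true(screen_cohort(cohort, d1$truth$causal_vid)$absent)

  # without a planted causal variant the truth file records none
  d0 <- generate_study(simulation_config(n_background = 100,
                                         causal_present = FALSE),
                       31, dir = tempfile("study_null_"))
  expect_true(is.na(d0$truth$causal_vid))
  expect_false(file.exists(file.path(dirname(d0$paths$vcf), "cohort.vcf")))
})

test_that("tidy, glance and plot methods summarize a cascade run", {
  res <- run_cascade(fnmtc_genotypes(), fnmtc_annotations(), fnmtc_pedigree(),
                     fnmtc_config())
  td <- tidy(res)
  expect_false(inherits(td, "fampri_candidates"))
  expect_equal(nrow(td), 5)
  gl <- glance(res)
  expect_equal(gl$n_input, 12)
  expect_equal(gl$n_retained, 5)
  expect_equal(gl$top_gene, "VWF")
  p1 <- ggplot2::autoplot(res)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_stage_counts(res)
  expect_s3_class(p2, "ggplot")
})
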