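test_that("individual stages implement their carrier and missingness rules", {
  gt <- tibble::tibble(
    vid = sprintf("1:%d:A:C", 1:6),
    A1 = c(1L, 1L, 1L, 2L, 1L, NA),
    A2 = c(1L, 0L, 1L, 2L, 1L, 1L),
    C1 = c(0L, 0L, 1L, 0L, NA, 0L)
  )
  aff <- c("A1", "A2")

  # intersection: carried by every affected; missing excludes
  kept <- intersect_affected(gt, aff)
  expect_setequal(kept, gt$vid[c(1, 3, 4, 5)])
  expect_error(intersect_affected(gt, character()), "non-empty")
  expect_error(intersect_affected(gt, "NOPE"), "unknown")

  # control exclusion: any carrier control drops; missing control keeps
  kept2 <- exclude_controls(gt, gt$vid, "C1")
  expect_setequal(kept2, gt$vid[c(1, 2, 4, 5, 6)])

  # zygosity: drop only when all affected are homozygous alt
  kept3 <- filter_zygosity(gt, gt$vid, aff)
  expect_setequal(kept3, gt$vid[-4])

  ann <- fnmtc_annotations()
  # region filter keeps exonic/splicing by default
  ann2 <- ann
  ann2$region[1] <- "intronic"
  ann2$region[2] <- "splicing"
  kept4 <- filter_region(ann2, ann2$vid)
  expect_false(ann2$vid[1] %in% kept4)
  expect_true(ann2$vid[2] %in% kept4)
  expect_error(filter_region(ann, "9:9:A:C"), "no annotation")

  # function filter drops synonymous, keeps stopgain
  ann3 <- ann
  ann3$`function`[1] <- "synonymous_SNV"
  ann3$`function`[2] <- "stopgain"
  kept5 <- filter_function(ann3, ann3$vid)
  expect_false(ann3$vid[1] %in% kept5)
  expect_true(ann3$vid[2] %in% kept5)
})

test_that("frequency filter uses strict threshold, EAS fields and NA policy", {
  ann <- fnmtc_annotations()
  kept <- filter_af(ann, ann$vid)
  kept_genes <- ann$gene[ann$vid %in% kept]
  expect_setequal(kept_genes, c("PPP4R3A", "MANSC1", "IQSEC3", "MYL1", "VWF"))
  # CTBS (EAS frequencies 0.03 / 0.032) is excluded
  expect_false("CTBS" %in% kept_genes)
  # all-NA frequencies pass under the default policy, fail under "fail"
  pp_vid <- ann$vid[ann$gene == "PPP4R3A"]
  expect_false(pp_vid %in% filter_af(ann, ann$vid, na_policy = "fail"))
  # frequency exactly at the threshold is kept (strict >)
  ann2 <- ann
  ann2$af_exac_eas[ann2$gene == "PPP4R3A"] <- 0.001
  expect_true(pp_vid %in% filter_af(ann2, ann2$vid))
  ann2$af_exac_eas[ann2$gene == "PPP4R3A"] <- 0.0010001
  expect_false(pp_vid %in% filter_af(ann2, ann2$vid))
})

test_that("cascade equals the brute-force predicate oracle on random inputs", {
  samples <- sprintf("S%02d", 1:12)
  config <- cascade_config(affected = samples[1:4], controls = samples[5:6])
  ped <- pedigree(tibble::tibble(
    id = samples, father = NA_character_, mother = NA_character_,
    sex = "unknown",
    affection = c(rep("affected", 4), rep("unaffected", 8))
  ))
  for (trial in 1:50) {
    gt <- random_gt(500, samples, seed = trial)
    ann <- random_annotations(gt$vid, seed = trial)
    res <- run_cascade(gt, ann, ped, config)
    expect_setequal(res$vid, oracle_cascade(gt, ann, config))
    # stage counts never increase
    expect_true(all(diff(stage_counts(res)$n) <= 0))
  }
})

test_that("independent stages commute and the cascade is idempotent", {
  samples <- sprintf("S%02d", 1:8)
  config <- cascade_config(affected = samples[1:3], controls = samples[4])
  set.seed(99)
  for (trial in 1:10) {
    gt <- random_gt(200, samples, seed = 1000 + trial)
    ann <- random_annotations(gt$vid, seed = 1000 + trial)
    base <- intersect_affected(gt, config$affected)
    base <- exclude_controls(gt, base, config$controls)
    stages <- list(
      function(v) filter_region(ann, v, config$keep_regions),
      function(v) filter_function(ann, v, config$drop_functions),
      function(v) filter_zygosity(gt, v, config$affected),
      function(v) filter_af(ann, v, config$af_fields, config$af_threshold,
                            config$na_policy)
    )
    ref <- Reduce(function(v, f) f(v), stages, base)
    perm <- sample(4)
    got <- Reduce(function(v, f) f(v), stages[perm], base)
    expect_setequal(got, ref)

    # fixed point: rerunning the cascade on its own survivors changes nothing
    ped <- pedigree(tibble::tibble(
      id = samples, father = NA_character_, mother = NA_character_,
      sex = "unknown",
      affection = c(rep("affected", 3), rep("unaffected", 5))
    ))
    res1 <- run_cascade(gt, ann, ped, config)
    gt2 <- gt[gt$vid %in% res1$vid, , drop = FALSE]
    res2 <- run_cascade(gt2, ann, ped, config)
    expect_setequal(res2$vid, res1$vid)
  }
})

test_that("cascade audits stages and handles degenerate inputs", {
  res <- run_cascade(fnmtc_genotypes(), fnmtc_annotations(), fnmtc_pedigree(),
                     fnmtc_config())
  sc <- stage_counts(res)
  expect_equal(sc$stage[1], "input")
  expect_equal(sc$n, c(12, 12, 12, 12, 12, 12, 5))

  # empty variant input: empty table, all-zero counts
  gt0 <- fnmtc_genotypes()[0, ]
  res0 <- run_cascade(gt0, fnmtc_annotations(), fnmtc_pedigree(),
                      fnmtc_config())
  expect_equal(nrow(res0), 0)
  expect_true(all(stage_counts(res0)$n == 0))

  # handing the causal variant to the control removes it
  gt1 <- fnmtc_genotypes()
  pp_vid <- fnmtc_annotations()$vid[fnmtc_annotations()$gene == "PPP4R3A"]
  gt1$II2[gt1$vid == pp_vid] <- 1L
  res1 <- run_cascade(gt1, fnmtc_annotations(), fnmtc_pedigree(),
                      fnmtc_config())
  expect_false(pp_vid %in% res1$vid)

  # verbose mode emits one audit line per stage
  expect_message(
    run_cascade(fnmtc_genotypes(), fnmtc_annotations(), fnmtc_pedigree(),
                fnmtc_config(), verbose = TRUE),
    "stage=filter_af in=12 out=5"
  )
})

test_that("cascade configuration validates and round-trips through JSON", {
  expect_error(cascade_config(affected = "A", controls = "A"), "disjoint")
  expect_error(cascade_config(affected = "A", af_threshold = 2), "af_threshold")
  cfg <- cascade_config(affected = c("A", "B"), controls = "C",
                        af_threshold = 0.005, na_policy = "fail")
  path <- tempfile(fileext = ".json")
  write_cascade_config(cfg, path)
  expect_equal(read_cascade_config(path), cfg)
})
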