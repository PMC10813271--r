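# Shared fixture builders and independent oracles.

# write VCF text lines to a temp file
write_vcf_text <- function(body_lines, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, gts, fmt = "GT") {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, gts),
        collapse = "\t")
}

# character-level reference parse of a small VCF: independent of read_vcf
naive_parse_vcf <- function(path) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  cols <- strsplit(header, "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[!startsWith(lines, "#")]
  rows <- strsplit(body, "\t")
  gt_map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- lapply(rows, function(f) {
    vid <- paste(sub("^chr", "", f[1]), f[2], f[4], f[5], sep = ":")
    calls <- vapply(f[-(1:9)], function(cell) {
      g <- gsub("|", "/", strsplit(cell, ":")[[1]][1], fixed = TRUE)
      if (g %in% names(gt_map)) gt_map[[g]] else NA_integer_
    }, integer(1))
    c(list(vid = vid), as.list(calls))
  })
  dplyr::bind_rows(lapply(out, function(x) {
    tibble::as_tibble(stats::setNames(x, c("vid", samples)))
  }))
}

# random genotype table: n_var x samples with dosage 0/1/2/NA
random_gt <- function(n_var, samples, seed,
                      probs = c(0.55, 0.25, 0.12, 0.08)) {
  set.seed(seed)
  vals <- sample(c(0L, 1L, 2L, NA_integer_), n_var * length(samples),
                 replace = TRUE, prob = probs)
  m <- matrix(vals, nrow = n_var)
  gt <- tibble::as_tibble(as.data.frame(m))
  names(gt) <- samples
  dplyr::bind_cols(tibble::tibble(vid = sprintf("1:%d:A:C", seq_len(n_var))),
                   gt)
}

# random annotation table over the full enumerations, with NA sprinkled in
random_annotations <- function(vids, seed) {
  set.seed(seed + 77)
  n <- length(vids)
  maybe_na <- function(x, p = 0.25) {
    x[stats::runif(length(x)) < p] <- NA
    x
  }
  af <- function() maybe_na(round(stats::runif(n, 0, 0.05), 6), 0.4)
  tibble::tibble(
    vid = vids,
    gene = sprintf("G%04d", seq_len(n)),
    region = sample(c("exonic", "splicing", "intronic", "UTR3", "UTR5",
                      "intergenic", "ncRNA", "other"), n, replace = TRUE),
    `function` = sample(c("nonsynonymous_SNV", "synonymous_SNV", "stopgain",
                          "stoploss", "frameshift", "nonframeshift",
                          "unknown"), n, replace = TRUE),
    af_1000g_all = af(), af_1000g_eas = af(),
    af_exac_all = af(), af_exac_eas = af(),
    sift_score = maybe_na(round(stats::runif(n), 6)),
    sift_pred = maybe_na(sample(c("D", "T"), n, replace = TRUE)),
    pp2_hdiv_score = maybe_na(round(stats::runif(n), 6)),
    pp2_hdiv_pred = maybe_na(sample(c("D", "P", "B"), n, replace = TRUE)),
    mt_score = maybe_na(round(stats::runif(n), 6)),
    mt_pred = maybe_na(sample(c("A", "D", "N", "P"), n, replace = TRUE))
  )
}

# brute-force cascade oracle: per-variant boolean conjunction, evaluated
# with plain loops, independent of the vectorized stage implementations
oracle_cascade <- function(gt, ann, config) {
  survivors <- character()
  for (i in seq_len(nrow(gt))) {
    vid <- gt$vid[i]
    row <- gt[i, , drop = FALSE]
    a <- unlist(row[, config$affected, drop = FALSE])
    ctl <- unlist(row[, config$controls, drop = FALSE])
    arow <- ann[ann$vid == vid, , drop = FALSE]
    stopifnot(nrow(arow) == 1)
    afs <- unlist(arow[, config$af_fields, drop = FALSE])
    af_ok <- if (all(is.na(afs))) config$na_policy == "pass" else
      max(afs, na.rm = TRUE) <= config$af_threshold
    pass <- all(!is.na(a) & a >= 1) &&
      !any(!is.na(ctl) & ctl >= 1) &&
      arow$region %in% config$keep_regions &&
      !(arow$`function` %in% config$drop_functions) &&
      !all(!is.na(a) & a == 2) &&
      af_ok
    if (pass) survivors <- c(survivors, vid)
  }
  survivors
}

# analytic probability that a background variant at founder allele
# frequency af shows the surviving genotype pattern in the built-in family
# template (all four affected carriers, control II2 non-carrier, affected
# members not all homozygous-alt), by exact enumeration over founder
# genotypes and Mendelian transmission
pattern_prob <- function(af) {
  hw <- c((1 - af)^2, 2 * af * (1 - af), af^2)
  child_dist <- function(gm, gf) {
    pm <- gm / 2; pf <- gf / 2
    c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
  }
  total <- 0
  for (gI1 in 0:2) for (gI2 in 0:2) for (gII4 in 0:2) {
    w <- hw[gI1 + 1] * hw[gI2 + 1] * hw[gII4 + 1]
    if (w == 0) next
    sib <- child_dist(gI1, gI2)      # distribution of II2 and II3
    p_II2_ref <- sib[1]
    for (gII3 in 1:2) {
      kid <- child_dist(gII3, gII4)  # III3/III5/III7 (and III9)
      p_carrier <- kid[2] + kid[3]
      p_hom <- kid[3]
      contrib <- p_carrier^3 - (if (gII3 == 2) p_hom^3 else 0)
      total <- total + w * p_II2_ref * sib[gII3 + 1] * contrib
    }
  }
  total
}

# expected number of cascade survivors among background variants of a
# simulated study, conditioning on the realized annotations
expected_background_survivors <- function(variants, ann, config) {
  bg <- !variants$is_causal
  a <- ann[match(variants$vid, ann$vid), ]
  region_ok <- a$region %in% config$keep_regions
  func_ok <- !(a$`function` %in% config$drop_functions)
  afm <- as.matrix(a[, config$af_fields, drop = FALSE])
  af_max <- apply(afm, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  af_ok <- ifelse(is.na(af_max), config$na_policy == "pass",
                  af_max <= config$af_threshold)
  det <- bg & region_ok & func_ok & af_ok
  p <- vapply(variants$af_founder[det], pattern_prob, numeric(1))
  list(expectation = sum(p), variance = sum(p * (1 - p)))
}
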