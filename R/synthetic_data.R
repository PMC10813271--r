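#' Simulation configuration for synthetic family-WES studies
#'
#' Defines the study conditions emulated by the generator: a two-generation
#' autosomal-dominant pedigree with a fully penetrant causal variant that is
#' rare-or-absent in population catalogues, on a background of common and
#' rare variants with predictor-score distributions spanning the SIFT /
#' PolyPhen2 / MutationTaster bands.
#'
#' @param pedigree_template `"fig1"` for the built-in two-generation family
#'   template (six genotyped members: one elderly unaffected control, an
#'   affected parent, three affected offspring, one unaffected offspring),
#'   or a data frame accepted by [pedigree()].
#' @param n_background Number of non-causal background variants.
#' @param causal_present Plant a causal variant (default `TRUE`).
#' @param causal_founder Id of the carrier founder seeding the causal
#'   variant (default `"II3"`, the affected parent of the template).
#' @param penetrance Probability that an affected member carries the causal
#'   variant (and an unaffected member does not); 1 gives deterministic
#'   carrier status matching affection.
#' @param background_af_mix Named weights (summing to 1) of the background
#'   allele-frequency mixture: `na` (uncatalogued; all frequency fields
#'   missing), `rare` (uniform on (0, 0.001]), `common` (uniform on
#'   (0.001, 0.2]).
#' @param na_founder_af Allele frequency used to simulate founder genotypes
#'   for uncatalogued (`na`) background variants: "not catalogued" means
#'   unobserved, not impossible, so these variants can still produce rare
#'   background survivors.
#' @param region_probs Named probabilities over annotation regions for
#'   background variants.
#' @param synonymous_prob Probability that an exonic background variant is
#'   synonymous (the rest are nonsynonymous).
#' @param deleterious_profile List of causal-variant predictor
#'   distributions: `sift` and `pp2` are `c(min, max)` uniform supports,
#'   `mt_d_prob` is the probability of a MutationTaster `"D"` call
#'   (otherwise `"N"`).
#' @param cohort_n_samples,cohort_carrier_rate Size and per-sample causal
#'   carrier probability of the simulated validation cohort.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(pedigree_template = "fig1",
                              n_background = 5000,
                              causal_present = TRUE,
                              causal_founder = "II3",
                              penetrance = 1.0,
                              background_af_mix = c(na = 0.20, rare = 0.20,
                                                    common = 0.60),
                              na_founder_af = 5e-4,
                              region_probs = c(exonic = 0.55, splicing = 0.05,
                                               intronic = 0.25, UTR3 = 0.05,
                                               UTR5 = 0.04, ncRNA = 0.04,
                                               intergenic = 0.01, other = 0.01),
                              synonymous_prob = 0.40,
                              deleterious_profile = list(sift = c(0, 0.05),
                                                         pp2 = c(0.957, 1),
                                                         mt_d_prob = 0.9),
                              cohort_n_samples = 248,
                              cohort_carrier_rate = 0) {
  stopifnot(
    n_background >= 0,
    penetrance >= 0, penetrance <= 1,
    abs(sum(background_af_mix) - 1) < 1e-8,
    setequal(names(background_af_mix), c("na", "rare", "common")),
    all(names(region_probs) %in% REGION_LEVELS),
    abs(sum(region_probs) - 1) < 1e-8,
    synonymous_prob >= 0, synonymous_prob <= 1,
    na_founder_af >= 0, na_founder_af <= 1,
    cohort_n_samples >= 0,
    cohort_carrier_rate >= 0, cohort_carrier_rate <= 1
  )
  structure(
    list(pedigree_template = pedigree_template,
         n_background = as.integer(n_background),
         causal_present = isTRUE(causal_present),
         causal_founder = causal_founder,
         penetrance = penetrance,
         background_af_mix = background_af_mix,
         na_founder_af = na_founder_af,
         region_probs = region_probs,
         synonymous_prob = synonymous_prob,
         deleterious_profile = deleterious_profile,
         cohort_n_samples = as.integer(cohort_n_samples),
         cohort_carrier_rate = cohort_carrier_rate),
    class = "simulation_config"
  )
}

# the built-in two-generation dominant-family template: an elderly
# unaffected control (II2) and affected parent (II3) in generation II,
# three affected and one unaffected offspring in generation III; only the
# six members II2/II3/III3/III5/III7/III9 are genotyped, matching a WES
# design where generation I and the unaffected spouse are unavailable.
fig1_template <- function() {
  tibble::tibble(
    id     = c("I1", "I2", "I4", "II2", "II3", "II4",
               "III3", "III5", "III7", "III9"),
    father = c(NA, NA, NA, "I1", "I1", "I4",
               "II4", "II4", "II4", "II4"),
    mother = c(NA, NA, NA, "I2", "I2", NA,
               "II3", "II3", "II3", "II3"),
    sex    = c("male", "female", "male", "female", "female", "male",
               "female", "female", "male", "male"),
    affection = c("unknown", "unknown", "unaffected", "unaffected",
                  "affected", "unaffected",
                  "affected", "affected", "affected", "unaffected"),
    genotyped = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, TRUE)
  )
}

#' Simulate (instantiate) the study pedigree
#'
#' @param config A [simulation_config()]; its `pedigree_template` is either
#'   the built-in `"fig1"` two-generation family or a custom member table.
#' @return A `fampri_pedigree` tibble.
#' @export
simulate_pedigree <- function(config = simulation_config()) {
  template <- config$pedigree_template
  if (is.character(template) && identical(template, "fig1")) {
    return(pedigree(fig1_template()))
  }
  if (is.data.frame(template)) {
    return(pedigree(template))
  }
  stop("pedigree_template must be \"fig1\" or a member data frame",
       call. = FALSE)
}

# topological order: parents before children
topo_order <- function(ped) {
  remaining <- ped$id
  placed <- character()
  order <- character()
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(id) {
      i <- match(id, ped$id)
      parents <- stats::na.omit(c(ped$father[i], ped$mother[i]))
      all(parents %in% placed)
    }, logical(1))
    if (!any(ready)) stop("pedigree is not acyclic", call. = FALSE)
    order <- c(order, remaining[ready])
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  order
}

#' Simulate the variant set of a synthetic study
#'
#' Draws background variant identities (chromosome, position, alleles) from
#' a synthetic exome coordinate set (positions without replacement, so vids
#' are unique) and assigns each an allele-frequency class from the
#' configured mixture. When `causal_present`, a causal variant is added
#' with no catalogued frequency.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `vid`,
#'   `gene`, `is_causal`, `af_class` (`"na"`, `"rare"`, `"common"` or
#'   `"causal"`), `af_catalog` (value written to the frequency fields; `NA`
#'   for uncatalogued) and `af_founder` (frequency used for founder
#'   genotype simulation).
#' @export
simulate_variants <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_background + as.integer(config$causal_present)
  bases <- c("A", "C", "G", "T")
  chrom <- as.character(sample.int(22, n, replace = TRUE))
  pos <- sort(sample.int(5e7, n, replace = FALSE))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  gene <- sprintf("G%05d", seq_len(n))

  is_causal <- rep(FALSE, n)
  if (config$causal_present) is_causal[sample.int(n, 1)] <- TRUE

  n_bg <- sum(!is_causal)
  af_class <- rep("causal", n)
  af_class[!is_causal] <- sample(names(config$background_af_mix), n_bg,
                                 replace = TRUE,
                                 prob = config$background_af_mix)
  af_catalog <- rep(NA_real_, n)
  rare <- af_class == "rare"
  common <- af_class == "common"
  af_catalog[rare] <- stats::runif(sum(rare), 0, 0.001)
  af_catalog[common] <- stats::runif(sum(common), 0.001, 0.2)

  af_founder <- af_catalog
  af_founder[af_class == "na"] <- config$na_founder_af
  af_founder[is_causal] <- 0  # planted, not drawn from the population

  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vid = make_vid(chrom, pos, ref, alt),
    gene = gene, is_causal = is_causal,
    af_class = af_class, af_catalog = af_catalog, af_founder = af_founder
  )
}

#' Simulate pedigree genotypes by Mendelian transmission
#'
#' Founder genotypes are drawn per variant from Hardy-Weinberg proportions
#' at the variant's simulated allele frequency (uncatalogued variants use
#' the configured `na_founder_af`); each offspring receives one allele from
#' each parent with probability dosage/2. A member with one unknown parent
#' draws that allele from the population frequency. The causal variant is
#' planted heterozygous in the configured carrier founder and assigned to
#' descendants so that carrier status matches affection with probability
#' `penetrance` (at penetrance 1 every affected member carries it and no
#' unaffected member does).
#'
#' @param ped A `fampri_pedigree` (see [simulate_pedigree()]).
#' @param variants Variant tibble from [simulate_variants()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list: `genotypes` (wide dosage tibble restricted to genotyped
#'   members) and `truth` (list with `causal_vid`, `carrier_ids`,
#'   `expected_segregation`; `causal_vid` is `NA` when no causal variant
#'   was planted).
#' @export
simulate_genotypes <- function(ped, variants, config = simulation_config(),
                               seed = 1) {
  set.seed(seed + 1L)
  n <- nrow(variants)
  af <- variants$af_founder
  order_ids <- topo_order(ped)
  calls <- matrix(0L, nrow = n, ncol = nrow(ped),
                  dimnames = list(variants$vid, ped$id))
  for (id in order_ids) {
    i <- match(id, ped$id)
    f <- ped$father[i]
    m <- ped$mother[i]
    pat <- if (is.na(f)) stats::rbinom(n, 1, af) else
      stats::rbinom(n, 1, calls[, f] / 2)
    mat <- if (is.na(m)) stats::rbinom(n, 1, af) else
      stats::rbinom(n, 1, calls[, m] / 2)
    calls[, id] <- as.integer(pat + mat)
  }

  truth <- list(causal_vid = NA_character_, carrier_ids = character(),
                expected_segregation = NA)
  if (any(variants$is_causal)) {
    cv <- which(variants$is_causal)
    founder <- config$causal_founder
    if (!founder %in% ped$id) {
      stop("causal founder not in pedigree: ", founder, call. = FALSE)
    }
    carrier <- stats::setNames(rep(FALSE, nrow(ped)), ped$id)
    carrier[founder] <- TRUE
    for (id in setdiff(ped$id, founder)) {
      i <- match(id, ped$id)
      match_affection <- stats::runif(1) < config$penetrance
      is_affected <- ped$affection[i] == "affected"
      carrier[id] <- if (match_affection) is_affected else !is_affected
    }
    calls[cv, ] <- as.integer(carrier[colnames(calls)])
    genotyped_ids <- ped$id[ped$genotyped]
    seg <- all(carrier[ped$id[ped$affection == "affected" & ped$genotyped]]) &&
      !any(carrier[ped$id[ped$affection == "unaffected" & ped$genotyped]])
    truth <- list(
      causal_vid = variants$vid[cv],
      carrier_ids = names(carrier)[carrier],
      expected_segregation = seg
    )
  }

  genotyped_ids <- ped$id[ped$genotyped]
  gt <- tibble::as_tibble(as.data.frame(calls[, genotyped_ids, drop = FALSE]))
  gt <- dplyr::bind_cols(tibble::tibble(vid = variants$vid), gt)
  list(genotypes = gt, truth = truth)
}

#' Simulate the annotation table of a synthetic study
#'
#' The causal variant is exonic and nonsynonymous with all population
#' frequency fields missing and deleterious-leaning predictor draws from
#' the configured profile. Background variants draw regions and function
#' classes from the configured mixtures, write their simulated catalogue
#' frequency into all four frequency columns, and draw benign-leaning
#' predictor scores (SIFT uniform on \[0,1\], PolyPhen2 Beta(1,4),
#' MutationTaster mostly polymorphism calls).
#'
#' @param variants Variant tibble from [simulate_variants()].
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return An annotation tibble (see [read_annotations()] for the schema).
#' @export
simulate_annotations <- function(variants, config = simulation_config(),
                                 seed = 1) {
  set.seed(seed + 2L)
  n <- nrow(variants)
  causal <- variants$is_causal

  region <- sample(names(config$region_probs), n, replace = TRUE,
                   prob = config$region_probs)
  func <- rep("unknown", n)
  exonic <- region == "exonic"
  func[exonic] <- ifelse(stats::runif(sum(exonic)) < config$synonymous_prob,
                         "synonymous_SNV", "nonsynonymous_SNV")

  sift <- stats::runif(n)
  pp2 <- stats::rbeta(n, 1, 4)
  mt_pred <- sample(c("N", "P", "D", "A"), n, replace = TRUE,
                    prob = c(0.70, 0.10, 0.15, 0.05))
  mt_score <- stats::runif(n, 0.5, 1)

  prof <- config$deleterious_profile
  if (any(causal)) {
    region[causal] <- "exonic"
    func[causal] <- "nonsynonymous_SNV"
    sift[causal] <- stats::runif(sum(causal), prof$sift[1], prof$sift[2])
    pp2[causal] <- stats::runif(sum(causal), prof$pp2[1], prof$pp2[2])
    mt_pred[causal] <- ifelse(stats::runif(sum(causal)) < prof$mt_d_prob,
                              "D", "N")
    mt_score[causal] <- 1
  }

  af <- variants$af_catalog
  ann <- tibble::tibble(
    vid = variants$vid,
    gene = variants$gene,
    region = region,
    `function` = func,
    af_1000g_all = af,
    af_1000g_eas = af,
    af_exac_all = af,
    af_exac_eas = af,
    sift_score = round(sift, 6),
    sift_pred = classify_sift(round(sift, 6)),
    pp2_hdiv_score = round(pp2, 6),
    pp2_hdiv_pred = classify_pp2_hdiv(round(pp2, 6)),
    mt_score = round(mt_score, 6),
    mt_pred = mt_pred
  )
  validate_annotations(ann)
}

#' Simulate a validation cohort for the causal variant
#'
#' Generates an independent cohort genotype matrix containing the causal
#' variant, with each sample an independent heterozygous carrier with
#' probability `cohort_carrier_rate` (0 by default: the causal variant is
#' absent from sporadic cases).
#'
#' @param vid Variant id carried by the cohort matrix.
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A genotype tibble with one row (the variant) and
#'   `cohort_n_samples` sample columns named `C0001`, `C0002`, ...
#' @export
simulate_cohort <- function(vid, config = simulation_config(), seed = 1) {
  set.seed(seed + 3L)
  n <- config$cohort_n_samples
  calls <- stats::rbinom(n, 1, config$cohort_carrier_rate)
  out <- tibble::as_tibble(as.list(stats::setNames(as.integer(calls),
                                                   sprintf("C%04d", seq_len(n)))))
  dplyr::bind_cols(tibble::tibble(vid = vid), out)
}

# serialize a genotype tibble + variant table as a minimal VCF 4.2 text file
write_vcf <- function(variants, gt, path) {
  samples <- gt_samples(gt)
  stopifnot(identical(variants$vid, gt$vid))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=fampri-synthetic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  code <- c("0/0", "0/1", "1/1")
  gt_cols <- vapply(samples, function(s) {
    x <- gt[[s]]
    ifelse(is.na(x), "./.", code[x + 1L])
  }, character(nrow(gt)))
  if (is.null(dim(gt_cols))) gt_cols <- matrix(gt_cols, nrow = nrow(gt))
  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt,
    ".", "PASS", ".", "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a complete synthetic family-WES study on disk
#'
#' Writes a runnable study into a directory: `study.vcf` (pedigree
#' genotypes), `study.ped`, `annotations.tsv`, `cohort.vcf` (validation
#' cohort restricted to the causal variant, when present) and `truth.json`
#' (causal vid, carrier ids, expected segregation). With the default fully
#' penetrant configuration, running [run_cascade()] on the outputs retains
#' the causal variant and reports its segregation as `TRUE`. Identical
#' `config` and `seed` give byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed driving every random draw.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `paths` (named list of written files) and
#'   the in-memory study objects (`ped`, `variants`, `genotypes`,
#'   `annotations`, `truth`).
#' @export
generate_study <- function(config = simulation_config(), seed = 1,
                           dir = tempfile("fampri_study_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- simulate_pedigree(config)
  variants <- simulate_variants(config, seed)
  sim <- simulate_genotypes(ped, variants, config, seed)
  ann <- simulate_annotations(variants, config, seed)

  paths <- list(
    vcf = file.path(dir, "study.vcf"),
    ped = file.path(dir, "study.ped"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(variants, sim$genotypes, paths$vcf)
  write_ped(ped, paths$ped)
  write_annotations(ann, paths$annotations)
  if (config$causal_present) {
    paths$cohort <- file.path(dir, "cohort.vcf")
    cohort <- simulate_cohort(sim$truth$causal_vid, config, seed)
    write_vcf(variants[variants$is_causal, , drop = FALSE], cohort,
              paths$cohort)
  }
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(list(paths = paths, ped = ped, variants = variants,
                 genotypes = sim$genotypes, annotations = ann,
                 truth = sim$truth))
}
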