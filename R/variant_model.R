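#' Read a biallelic VCF into a variant table and genotype matrix
#'
#' Parses a VCF 4.x text file (via \pkg{vcfR}) into a tibble of variant
#' records and a wide genotype table counting alternate alleles per sample.
#' Only biallelic SNV-style sites are accepted; multiallelic ALT fields are
#' an error rather than being silently split, because splitting risks
#' misassigning genotypes.
#'
#' Genotype strings are interpreted as unphased allele dosages:
#' `0/0` (or `0|0`) is 0, `0/1` and `1/0` are 1, `1/1` is 2, and `./.` (or
#' `.`) is missing (`NA`). Missing is deliberately distinct from 0 and stays
#' `NA` throughout the pipeline.
#'
#' @param path Path to a VCF file with a `GT` entry in FORMAT.
#' @return A list with two tibbles:
#'   \describe{
#'     \item{variants}{columns `chrom`, `pos`, `ref`, `alt`, `vid`.}
#'     \item{genotypes}{column `vid` followed by one integer column per
#'       sample with values 0/1/2 or `NA` for missing.}
#'   }
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, , drop = FALSE], stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(
      variants = tibble::tibble(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                vid = character()),
      genotypes = tibble::tibble(vid = character())
    ))
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    stop(sprintf("multiallelic ALT at data line %d (%s:%s); split sites are not supported",
                 which(multi)[1], fix$CHROM[which(multi)[1]], fix$POS[which(multi)[1]]),
         call. = FALSE)
  }

  variants <- tibble::tibble(
    chrom = fix$CHROM,
    pos   = as.integer(fix$POS),
    ref   = fix$REF,
    alt   = fix$ALT,
    vid   = make_vid(fix$CHROM, fix$POS, fix$REF, fix$ALT)
  )
  dup <- duplicated(variants$vid)
  if (any(dup)) {
    stop("duplicate variant id(s): ", paste(unique(variants$vid[dup]), collapse = ", "),
         call. = FALSE)
  }

  gt_part <- vcf@gt
  if (is.null(gt_part) || ncol(gt_part) < 2) {
    genotypes <- tibble::tibble(vid = variants$vid)
    return(list(variants = variants, genotypes = genotypes))
  }
  fmt <- gt_part[, "FORMAT"]
  has_gt <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) "GT" %in% f, logical(1))
  if (any(!has_gt)) {
    stop(sprintf("FORMAT without GT key at data line %d", which(!has_gt)[1]),
         call. = FALSE)
  }

  gt_chr <- vcfR::extract.gt(vcf, element = "GT", return.alleles = FALSE)
  gt_chr <- gsub("|", "/", gt_chr, fixed = TRUE)
  decode <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x %in% "0/0"] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% "1/1"] <- 2L
    bad <- !is.na(x) & !(x %in% c("0/0", "0/1", "1/0", "1/1", "./.", "."))
    if (any(bad)) {
      stop("unrecognized GT value: ", x[bad][1], call. = FALSE)
    }
    out
  }
  calls <- apply(gt_chr, 2, decode)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(gt_chr),
                                           dimnames = dimnames(gt_chr))
  genotypes <- tibble::as_tibble(as.data.frame(calls))
  genotypes <- dplyr::bind_cols(tibble::tibble(vid = variants$vid), genotypes)
  list(variants = variants, genotypes = genotypes)
}

#' Construct a pedigree table
#'
#' Validates member records and returns a tidy pedigree: one row per member
#' with parent links, sex, affection status and (optionally) whether the
#' member was genotyped. Parent ids must resolve to member rows or be `NA`;
#' cyclic parentage is an error.
#'
#' @param members Data frame with columns `id`, `father`, `mother`, `sex`
#'   (`"male"`, `"female"` or `"unknown"`), `affection` (`"affected"`,
#'   `"unaffected"` or `"unknown"`), and optionally `genotyped` (logical)
#'   and `family`.
#' @return A tibble of class `fampri_pedigree`.
#' @export
pedigree <- function(members) {
  members <- tibble::as_tibble(members)
  required <- c("id", "father", "mother", "sex", "affection")
  missing <- setdiff(required, names(members))
  if (length(missing) > 0) {
    stop("pedigree is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"genotyped" %in% names(members)) members$genotyped <- TRUE
  if (!"family" %in% names(members)) members$family <- "FAM1"
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)

  if (anyDuplicated(members$id)) {
    stop("duplicate member id(s): ",
         paste(unique(members$id[duplicated(members$id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_aff <- !members$affection %in% c("affected", "unaffected", "unknown")
  if (any(bad_aff)) {
    stop("invalid affection value: ", members$affection[bad_aff][1], call. = FALSE)
  }
  bad_sex <- !members$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop("invalid sex value: ", members$sex[bad_sex][1], call. = FALSE)
  }
  for (col in c("father", "mother")) {
    refs <- members[[col]]
    unresolved <- !is.na(refs) & !(refs %in% members$id)
    if (any(unresolved)) {
      stop(sprintf("unresolvable %s id '%s' for member '%s'",
                   col, refs[unresolved][1], members$id[unresolved][1]),
           call. = FALSE)
    }
  }

  # cycle check: walk ancestors of every member
  parent_of <- stats::setNames(
    lapply(seq_len(nrow(members)), function(i) {
      stats::na.omit(c(members$father[i], members$mother[i]))
    }),
    members$id
  )
  for (id in members$id) {
    seen <- character()
    frontier <- parent_of[[id]]
    while (length(frontier) > 0) {
      if (id %in% frontier) {
        stop("cyclic parentage involving member '", id, "'", call. = FALSE)
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(parent_of[frontier])), seen)
    }
  }

  out <- members[, c("family", "id", "father", "mother", "sex", "affection",
                     "genotyped")]
  class(out) <- c("fampri_pedigree", class(out))
  out
}

#' Read a 6-column PED pedigree file
#'
#' Reads the pre-MAKEPED PED dialect: whitespace-delimited columns
#' `family id father mother sex phenotype`, with parent id `0` meaning no
#' parent, sex `1` male / `2` female / other unknown, and phenotype `2`
#' affected / `1` unaffected / `0` or `-9` unknown.
#'
#' @param path Path to a PED file.
#' @return A `fampri_pedigree` tibble (see [pedigree()]).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("PED file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 6) {
    stop("PED file must have 6 columns (family id father mother sex phenotype)",
         call. = FALSE)
  }
  names(raw)[1:6] <- c("family", "id", "father", "mother", "sex", "phenotype")
  pedigree(tibble::tibble(
    family = raw$family,
    id     = raw$id,
    father = ifelse(raw$father == "0", NA_character_, raw$father),
    mother = ifelse(raw$mother == "0", NA_character_, raw$mother),
    sex    = dplyr::case_match(raw$sex, "1" ~ "male", "2" ~ "female",
                               .default = "unknown"),
    affection = dplyr::case_match(raw$phenotype, "2" ~ "affected",
                                  "1" ~ "unaffected", .default = "unknown")
  ))
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped A `fampri_pedigree` tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path) {
  lines <- sprintf(
    "%s\t%s\t%s\t%s\t%s\t%s",
    ped$family, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2", .default = "0"),
    dplyr::case_match(ped$affection, "affected" ~ "2", "unaffected" ~ "1",
                      .default = "0")
  )
  writeLines(lines, path)
  invisible(path)
}

# validate one annotation tibble (shared by read_annotations and constructors)
validate_annotations <- function(ann) {
  missing <- setdiff(ANNOTATION_COLUMNS, names(ann))
  if (length(missing) > 0) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$vid)) {
    stop("duplicate vid in annotation table: ",
         ann$vid[duplicated(ann$vid)][1], call. = FALSE)
  }
  check_enum <- function(col, levels) {
    x <- ann[[col]]
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' (row %d)",
                   x[bad][1], col, which(bad)[1]), call. = FALSE)
    }
  }
  check_enum("region", REGION_LEVELS)
  check_enum("function", FUNCTION_LEVELS)
  check_enum("sift_pred", SIFT_LEVELS)
  check_enum("pp2_hdiv_pred", PP2_LEVELS)
  check_enum("mt_pred", MT_LEVELS)
  for (col in c(AF_FIELDS, "sift_score", "pp2_hdiv_score", "mt_score")) {
    x <- ann[[col]]
    bad <- !is.na(x) & (x < 0 | x > 1)
    if (any(bad)) {
      stop(sprintf("value %g outside [0,1] in column '%s' (row %d)",
                   x[bad][1], col, which(bad)[1]), call. = FALSE)
    }
  }
  ann
}

#' Read a variant annotation table
#'
#' Reads a tab-separated annotation table with the fixed column set
#' `vid gene region function af_1000g_all af_1000g_eas af_exac_all
#' af_exac_eas sift_score sift_pred pp2_hdiv_score pp2_hdiv_pred mt_score
#' mt_pred`. Empty cells and the literal token `NA` (case-insensitive)
#' denote missing values. Allele frequencies and predictor scores must lie
#' in \[0, 1\]; categorical predictions are validated against their
#' enumerations (SIFT D/T; PolyPhen2 HDIV D/P/B; MutationTaster A/D/N/P).
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per variant.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  missing <- setdiff(ANNOTATION_COLUMNS, names(raw))
  if (length(missing) > 0) {
    stop("annotation table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  to_na <- function(x) ifelse(is.na(x) | x == "" | toupper(x) == "NA", NA_character_, x)
  raw <- dplyr::mutate(raw, dplyr::across(dplyr::everything(), to_na))
  num <- function(col) {
    x <- raw[[col]]
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' (row %d)",
                   x[bad][1], col, which(bad)[1]), call. = FALSE)
    }
    out
  }
  ann <- tibble::tibble(
    vid = raw$vid,
    gene = raw$gene,
    region = raw$region,
    `function` = raw$`function`,
    af_1000g_all = num("af_1000g_all"),
    af_1000g_eas = num("af_1000g_eas"),
    af_exac_all  = num("af_exac_all"),
    af_exac_eas  = num("af_exac_eas"),
    sift_score = num("sift_score"),
    sift_pred = raw$sift_pred,
    pp2_hdiv_score = num("pp2_hdiv_score"),
    pp2_hdiv_pred = raw$pp2_hdiv_pred,
    mt_score = num("mt_score"),
    mt_pred = raw$mt_pred
  )
  validate_annotations(ann)
}

#' Write a variant annotation table
#'
#' Inverse of [read_annotations()]; missing values are serialized as the
#' literal token `NA`.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  readr::write_tsv(ann[, ANNOTATION_COLUMNS], path, na = "NA", progress = FALSE)
  invisible(path)
}
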