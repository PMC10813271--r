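#' Worked example: candidate variants of an FNMTC discovery family
#'
#' The package ships, as in-code fixtures, the twelve annotated candidate
#' variants that survive the pre-frequency stages of a familial
#' non-medullary thyroid carcinoma (FNMTC) exome study: a two-generation
#' pedigree with four affected members in which a heterozygous *PPP4R3A*
#' missense variant (14:91942196 C>T, p.Asp409Asn) cosegregates with
#' papillary thyroid carcinoma. `fnmtc_annotations()` returns the annotation
#' table (population frequencies from 1000 Genomes and ExAC, SIFT /
#' PolyPhen2 HDIV / MutationTaster scores and calls), `fnmtc_pedigree()` the
#' family structure (six genotyped members: the affected parent II3, three
#' affected offspring III3/III5/III7, the elderly unaffected control II2 and
#' the unaffected offspring III9), `fnmtc_genotypes()` the
#' segregation-consistent dosage matrix (heterozygous in every affected
#' member, reference in both unaffected members), and `fnmtc_config()` the
#' matching cascade configuration (II2 as the cascade control).
#'
#' @return A tibble (or `cascade_config` for `fnmtc_config()`); see each
#'   function's description.
#' @name fnmtc_example
NULL

#' @rdname fnmtc_example
#' @export
fnmtc_annotations <- function() {
  rows <- tibble::tribble(
    ~gene,      ~chrom,  ~pos,      ~ref, ~alt,
    ~af_1000g_all, ~af_1000g_eas, ~af_exac_all, ~af_exac_eas,
    ~sift_score, ~sift_pred, ~pp2_hdiv_score, ~pp2_hdiv_pred,
    ~mt_score, ~mt_pred,
    "PPP4R3A", "chr14", 91942196L, "C", "T",
    NA,     NA,    NA,     NA,     0.24,  "T", 1,     "D", 1,     "D",
    "MANSC1",  "chr12", 12483454L, "G", "C",
    NA,     NA,    0,      0.0001, 0.016, "D", 0.025, "B", 1,     "N",
    "IQSEC3",  "chr12", 283790L,   "C", "T",
    NA,     NA,    0,      0.0001, 0.001, "D", 0.961, "D", 1,     "D",
    "MYL1",    "chr2",  211179708L, "G", "A",
    0.0002, NA,    0,      0.0006, 0.007, "D", 0.702, "P", 1,     "D",
    "VWF",     "chr12", 6153513L,  "C", "T",
    NA,     NA,    0,      0.0003, 0.017, "D", 0.999, "D", 1,     "D",
    "DUSP16",  "chr12", 12630669L, "C", "T",
    0.013,  0.005, 0.026,  0.013,  NA,    NA,  0.005, "B", 1,     "N",
    "CHD4",    "chr12", 6711144L,  "A", "C",
    0.0074, 0.034, 0.013,  0.0093, 0.267, "T", 0,     "B", 0.939, "N",
    "SSPO",    "chr7",  149475053L, "C", "T",
    0.004,  0.018, 0.001,  0.012,  NA,    NA,  0.001, "B", NA,    NA,
    "NLRP9",   "chr19", 56228104L, "C", "T",
    0.0026, 0.013, 0.0013, 0.018,  0.54,  "T", 0.059, "B", 1,     "N",
    "ANO2",    "chr12", 5853474L,  "C", "T",
    0.015,  0.025, 0.0059, 0.024,  0.973, "T", 0.285, "B", 1,     "D",
    "CTBS",    "chr1",  85029077L, "C", "T",
    0.15,   0.03,  0.2,    0.032,  0.109, "T", 0.489, "P", 0.017, "P",
    "OR51B4",  "chr11", 5322776L,  "G", "A",
    0.01,   0.044, 0.0049, 0.041,  0.012, "D", 0.185, "B", 1,     "N"
  )
  ann <- dplyr::mutate(rows,
                       vid = make_vid(.data$chrom, .data$pos, .data$ref,
                                      .data$alt),
                       region = "exonic",
                       `function` = "nonsynonymous_SNV")
  validate_annotations(ann[, ANNOTATION_COLUMNS])
}

#' @rdname fnmtc_example
#' @export
fnmtc_pedigree <- function() {
  simulate_pedigree(simulation_config())
}

#' @rdname fnmtc_example
#' @export
fnmtc_genotypes <- function() {
  ann <- fnmtc_annotations()
  tibble::tibble(
    vid = ann$vid,
    II2 = 0L, II3 = 1L, III3 = 1L, III5 = 1L, III7 = 1L, III9 = 0L
  )
}

#' @rdname fnmtc_example
#' @export
fnmtc_config <- function() {
  cascade_config(
    affected = c("II3", "III3", "III5", "III7"),
    controls = "II2"
  )
}
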