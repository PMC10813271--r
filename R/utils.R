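# Internal constants and small helpers shared across modules.

REGION_LEVELS <- c("exonic", "splicing", "intronic", "UTR3", "UTR5",
                   "intergenic", "ncRNA", "other")

FUNCTION_LEVELS <- c("nonsynonymous_SNV", "synonymous_SNV", "stopgain",
                     "stoploss", "frameshift", "nonframeshift", "unknown")

SIFT_LEVELS <- c("D", "T")
PP2_LEVELS  <- c("D", "P", "B")
MT_LEVELS   <- c("A", "D", "N", "P")

AF_FIELDS <- c("af_1000g_all", "af_1000g_eas", "af_exac_all", "af_exac_eas")

ANNOTATION_COLUMNS <- c("vid", "gene", "region", "function",
                        AF_FIELDS,
                        "sift_score", "sift_pred",
                        "pp2_hdiv_score", "pp2_hdiv_pred",
                        "mt_score", "mt_pred")

AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")

#' Normalize a chromosome label
#'
#' Strips a leading `"chr"` prefix so that `"chr14"` and `"14"` compare equal
#' when building variant identity keys.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
#' @examples
#' normalize_chrom(c("chr14", "14", "chrX"))
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Build a variant identity key
#'
#' The key is `"<chrom>:<pos>:<ref>:<alt>"` with the chromosome label
#' normalized by [normalize_chrom()]. It is the join key between genotype
#' matrices, annotation tables and candidate tables.
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic SNVs (1-based
#'   positions, single-reference/alternate allele strings).
#' @return Character vector of variant ids.
#' @export
#' @examples
#' make_vid("chr14", 91942196, "C", "T")
make_vid <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  stopifnot(all(pos >= 1L, na.rm = TRUE))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("ref and alt alleles must be non-empty", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

# sample columns of a genotype table (every column but vid)
gt_samples <- function(gt) {
  setdiff(names(gt), "vid")
}

assert_samples_present <- function(gt, ids, what = "sample") {
  missing <- setdiff(ids, gt_samples(gt))
  if (length(missing) > 0) {
    stop(sprintf("unknown %s id(s): %s", what, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

# genotype sub-matrix (variants x ids) as a plain integer matrix with vid rownames
gt_matrix <- function(gt, ids = gt_samples(gt)) {
  assert_samples_present(gt, ids)
  m <- as.matrix(gt[, ids, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- gt$vid
  m
}
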