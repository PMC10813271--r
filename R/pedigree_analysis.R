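#' Check cosegregation of a variant with the affected phenotype
#'
#' A variant segregates with the phenotype when every genotyped affected
#' family member carries the alternate allele (dosage 1 or 2) and no
#' designated control carries it. A missing genotype in an affected member
#' means carriage cannot be confirmed, so segregation is reported as
#' `FALSE`; a missing genotype in a control is not counted as carriage.
#'
#' @param gt Genotype table (`vid` column plus one dosage column per sample).
#' @param ped A `fampri_pedigree` tibble; affected members are those with
#'   `affection == "affected"` that appear in `gt`.
#' @param vid Variant id to test.
#' @param controls Character vector of control sample ids. Defaults to all
#'   genotyped unaffected pedigree members present in `gt`.
#' @return A one-row tibble: `vid`, `segregates`, `affected_carriers`,
#'   `control_carriers`, `informative_meioses`.
#' @export
check_segregation <- function(gt, ped, vid, controls = NULL) {
  stopifnot(length(vid) == 1)
  if (!vid %in% gt$vid) stop("variant not in genotype table: ", vid, call. = FALSE)
  affected <- intersect(ped$id[ped$affection == "affected"], gt_samples(gt))
  if (length(affected) == 0) {
    stop("no genotyped affected members in the pedigree", call. = FALSE)
  }
  if (is.null(controls)) {
    controls <- intersect(ped$id[ped$affection == "unaffected"], gt_samples(gt))
  }
  assert_samples_present(gt, controls, "control")
  bad <- setdiff(controls, ped$id[ped$affection == "unaffected"])
  if (length(bad) > 0) {
    stop("control(s) not unaffected pedigree members: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  row <- gt[gt$vid == vid, , drop = FALSE]
  aff_calls <- unlist(row[, affected, drop = FALSE])
  ctl_calls <- unlist(row[, controls, drop = FALSE])
  affected_carriers <- sum(aff_calls %in% c(1L, 2L))
  control_carriers <- sum(ctl_calls %in% c(1L, 2L))
  segregates <- !anyNA(aff_calls) &&
    affected_carriers == length(affected) &&
    control_carriers == 0
  m <- informative_meioses(gt, ped, vid)
  tibble::tibble(
    vid = vid,
    segregates = segregates,
    affected_carriers = affected_carriers,
    control_carriers = control_carriers,
    informative_meioses = m
  )
}

#' Count informative meioses for a variant
#'
#' An informative meiosis is a parent-to-offspring transmission in which a
#' genotyped carrier offspring has a genotyped carrier parent within the
#' pedigree. Founders and offspring whose carrier parent is not genotyped
#' are not counted: the count reflects observed carrier transmissions only,
#' which is the exponent of the chance-cosegregation probability
#' \eqn{(1/2)^m}.
#'
#' @inheritParams check_segregation
#' @return Integer count of informative meioses (0 when no transmissions
#'   are observable).
#' @export
informative_meioses <- function(gt, ped, vid) {
  stopifnot(length(vid) == 1)
  if (!vid %in% gt$vid) stop("variant not in genotype table: ", vid, call. = FALSE)
  row <- gt[gt$vid == vid, , drop = FALSE]
  genotyped <- intersect(ped$id, gt_samples(gt))
  carrier <- function(id) {
    id %in% genotyped && !is.na(row[[id]]) && row[[id]] >= 1L
  }
  m <- 0L
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    if (!carrier(id)) next
    parents <- stats::na.omit(c(ped$father[i], ped$mother[i]))
    if (length(parents) == 0) next  # founder
    if (any(vapply(parents, carrier, logical(1)))) m <- m + 1L
  }
  m
}

#' Chance cosegregation probability
#'
#' The probability that a neutral variant cosegregates with the phenotype by
#' chance across `m` informative meioses is \eqn{(1/2)^m}; under ACMG-style
#' variant assessment a small number of meioses (e.g. m = 3, probability
#' 0.125) supplies only supporting evidence of pathogenicity.
#'
#' @param m Non-negative integer count of informative meioses.
#' @return Probability in (0, 1].
#' @seealso [cosegregation_percent()] for the rendered percentage.
#' @export
#' @examples
#' cosegregation_probability(3) # 0.125
cosegregation_probability <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 0 || m != as.integer(m)) {
    stop("m must be a single non-negative integer", call. = FALSE)
  }
  0.5^m
}

#' Cosegregation probability rendered as a percentage
#'
#' @inheritParams cosegregation_probability
#' @return Character scalar, the probability as a percentage rounded to one
#'   decimal (e.g. `"12.5%"` for m = 3).
#' @export
cosegregation_percent <- function(m) {
  sprintf("%.1f%%", 100 * cosegregation_probability(m))
}
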