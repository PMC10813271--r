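#' Screen a cohort genotype matrix for a candidate variant
#'
#' Counts carriers (dosage 1 or 2) of a variant across an independent cohort
#' — the presence/absence validation step applied to sporadic cases after a
#' family candidate has been prioritized. Samples with a missing genotype
#' are excluded from the allele-frequency denominator, and the `absent`
#' claim is driven by the carrier count (per-sample presence/absence, as in
#' Sanger validation), not by the allele count.
#'
#' @param gt Cohort genotype table (`vid` column plus one dosage column per
#'   sample).
#' @param vid Variant id to screen.
#' @return A one-row tibble: `vid`, `n_samples`, `n_missing`, `n_carriers`,
#'   `allele_count`, `allele_freq` (= allele_count / (2 * (n_samples -
#'   n_missing)); `NA` when no sample is genotyped) and `absent`.
#' @export
screen_cohort <- function(gt, vid) {
  stopifnot(length(vid) == 1)
  if (!vid %in% gt$vid) stop("variant not in cohort matrix: ", vid, call. = FALSE)
  samples <- gt_samples(gt)
  calls <- unlist(gt[gt$vid == vid, samples, drop = FALSE])
  n_samples <- length(samples)
  n_missing <- sum(is.na(calls))
  n_carriers <- sum(calls %in% c(1L, 2L))
  allele_count <- sum(calls, na.rm = TRUE)
  denom <- 2 * (n_samples - n_missing)
  tibble::tibble(
    vid = vid,
    n_samples = n_samples,
    n_missing = n_missing,
    n_carriers = n_carriers,
    allele_count = allele_count,
    allele_freq = if (denom > 0) allele_count / denom else NA_real_,
    absent = n_carriers == 0
  )
}

#' Read a population frequency table
#'
#' Reads a TSV with columns `vid`, `population`, `af` — the shape of a
#' frequency extract from a population catalogue (gnomAD, ExAC, 1000
#' Genomes).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `vid`, `population`, `af`.
#' @export
read_frequency_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    vid = "c", population = "c", af = "d"
  ), na = "NA", progress = FALSE)
  missing <- setdiff(c("vid", "population", "af"), names(tab))
  if (length(missing) > 0) {
    stop("frequency table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(tab$af) & (tab$af < 0 | tab$af > 1)
  if (any(bad)) {
    stop("allele frequency outside [0,1] at row ", which(bad)[1], call. = FALSE)
  }
  tab
}

#' Look up a variant in a population frequency table
#'
#' A variant missing from the table is reported as absent from the
#' catalogue rather than raising an error — absence from a population
#' resource is itself the evidence of interest for a rare candidate.
#'
#' @param freq_table Tibble with columns `vid`, `population`, `af`
#'   (see [read_frequency_table()]).
#' @param vid Variant id to look up.
#' @param population Optional population label to restrict the lookup
#'   (e.g. `"EAS"`).
#' @return A one-row tibble: `vid`, `population`, `af` (`NA` when absent)
#'   and `absent`.
#' @export
population_lookup <- function(freq_table, vid, population = NULL) {
  stopifnot(length(vid) == 1)
  hits <- freq_table[freq_table$vid == vid, , drop = FALSE]
  if (!is.null(population)) {
    hits <- hits[hits$population %in% population, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    return(tibble::tibble(vid = vid,
                          population = population %||% NA_character_,
                          af = NA_real_, absent = TRUE))
  }
  tibble::tibble(vid = vid,
                 population = hits$population[1],
                 af = hits$af[1],
                 absent = FALSE)
}
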