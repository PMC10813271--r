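#' Band a SIFT score into a categorical call
#'
#' SIFT scores at or below 0.05 are called Deleterious (`"D"`), larger
#' scores Tolerated (`"T"`). `NA` scores yield `NA` calls.
#'
#' @param score Numeric vector of SIFT scores in \[0, 1\].
#' @return Character vector of `"D"`/`"T"` calls.
#' @export
#' @examples
#' classify_sift(c(0.016, 0.24, 0.05))
classify_sift <- function(score) {
  stopifnot(all(is.na(score) | (score >= 0 & score <= 1)))
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score <= 0.05 ~ "D",
    .default = "T"
  )
}

#' Band a PolyPhen2 HDIV score into a categorical call
#'
#' Scores of at least 0.957 are Probably damaging (`"D"`), scores between
#' 0.453 and 0.956 Possibly damaging (`"P"`), and scores at or below 0.452
#' Benign (`"B"`). The published bands leave the intervals (0.452, 0.453)
#' and (0.956, 0.957) unassigned; scores falling there are assigned to the
#' lower (more benign) band.
#'
#' @param score Numeric vector of PolyPhen2 HDIV scores in \[0, 1\].
#' @return Character vector of `"D"`/`"P"`/`"B"` calls.
#' @export
#' @examples
#' classify_pp2_hdiv(c(0.961, 0.702, 0.285))
classify_pp2_hdiv <- function(score) {
  stopifnot(all(is.na(score) | (score >= 0 & score <= 1)))
  dplyr::case_when(
    is.na(score) ~ NA_character_,
    score >= 0.957 ~ "D",
    score >= 0.453 ~ "P",
    .default = "B"
  )
}

#' Is a MutationTaster prediction a harmful call?
#'
#' Both `"A"` (disease-causing automatic) and `"D"` (disease-causing)
#' indicate potentially harmful variants; `"N"`/`"P"` are polymorphism
#' calls and `NA` (no prediction) counts as not harmful.
#'
#' @param pred Character vector of MutationTaster predictions
#'   (`"A"`, `"D"`, `"N"`, `"P"` or `NA`).
#' @return Logical vector.
#' @export
harmful_mt <- function(pred) {
  bad <- !is.na(pred) & !(pred %in% MT_LEVELS)
  if (any(bad)) stop("invalid MutationTaster prediction: ", pred[bad][1],
                     call. = FALSE)
  !is.na(pred) & pred %in% c("A", "D")
}

#' Composite hazard score from three predictor calls
#'
#' The score sums per-predictor weights: SIFT `"D"` contributes 1;
#' PolyPhen2 HDIV `"D"` contributes 1 and `"P"` contributes 0.5;
#' a harmful MutationTaster call (`"A"` or `"D"`) contributes 1. Any other
#' call, including a missing one, contributes 0, so the score lies in
#' \{0, 0.5, 1, ..., 3\}.
#'
#' @param sift Character vector of SIFT calls (`"D"`/`"T"`/`NA`).
#' @param pp2 Character vector of PolyPhen2 HDIV calls (`"D"`/`"P"`/`"B"`/`NA`).
#' @param mt Character vector of MutationTaster calls (`"A"`/`"D"`/`"N"`/`"P"`/`NA`).
#' @return Numeric vector of hazard scores.
#' @export
#' @examples
#' hazard_score("T", "D", "D") # 2
#' hazard_score("D", "P", "D") # 2.5
hazard_score <- function(sift, pp2, mt) {
  check <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) stop("invalid ", what, " call: ", x[bad][1], call. = FALSE)
  }
  check(sift, SIFT_LEVELS, "SIFT")
  check(pp2, PP2_LEVELS, "PolyPhen2")
  check(mt, MT_LEVELS, "MutationTaster")
  w_sift <- as.numeric(!is.na(sift) & sift == "D")
  w_pp2 <- dplyr::case_when(
    is.na(pp2) ~ 0,
    pp2 == "D" ~ 1,
    pp2 == "P" ~ 0.5,
    .default = 0
  )
  w_mt <- as.numeric(harmful_mt(mt))
  w_sift + w_pp2 + w_mt
}

#' Score annotated variants with the composite hazard score
#'
#' Adds effective predictor calls and a `hazard_score` column to an
#' annotation table. Categorical predictions present in the table take
#' precedence; banding from the numeric score (via [classify_sift()] and
#' [classify_pp2_hdiv()]) is used only to fill missing SIFT and PolyPhen2
#' calls. MutationTaster has no score-to-band rule, so a missing prediction
#' stays missing.
#'
#' @param ann Annotation tibble (see [read_annotations()]).
#' @return The input tibble with an added `hazard_score` column.
#' @export
score_candidates <- function(ann) {
  sift_call <- ifelse(is.na(ann$sift_pred),
                      classify_sift(ann$sift_score), ann$sift_pred)
  pp2_call <- ifelse(is.na(ann$pp2_hdiv_pred),
                     classify_pp2_hdiv(ann$pp2_hdiv_score), ann$pp2_hdiv_pred)
  dplyr::mutate(ann,
                hazard_score = hazard_score(sift_call, pp2_call, ann$mt_pred))
}

#' Rank scored candidates
#'
#' Orders candidate rows by hazard score (descending). Ties are broken by
#' PolyPhen2 HDIV score descending, then SIFT score ascending (lower SIFT is
#' more deleterious; missing scores sort last), then gene symbol. The
#' ordering is advisory: no single candidate is auto-selected.
#'
#' @param scored Tibble with a `hazard_score` column (from
#'   [score_candidates()]).
#' @return The same tibble ordered by priority with an integer `rank`
#'   column (1 = highest priority).
#' @export
rank_candidates <- function(scored) {
  out <- dplyr::arrange(
    scored,
    dplyr::desc(.data$hazard_score),
    dplyr::desc(.data$pp2_hdiv_score),
    .data$sift_score,
    .data$gene
  )
  dplyr::mutate(out, rank = dplyr::row_number())
}
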