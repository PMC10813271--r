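#' Candidate table construction
#'
#' A candidate table is the ordered output of the filter cascade: one row
#' per surviving variant with its annotation fields, composite hazard score
#' and rank, carrying per-stage audit counts and per-variant segregation
#' results as attributes.
#'
#' @param rows Tibble of ranked candidate rows (annotation columns plus
#'   `hazard_score` and `rank`).
#' @param stage_counts Tibble with columns `stage` and `n`, one row per
#'   cascade stage in execution order (non-increasing `n`).
#' @param segregation Optional tibble of per-variant segregation results.
#' @return A tibble of class `fampri_candidates`.
#' @export
candidate_table <- function(rows, stage_counts,
                            segregation = NULL) {
  rows <- tibble::as_tibble(rows)
  stage_counts <- tibble::as_tibble(stage_counts)
  stopifnot(all(c("stage", "n") %in% names(stage_counts)))
  if (any(diff(stage_counts$n) > 0)) {
    stop("stage counts must be non-increasing along the cascade", call. = FALSE)
  }
  if (nrow(rows) > 0 && !setequal(rows$rank, seq_len(nrow(rows)))) {
    stop("rank must be a permutation of 1..n", call. = FALSE)
  }
  structure(
    rows,
    stage_counts = stage_counts,
    segregation = segregation,
    class = c("fampri_candidates", class(rows))
  )
}

#' Per-stage audit counts of a candidate table
#'
#' @param x A `fampri_candidates` table.
#' @return A tibble with columns `stage` and `n`.
#' @export
stage_counts <- function(x) {
  attr(x, "stage_counts")
}

#' Per-variant segregation results attached to a candidate table
#'
#' @param x A `fampri_candidates` table.
#' @return A tibble of segregation results, or `NULL` if none were attached.
#' @export
segregation_results <- function(x) {
  attr(x, "segregation")
}

#' Write a candidate table (TSV plus audit sidecar)
#'
#' Writes the candidate rows as a TSV mirroring the annotation column set
#' plus `hazard_score` and `rank` (missing values as `NA`), and a sidecar
#' JSON file `<path>.audit.json` holding the stage counts and any
#' segregation results.
#'
#' @param table A `fampri_candidates` table.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_candidates <- function(table, path) {
  cols <- c(ANNOTATION_COLUMNS, "hazard_score", "rank")
  rows <- tibble::as_tibble(table)[, cols, drop = FALSE]
  readr::write_tsv(rows, path, na = "NA", progress = FALSE)
  audit <- list(stage_counts = stage_counts(table))
  seg <- segregation_results(table)
  if (!is.null(seg)) audit$segregation <- seg
  jsonlite::write_json(audit, paste0(path, ".audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read back a candidate table written by [write_candidates()]
#'
#' @param path TSV path previously passed to [write_candidates()].
#' @return A `fampri_candidates` tibble with its audit attributes restored.
#' @export
read_candidates <- function(path) {
  if (!file.exists(path)) stop("candidate file not found: ", path, call. = FALSE)
  rows <- readr::read_tsv(
    path,
    col_types = readr::cols(
      vid = "c", gene = "c", region = "c", `function` = "c",
      sift_pred = "c", pp2_hdiv_pred = "c", mt_pred = "c",
      rank = "i", .default = "d"
    ),
    na = "NA", progress = FALSE
  )
  sidecar <- paste0(path, ".audit.json")
  stages <- tibble::tibble(stage = character(), n = integer())
  seg <- NULL
  if (file.exists(sidecar)) {
    audit <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    stages <- tibble::as_tibble(audit$stage_counts)
    if (!is.null(audit$segregation)) seg <- tibble::as_tibble(audit$segregation)
  }
  candidate_table(rows, stages, segregation = seg)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a candidate table into a plain tibble
#'
#' @param x A `fampri_candidates` table.
#' @param ... Unused.
#' @return A plain tibble of the candidate rows, ordered by rank.
#' @export
tidy.fampri_candidates <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  dplyr::arrange(out, .data$rank)
}

#' One-row summary of a cascade run
#'
#' @param x A `fampri_candidates` table.
#' @param ... Unused.
#' @return A one-row tibble: variants in, variants retained, number of
#'   stages, top-ranked gene and its hazard score.
#' @export
glance.fampri_candidates <- function(x, ...) {
  sc <- stage_counts(x)
  top <- dplyr::slice_min(tibble::as_tibble(x), .data$rank, n = 1,
                          with_ties = FALSE)
  tibble::tibble(
    n_input = if (nrow(sc) > 0) sc$n[1] else nrow(x),
    n_retained = nrow(x),
    n_stages = max(nrow(sc) - 1L, 0L),
    top_gene = if (nrow(top) > 0) top$gene else NA_character_,
    top_hazard_score = if (nrow(top) > 0) top$hazard_score else NA_real_
  )
}

#' @export
print.fampri_candidates <- function(x, ...) {
  sc <- stage_counts(x)
  cat(sprintf("<fampri_candidates> %d candidate variant(s)\n", nrow(x)))
  if (nrow(sc) > 0) {
    cat("cascade:", paste(sprintf("%s=%d", sc$stage, sc$n), collapse = " -> "),
        "\n")
  }
  NextMethod()
}
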