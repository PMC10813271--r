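#' Cascade configuration
#'
#' Bundles the sample designations and filter settings of the multi-stage
#' family filter cascade. Defaults follow the dominant-model family study
#' design: keep exonic and splicing variants, drop synonymous changes, and
#' exclude variants whose East Asian allele frequency (1000 Genomes EAS or
#' ExAC EAS) exceeds 0.001 (strictly greater; a frequency equal to the
#' threshold is kept). Variants with no catalogued frequency pass under the
#' default `na_policy = "pass"`.
#'
#' @param affected Character vector of affected sample ids (non-empty).
#' @param controls Character vector of control sample ids (may be empty);
#'   must be disjoint from `affected`.
#' @param keep_regions Regions retained by the region filter.
#' @param drop_functions Function classes removed by the function filter.
#' @param af_fields Allele-frequency columns screened by the frequency
#'   filter.
#' @param af_threshold Exclusion threshold; a variant is dropped when its
#'   maximum non-missing screened frequency is strictly greater.
#' @param na_policy `"pass"` keeps variants whose screened frequencies are
#'   all missing; `"fail"` drops them.
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(affected,
                           controls = character(),
                           keep_regions = c("exonic", "splicing"),
                           drop_functions = "synonymous_SNV",
                           af_fields = c("af_1000g_eas", "af_exac_eas"),
                           af_threshold = 0.001,
                           na_policy = c("pass", "fail")) {
  na_policy <- match.arg(na_policy)
  affected <- as.character(affected)
  controls <- as.character(controls)
  if (length(affected) == 0) stop("affected set must be non-empty", call. = FALSE)
  if (length(intersect(affected, controls)) > 0) {
    stop("affected and control sets must be disjoint", call. = FALSE)
  }
  if (!is.numeric(af_threshold) || af_threshold < 0 || af_threshold > 1) {
    stop("af_threshold must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(all(keep_regions %in% REGION_LEVELS),
            all(drop_functions %in% FUNCTION_LEVELS),
            all(af_fields %in% AF_FIELDS))
  structure(
    list(affected = affected, controls = controls,
         keep_regions = keep_regions, drop_functions = drop_functions,
         af_fields = af_fields, af_threshold = af_threshold,
         na_policy = na_policy),
    class = "cascade_config"
  )
}

#' Read or write a cascade configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_cascade_config()` returns a `cascade_config`;
#'   `write_cascade_config()` returns `path` invisibly.
#' @export
read_cascade_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cascade_config(
    affected = x$affected,
    controls = x$controls %||% character(),
    keep_regions = x$keep_regions %||% c("exonic", "splicing"),
    drop_functions = x$drop_functions %||% "synonymous_SNV",
    af_fields = x$af_fields %||% c("af_1000g_eas", "af_exac_eas"),
    af_threshold = x$af_threshold %||% 0.001,
    na_policy = x$na_policy %||% "pass"
  )
}

#' @rdname read_cascade_config
#' @param config A `cascade_config` object.
#' @export
write_cascade_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Intersection filter: variants carried by every affected member
#'
#' Keeps a variant only when every affected sample carries the alternate
#' allele (dosage 1 or 2). A missing genotype in an affected member excludes
#' the variant: carriage cannot be confirmed.
#'
#' @param gt Genotype table.
#' @param affected Character vector of affected sample ids.
#' @param vids Variant ids to consider (default: all in `gt`).
#' @return Character vector of surviving variant ids.
#' @export
intersect_affected <- function(gt, affected, vids = gt$vid) {
  if (length(affected) == 0) stop("affected set must be non-empty", call. = FALSE)
  m <- gt_matrix(gt, affected)
  keep <- rowSums(m >= 1L) == length(affected)  # NA propagates to FALSE below
  keep[is.na(keep)] <- FALSE
  intersect(vids, gt$vid[keep])
}

#' Control-exclusion filter
#'
#' Drops a variant when any control sample carries the alternate allele.
#' A missing control genotype does not count as carriage.
#'
#' @param gt Genotype table.
#' @param vids Variant ids entering the stage.
#' @param controls Character vector of control sample ids; with no controls
#'   the stage is a no-op.
#' @return Character vector of surviving variant ids.
#' @export
exclude_controls <- function(gt, vids, controls) {
  if (length(controls) == 0) return(vids)
  m <- gt_matrix(gt, controls)
  carrier <- rowSums(m >= 1L, na.rm = TRUE) > 0
  setdiff(vids, gt$vid[carrier])
}

assert_annotated <- function(ann, vids) {
  missing <- setdiff(vids, ann$vid)
  if (length(missing) > 0) {
    stop("no annotation for variant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}

#' Region filter
#'
#' Keeps variants whose annotated region is in `keep_regions` (default
#' exonic and splicing: intronic, UTR and other non-coding classes are
#' removed).
#'
#' @param ann Annotation tibble.
#' @param vids Variant ids entering the stage.
#' @param keep_regions Character vector of regions to retain.
#' @return Character vector of surviving variant ids.
#' @export
filter_region <- function(ann, vids, keep_regions = c("exonic", "splicing")) {
  assert_annotated(ann, vids)
  sub <- ann[match(vids, ann$vid), ]
  vids[sub$region %in% keep_regions]
}

#' Function-class filter
#'
#' Drops variants whose annotated function class is in `drop_functions`
#' (default: synonymous substitutions).
#'
#' @param ann Annotation tibble.
#' @param vids Variant ids entering the stage.
#' @param drop_functions Character vector of function classes to remove.
#' @return Character vector of surviving variant ids.
#' @export
filter_function <- function(ann, vids, drop_functions = "synonymous_SNV") {
  assert_annotated(ann, vids)
  sub <- ann[match(vids, ann$vid), ]
  vids[!(sub$`function` %in% drop_functions)]
}

#' Zygosity filter
#'
#' Drops variants that are homozygous for the alternate allele in every
#' affected member (fully homozygous sites are implausible under the
#' dominant model being screened); any heterozygous or missing affected
#' call keeps the variant.
#'
#' @param gt Genotype table.
#' @param vids Variant ids entering the stage.
#' @param affected Character vector of affected sample ids.
#' @return Character vector of surviving variant ids.
#' @export
filter_zygosity <- function(gt, vids, affected) {
  m <- gt_matrix(gt, affected)
  all_hom <- rowSums(m == 2L) == length(affected)
  all_hom[is.na(all_hom)] <- FALSE
  setdiff(vids, gt$vid[all_hom])
}

#' Population allele-frequency filter
#'
#' Drops a variant when the maximum of its non-missing screened frequency
#' fields is strictly greater than `af_threshold`. Variants whose screened
#' fields are all missing are kept under `na_policy = "pass"` (absence from
#' population catalogues is evidence of rarity) and dropped under `"fail"`.
#'
#' @param ann Annotation tibble.
#' @param vids Variant ids entering the stage.
#' @param af_fields Frequency columns to screen.
#' @param af_threshold Exclusion threshold (strict inequality).
#' @param na_policy `"pass"` or `"fail"` for all-missing rows.
#' @return Character vector of surviving variant ids.
#' @export
filter_af <- function(ann, vids,
                      af_fields = c("af_1000g_eas", "af_exac_eas"),
                      af_threshold = 0.001,
                      na_policy = c("pass", "fail")) {
  na_policy <- match.arg(na_policy)
  assert_annotated(ann, vids)
  sub <- ann[match(vids, ann$vid), af_fields, drop = FALSE]
  af_max <- apply(as.matrix(sub), 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  keep <- ifelse(is.na(af_max), na_policy == "pass", af_max <= af_threshold)
  vids[keep]
}

#' Run the full family filter cascade
#'
#' Applies the stages in order: intersection over affected members, control
#' exclusion, region filter, function filter, zygosity filter, and the
#' population allele-frequency screen. Surviving variants are scored with
#' the composite hazard score, ranked, and returned as a
#' [candidate_table()] carrying per-stage audit counts and per-variant
#' segregation results.
#'
#' @param gt Genotype table (from [read_vcf()]).
#' @param ann Annotation tibble (from [read_annotations()]).
#' @param ped A `fampri_pedigree` (from [read_ped()]); used for the
#'   segregation annotation of surviving variants.
#' @param config A [cascade_config()].
#' @param verbose Emit one `stage=<name> in=<n> out=<m>` message per stage.
#' @return A `fampri_candidates` tibble.
#' @export
run_cascade <- function(gt, ann, ped, config, verbose = FALSE) {
  stopifnot(inherits(config, "cascade_config"))
  assert_samples_present(gt, config$affected, "affected sample")
  assert_samples_present(gt, config$controls, "control sample")

  stages <- list(
    intersect_affected = function(v) intersect_affected(gt, config$affected, v),
    exclude_controls   = function(v) exclude_controls(gt, v, config$controls),
    filter_region      = function(v) filter_region(ann, v, config$keep_regions),
    filter_function    = function(v) filter_function(ann, v, config$drop_functions),
    filter_zygosity    = function(v) filter_zygosity(gt, v, config$affected),
    filter_af          = function(v) filter_af(ann, v, config$af_fields,
                                               config$af_threshold,
                                               config$na_policy)
  )

  vids <- gt$vid
  counts <- tibble::tibble(stage = "input", n = length(vids))
  for (stage in names(stages)) {
    n_in <- length(vids)
    vids <- stages[[stage]](vids)
    if (verbose) {
      message(sprintf("stage=%s in=%d out=%d", stage, n_in, length(vids)))
    }
    counts <- dplyr::bind_rows(counts,
                               tibble::tibble(stage = stage, n = length(vids)))
  }

  surviving <- ann[ann$vid %in% vids, , drop = FALSE]
  ranked <- rank_candidates(score_candidates(surviving))

  seg <- NULL
  if (nrow(ranked) > 0) {
    seg <- purrr::map_dfr(ranked$vid, function(v) {
      check_segregation(gt, ped, v, controls = config$controls)
    })
  }
  candidate_table(ranked, counts, segregation = seg)
}
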