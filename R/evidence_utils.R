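#' Read an aligned FASTA file
#'
#' Reads a pre-aligned amino-acid FASTA (all sequences the same length,
#' gaps as `-`) into a named character vector of sequence strings.
#'
#' @param path Path to the aligned FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path, call. = FALSE)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(recs) == 0) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(vapply(recs, function(s) as.character(s)[1], character(1)))
  names(seqs) <- names(recs)
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  seqs
}

#' Extract one alignment column
#'
#' @param aln Named character vector of equal-length aligned sequences
#'   (from [read_alignment()]).
#' @param position 1-based alignment column index.
#' @return Character vector of single-letter residues, one per sequence.
#' @export
alignment_column <- function(aln, position) {
  width <- unique(nchar(aln))
  stopifnot(length(width) == 1, position >= 1, position <= width)
  substr(aln, position, position)
}

#' Conservation of an alignment column
#'
#' Fraction of non-gap rows whose residue is identical to the reference
#' row's residue. Gap rows are excluded from the denominator (a deletion
#' carries no information about the residue's identity), and conservation
#' is exact-identity based: no substitution-matrix similarity is applied,
#' because the claim being tested is literal preservation of the residue
#' across species.
#'
#' @param residues Character vector of single-letter amino-acid codes
#'   (20-letter alphabet plus `"X"` and the gap `"-"`).
#' @param reference_index Row holding the reference residue; must not be a
#'   gap.
#' @return A one-row tibble: `reference`, `n_match`, `n_informative`,
#'   `fraction`, `is_invariant`.
#' @export
#' @examples
#' column_conservation(c("D", "D", "D", "D", "E", "E", "D", "D"))
column_conservation <- function(residues, reference_index = 1) {
  residues <- toupper(as.character(residues))
  if (length(residues) == 0) stop("alignment column is empty", call. = FALSE)
  bad <- !(residues %in% AA_ALPHABET)
  if (any(bad)) {
    stop("invalid residue code: ", residues[bad][1], call. = FALSE)
  }
  stopifnot(reference_index >= 1, reference_index <= length(residues))
  ref <- residues[reference_index]
  if (ref == "-") stop("reference residue must not be a gap", call. = FALSE)
  informative <- residues[residues != "-"]
  n_match <- sum(informative == ref)
  frac <- n_match / length(informative)
  tibble::tibble(
    reference = ref,
    n_match = n_match,
    n_informative = length(informative),
    fraction = frac,
    is_invariant = frac == 1
  )
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' Computes the qPCR fold change 2^-((Ct_target,case - Ct_ref,case) -
#' (Ct_target,ctrl - Ct_ref,ctrl)): target-gene cycle thresholds normalized
#' to an internal reference gene (e.g. GAPDH) in each sample, then to the
#' control condition. All arguments are vectorized.
#'
#' @param ct_target_case,ct_ref_case Cycle thresholds of the target and
#'   reference gene in the case/treatment sample.
#' @param ct_target_ctrl,ct_ref_ctrl Cycle thresholds in the control sample.
#' @return Numeric vector of fold changes (1 = no change; each additional
#'   cycle of ddCt halves the value).
#' @export
#' @examples
#' ddct_fold_change(20, 18, 22, 20) # ddCt = 0 -> 1
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  vals <- cbind(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all Ct values must be finite positive numbers", call. = FALSE)
  }
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Read a 4-column qPCR cycle-threshold table
#'
#' Reads a TSV with columns `ct_target_case`, `ct_ref_case`,
#' `ct_target_ctrl`, `ct_ref_ctrl` and appends the fold change computed by
#' [ddct_fold_change()].
#'
#' @param path Path to the TSV.
#' @return A tibble with the four Ct columns plus `fold_change`.
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "d"),
                         na = "NA", progress = FALSE)
  required <- c("ct_target_case", "ct_ref_case", "ct_target_ctrl", "ct_ref_ctrl")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("Ct table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dplyr::mutate(tab, fold_change = ddct_fold_change(
    .data$ct_target_case, .data$ct_ref_case,
    .data$ct_target_ctrl, .data$ct_ref_ctrl
  ))
}
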