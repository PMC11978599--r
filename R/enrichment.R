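#' Classify tissue-enriched genes from a bulk expression matrix
#'
#' Applies the Human-Protein-Atlas-style "tissue enriched" rule: a gene is
#' enriched in the target tissue when its expression there is at least
#' `fold_threshold` times the maximum across all other tissues (inclusive) and
#' above `expression_floor`, which suppresses ratio artifacts at near-zero
#' expression. Ratio conventions: 0/0 gives 0, x/0 gives +Inf for x > 0.
#'
#' @param expr Tibble with a `gene` column and one numeric column per tissue.
#' @param target_tissue Tissue column to test for enrichment.
#' @param fold_threshold Minimum fold change over the maximum other tissue
#'   (must exceed 1).
#' @param expression_floor Minimum target-tissue expression.
#' @return Tibble with one row per gene: `gene`, `target_expression`,
#'   `max_other`, `fold_over_max_other`, `enriched`.
#' @export
classify_tissue_enriched <- function(expr, target_tissue = "brain",
                                     fold_threshold = 4,
                                     expression_floor = 1) {
  if (!"gene" %in% names(expr)) abort("`expr` needs a `gene` column")
  tissues <- setdiff(names(expr), "gene")
  if (!target_tissue %in% tissues) {
    abort(sprintf("target tissue '%s' not present in matrix", target_tissue))
  }
  if (fold_threshold <= 1) abort("`fold_threshold` must exceed 1")
  vals <- as.matrix(expr[tissues])
  if (anyNA(vals) || any(vals < 0)) {
    abort("expression values must be non-negative and complete")
  }
  target <- vals[, target_tissue]
  other <- vals[, setdiff(tissues, target_tissue), drop = FALSE]
  max_other <- apply(other, 1, max)
  fold <- ifelse(max_other > 0, target / max_other,
                 ifelse(target > 0, Inf, 0))
  tibble::tibble(
    gene = expr$gene,
    target_expression = target,
    max_other = max_other,
    fold_over_max_other = fold,
    enriched = fold >= fold_threshold & target >= expression_floor
  )
}

#' Quality-control filter for the proteomics matrix
#'
#' Drops proteins with strictly more than `missing_threshold` missingness
#' ("over 10%" by default, so exactly 10% is retained) and proteins on an
#' explicit quality-control failure list. Every input protein appears in the
#' report.
#'
#' @param proteins Tibble: `participant` column plus one column per protein.
#' @param missing_threshold Maximum tolerated missing fraction (exclusive).
#' @param qc_fail_ids Proteins to drop regardless of missingness.
#' @return List with `proteins` (filtered tibble, column order preserved) and
#'   `report` (tibble: protein, missing_fraction, excluded, reason).
#' @export
qc_filter_proteins <- function(proteins, missing_threshold = 0.10,
                               qc_fail_ids = character()) {
  assert_prob(missing_threshold, "missing_threshold")
  prots <- setdiff(names(proteins), "participant")
  if (length(prots) == 0L) abort("proteomics matrix has no protein columns")
  miss <- purrr::map_dbl(proteins[prots], ~ mean(is.na(.x)))
  report <- tibble::tibble(
    protein = prots,
    missing_fraction = unname(miss),
    excluded = miss > missing_threshold | prots %in% qc_fail_ids,
    reason = dplyr::case_when(
      prots %in% qc_fail_ids ~ "qc_fail",
      miss > missing_threshold ~ "missingness",
      TRUE ~ "retained"
    )
  )
  keep <- c("participant", report$protein[!report$excluded])
  list(proteins = proteins[intersect(names(proteins), keep)], report = report)
}

#' Median-impute missing protein values
#'
#' Replaces each missing cell by the protein's observed median; observed cells
#' are untouched. Median (rather than mean) imputation is the deliberate
#' choice for the log-like NPX abundance scale.
#'
#' @param proteins Tibble: `participant` plus protein columns.
#' @return Tibble of the same shape with no missing protein values.
#' @export
impute_protein_values <- function(proteins) {
  prots <- setdiff(names(proteins), "participant")
  for (p in prots) {
    x <- proteins[[p]]
    if (all(is.na(x))) {
      abort(sprintf("protein '%s' has no observed values; cannot impute", p))
    }
    x[is.na(x)] <- median(x, na.rm = TRUE)
    proteins[[p]] <- x
  }
  proteins
}

#' Restrict a proteomics matrix to brain-enriched proteins
#'
#' Keeps the protein columns whose mapped gene was called enriched. Olink-style
#' panels index proteins by gene symbol, so the default mapping is the
#' identity.
#'
#' @param proteins Tibble: `participant` plus protein columns.
#' @param calls Output of [classify_tissue_enriched()].
#' @param mapping Optional two-column tibble (`protein`, `gene`); identity if
#'   `NULL`.
#' @param strict If `TRUE`, a protein without a gene mapping is an error;
#'   otherwise it is dropped with a warning.
#' @return Tibble restricted to `participant` + enriched proteins, column
#'   order preserved.
#' @export
select_brain_enriched <- function(proteins, calls, mapping = NULL,
                                  strict = TRUE) {
  prots <- setdiff(names(proteins), "participant")
  if (is.null(mapping)) {
    mapping <- tibble::tibble(protein = prots, gene = prots)
  }
  unmapped <- setdiff(prots, mapping$protein)
  if (length(unmapped) > 0) {
    msg <- sprintf("%d protein(s) without gene mapping: %s", length(unmapped),
                   paste(head(unmapped, 5), collapse = ", "))
    if (strict) abort(msg) else warn(paste(msg, "- dropped"))
  }
  enriched_genes <- calls$gene[calls$enriched]
  keep_prots <- mapping$protein[mapping$gene %in% enriched_genes]
  keep <- names(proteins)[names(proteins) %in% c("participant", keep_prots)]
  proteins[keep]
}
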