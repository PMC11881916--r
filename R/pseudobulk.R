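#' Per-cell normalization factors
#'
#' Scales every cell to a common library size using its combined (both-allele)
#' assigned-read total: `factor = target_sum / (xa_total + xi_total)`. The same
#' factor applies to both allele matrices of a cell, so within-cell allelic
#' ratios are unchanged. Cells with zero combined total get an `NA` factor and
#' are dropped from downstream aggregation (with a warning).
#'
#' @param ds an [allele_dataset()].
#' @param target_sum library size each cell is scaled to (default 10,000;
#'   escape ratios are invariant to this choice).
#' @return Numeric vector of per-cell factors, named by barcode.
#' @export
normalize_cells <- function(ds, target_sum = 1e4) {
  totals <- Matrix::rowSums(ds$xa) + Matrix::rowSums(ds$xi)
  if (length(totals) == 0 || all(totals == 0))
    stop("empty dataset: no cell has assigned reads")
  f <- target_sum / totals
  zero <- totals == 0
  if (any(zero)) {
    f[zero] <- NA_real_
    warning(sum(zero), " cell(s) with zero assigned reads dropped from aggregation")
  }
  stats::setNames(f, ds$cells$barcode)
}

group_schemes <- list(
  celltype_age = c("cell_type", "age_group"),
  celltype_sample = c("cell_type", "sample_id"),
  age = "age_group"
)

resolve_scheme <- function(by) {
  if (length(by) == 1 && by %in% names(group_schemes)) return(group_schemes[[by]])
  for (s in group_schemes) if (identical(sort(s), sort(by))) return(by)
  stop("unknown grouping scheme: ", paste(by, collapse = "+"),
       " (use cell_type+age_group, cell_type+sample_id, or age_group)")
}

# shared engine for normalized and integer pseudobulks
pseudobulk_engine <- function(ds, weights, by) {
  by <- resolve_scheme(by)
  keep <- !is.na(weights)
  cells <- ds$cells[keep, , drop = FALSE]
  gkey <- interaction(cells[by], drop = FALSE, sep = "\r", lex.order = TRUE)
  groups <- levels(gkey)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)),
                              j = as.integer(gkey),
                              x = weights[keep],
                              dims = c(nrow(cells), length(groups)))
  out <- list()
  for (al in c("xa_strain", "xi_strain")) {
    m <- if (al == "xa_strain") ds$xa[keep, , drop = FALSE]
         else ds$xi[keep, , drop = FALSE]
    sums <- as.matrix(Matrix::crossprod(m, ind))  # genes x groups
    df <- data.frame(
      gene_id = rep(ds$genes$gene_id, times = length(groups)),
      allele = al,
      stringsAsFactors = FALSE)
    parts <- do.call(rbind, strsplit(rep(groups, each = nrow(ds$genes)), "\r", fixed = TRUE))
    for (k in seq_along(by)) df[[by[k]]] <- parts[, k]
    df$value <- as.vector(sums)
    out[[al]] <- df
  }
  res <- rbind(out$xa_strain, out$xi_strain)
  res <- res[do.call(order, res[c("gene_id", "allele", by)]), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "by") <- by
  res
}

#' Aggregate normalized allele counts into a pseudobulk table
#'
#' `value(gene, allele, group) = sum over cells in group of
#' factor_cell * count(cell, gene, allele)`; every (gene, allele, group)
#' combination is present (zero-filled). Escape analysis uses the
#' `cell_type + age_group` scheme; the combined-cell analysis uses
#' `age_group` alone.
#'
#' @param ds an [allele_dataset()].
#' @param factors per-cell factors from [normalize_cells()] (`NA` = drop).
#' @param by grouping columns: `c("cell_type", "age_group")`,
#'   `c("cell_type", "sample_id")`, or `"age_group"`.
#' @return Long-format data.frame: `gene_id`, `allele`, grouping columns,
#'   `value`.
#' @export
pseudobulk <- function(ds, factors, by = c("cell_type", "age_group")) {
  stopifnot(length(factors) == nrow(ds$cells))
  pseudobulk_engine(ds, as.numeric(factors), by)
}

#' Raw integer pseudobulk sums
#'
#' Unnormalized per-(gene, allele, group) integer read sums, the input for
#' count-model differential expression (grouped by `cell_type + sample_id`,
#' or `sample_id` via the `age_group` scheme applied per cell type).
#'
#' @inheritParams pseudobulk
#' @return As [pseudobulk()], with integer-valued `value`.
#' @export
integer_pseudobulk <- function(ds, by = c("cell_type", "sample_id")) {
  pseudobulk_engine(ds, rep(1, nrow(ds$cells)), by)
}
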