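#' Classify a gene's escape transition between young and old
#'
#' Category rules, applied to the young and old [call_escape()] calls of one
#' (gene, cell type):
#' * `not_assessable` — either call is `not_assessable` or `not_detected`;
#' * `increased` — escapee at both ages AND the old CI lower bound strictly
#'   exceeds the young CI upper bound (CI separation alone never suffices);
#' * `maintained` — escapee at both ages, not increased;
#' * `lost` — escapee young, inactive old;
#' * `new_escape` — inactive young, escapee old;
#' * `inactive_both` — inactive at both ages.
#'
#' @param young_status,old_status statuses from [call_escape()].
#' @param young_ci_upper,old_ci_lower the CI bounds entering the increased
#'   rule (ignored unless both ages are escapees).
#' @return Character vector of categories (vectorized over inputs).
#' @export
classify_transition <- function(young_status, old_status,
                                young_ci_upper, old_ci_lower) {
  n <- length(young_status)
  out <- rep(NA_character_, n)
  na <- young_status %in% c("not_assessable", "not_detected") |
    old_status %in% c("not_assessable", "not_detected")
  out[na] <- "not_assessable"
  both <- !na & young_status == "escapee" & old_status == "escapee"
  out[both] <- ifelse(old_ci_lower[both] > young_ci_upper[both],
                      "increased", "maintained")
  out[!na & young_status == "escapee" & old_status == "inactive"] <- "lost"
  out[!na & young_status == "inactive" & old_status == "escapee"] <- "new_escape"
  out[!na & young_status == "inactive" & old_status == "inactive"] <- "inactive_both"
  out
}

#' Classify all escape transitions in a call set
#'
#' Pairs each (gene, cell-type level)'s young and old calls and applies
#' [classify_transition()].
#'
#' @param calls an `escape_calls` object from [call_escape()].
#' @return A data.frame of class `escape_transitions`: `gene_id`, `cell_type`,
#'   young/old statuses, adjusted proportions and CI bounds, `category`.
#' @export
classify_transitions <- function(calls) {
  y <- calls[calls$age_group == "young", , drop = FALSE]
  o <- calls[calls$age_group == "old", , drop = FALSE]
  ky <- paste(y$gene_id, y$cell_type, sep = "\r")
  ko <- paste(o$gene_id, o$cell_type, sep = "\r")
  if (anyDuplicated(ky) || anyDuplicated(ko))
    stop("duplicate (gene, cell type) records in escape calls")
  m <- match(ky, ko)
  if (anyNA(m)) stop("young/old call tables do not align")
  o <- o[m, , drop = FALSE]
  rec <- data.frame(
    gene_id = y$gene_id, cell_type = y$cell_type,
    young_status = y$status, old_status = o$status,
    young_p_escadj = y$p_escadj, old_p_escadj = o$p_escadj,
    young_ci_lower = y$ci_lower, young_ci_upper = y$ci_upper,
    old_ci_lower = o$ci_lower, old_ci_upper = o$ci_upper,
    detected = !(y$status == "not_detected" & o$status == "not_detected"),
    stringsAsFactors = FALSE)
  rec$category <- classify_transition(rec$young_status, rec$old_status,
                                      rec$young_ci_upper, rec$old_ci_lower)
  rec <- rec[order(rec$cell_type, rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, class = c("escape_transitions", "data.frame"))
}

transition_categories <- c("increased", "maintained", "lost", "new_escape",
                           "inactive_both", "not_assessable")

#' @export
print.escape_transitions <- function(x, ...) {
  cat("escape_transitions:", nrow(x), "(gene, cell type) records\n")
  print(table(category = factor(x$category, transition_categories),
              cell_type = x$cell_type))
  invisible(x)
}

#' Sankey-style category counts
#'
#' Counts transition categories per cell-type level. Conservation: per cell
#' type, the category counts sum to the number of X genes considered.
#'
#' @param records an `escape_transitions` table (one row per gene and cell
#'   type).
#' @return List of class `sankey_summary`: `counts` (data.frame cell_type x
#'   category with `n`), `n_genes` and `n_detected` per cell type.
#' @export
summarize_sankey <- function(records) {
  if (anyDuplicated(paste(records$gene_id, records$cell_type, sep = "\r")))
    stop("duplicate (gene, cell type) records")
  tab <- as.data.frame(table(
    cell_type = records$cell_type,
    category = factor(records$category, transition_categories)))
  names(tab)[3] <- "n"
  n_genes <- tapply(records$gene_id, records$cell_type, length)
  n_det <- tapply(records$detected, records$cell_type, sum)
  structure(list(counts = tab,
                 n_genes = as.integer(n_genes[order(names(n_genes))]),
                 n_detected = as.integer(n_det[order(names(n_det))]),
                 cell_types = sort(unique(records$cell_type))),
            class = "sankey_summary")
}

#' @export
print.sankey_summary <- function(x, ...) {
  wide <- stats::reshape(x$counts, idvar = "cell_type", timevar = "category",
                         direction = "wide")
  names(wide) <- sub("^n\\.", "", names(wide))
  wide$detected <- x$n_detected[match(wide$cell_type, x$cell_types)]
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Cross-cell-type escape pattern of one gene
#'
#' Ignoring uninformative records (`inactive_both`, `not_assessable`), a gene
#' is `consistent:<category>` if all informative cell types agree and `mixed`
#' if at least two distinct informative categories occur.
#'
#' @param categories transition categories of one gene across cell types.
#' @return `"consistent:<category>"`, `"mixed"`, or `"uninformative"` when no
#'   informative record exists.
#' @export
cross_celltype_pattern <- function(categories) {
  inf <- categories[!categories %in% c("inactive_both", "not_assessable")]
  if (length(inf) == 0) return("uninformative")
  u <- unique(inf)
  if (length(u) == 1) paste0("consistent:", u) else "mixed"
}

#' Dot-plot statistics for inactive-X expression
#'
#' Per (gene, group): the fraction of cells with a nonzero inactive-strain
#' count and the mean over all group cells of `log1p(normalized Xi count)` —
#' the size and color encodings of an expression dot plot.
#'
#' @param ds an [allele_dataset()].
#' @param factors per-cell factors from [normalize_cells()].
#' @param genes gene ids (default: all X-linked genes).
#' @param by grouping columns (default `cell_type + age_group`).
#' @return data.frame: `gene_id`, group columns, `fraction_expressing`,
#'   `mean_xi_expression`.
#' @export
xi_dotplot_stats <- function(ds, factors, genes = NULL,
                             by = c("cell_type", "age_group")) {
  if (is.null(genes)) genes <- ds$genes$gene_id[ds$genes$chromosome == "X"]
  gi <- match(genes, ds$genes$gene_id)
  if (anyNA(gi)) stop("unknown gene id(s): ",
                      paste(genes[is.na(gi)], collapse = ", "))
  keep <- !is.na(factors)
  cells <- ds$cells[keep, , drop = FALSE]
  gkey <- interaction(cells[by], drop = TRUE, sep = "\r", lex.order = TRUE)
  if (nlevels(gkey) == 0 || any(table(gkey) == 0)) stop("empty group")
  xi <- ds$xi[keep, gi, drop = FALSE]
  scaled <- methods::as(Matrix::Diagonal(x = unname(factors[keep])) %*% xi,
                        "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)),
                              j = as.integer(gkey), x = 1,
                              dims = c(nrow(cells), nlevels(gkey)))
  nz <- xi; nz@x <- as.numeric(nz@x > 0)
  gsize <- Matrix::colSums(ind)
  frac <- t(as.matrix(Matrix::crossprod(nz, ind))) / gsize   # groups x genes
  mexp <- t(as.matrix(Matrix::crossprod(scaled, ind))) / gsize
  parts <- do.call(rbind, strsplit(levels(gkey), "\r", fixed = TRUE))
  out <- data.frame(gene_id = rep(genes, each = nlevels(gkey)),
                    stringsAsFactors = FALSE)
  for (k in seq_along(by)) out[[by[k]]] <- rep(parts[, k], times = length(genes))
  out$fraction_expressing <- as.vector(frac)
  out$mean_xi_expression <- as.vector(mexp)
  out[order(out$gene_id, out[[by[1]]]), , drop = FALSE]
}

#' Paired test for escape change with age
#'
#' Standard paired two-tailed t test on old-minus-young adjusted escape
#' proportions across (gene, cell type) pairs.
#'
#' @param young,old paired adjusted escape proportions.
#' @return List: `statistic`, `df`, `p_value`, `n`, `degenerate` (TRUE when
#'   the differences have zero variance, in which case no test is computed).
#' @export
paired_escape_change_test <- function(young, old) {
  if (length(young) != length(old)) stop("young/old vectors must be paired")
  n <- length(young)
  if (n < 2) stop("paired test requires at least 2 pairs")
  d <- old - young
  if (stats::sd(d) == 0)
    return(list(statistic = NA_real_, df = n - 1L, p_value = NA_real_,
                n = n, degenerate = TRUE))
  tt <- stats::t.test(old, young, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, n = n, degenerate = FALSE)
}
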