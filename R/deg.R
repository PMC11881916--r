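#' Build a feature-by-sample count matrix for one cell-type analysis
#'
#' Subsets the dataset to one cell type (or keeps all cells for the combined
#' analysis), forms raw integer pseudobulk sums per sample, and reshapes them
#' to a (gene x allele) feature-by-sample matrix. Differential expression is
#' allele-resolved throughout: each gene contributes an `xa_strain` and an
#' `xi_strain` feature, named `<gene_id>::<allele>`.
#'
#' @param ds an [allele_dataset()].
#' @param cell_type one cell type, or `"all"` for the combined analysis.
#' @return List: `counts` (integer matrix features x samples), `age` (named
#'   age-group factor per sample column).
#' @export
de_count_matrix <- function(ds, cell_type = "all") {
  keep <- if (identical(cell_type, "all")) rep(TRUE, nrow(ds$cells))
          else ds$cells$cell_type == cell_type
  if (!any(keep)) stop("no cells of type ", cell_type)
  sub <- allele_dataset(ds$xa[keep, , drop = FALSE], ds$xi[keep, , drop = FALSE],
                        ds$cells[keep, , drop = FALSE], ds$genes)
  # collapse cell_type to one level so grouping is by sample alone
  sub$cells$cell_type <- "all"
  pb <- integer_pseudobulk(sub, c("cell_type", "sample_id"))
  samples <- sort(unique(pb$sample_id))
  feat <- paste(pb$gene_id, pb$allele, sep = "::")
  counts <- matrix(0L, length(unique(feat)), length(samples),
                   dimnames = list(unique(feat), samples))
  counts[cbind(match(feat, rownames(counts)), match(pb$sample_id, samples))] <-
    as.integer(pb$value)
  age_map <- unique(ds$cells[keep, c("sample_id", "age_group")])
  age <- stats::setNames(age_map$age_group, age_map$sample_id)[samples]
  list(counts = counts, age = age)
}

#' Filter features for differential expression
#'
#' Retains a (gene, allele) feature iff its total across samples is at least
#' `min_total` AND (under the default `"any_sample"` reading) at least one
#' individual sample holds `min_sample` counts. The `"every_sample"` reading
#' requires `min_sample` in all samples instead.
#'
#' @param counts integer feature-by-sample matrix.
#' @param min_total minimum total across samples (default 10).
#' @param min_sample minimum single-sample count (default 10).
#' @param mode `"any_sample"` (default) or `"every_sample"`.
#' @return Logical vector over rows of `counts`.
#' @export
filter_de_features <- function(counts, min_total = 10, min_sample = 10,
                               mode = c("any_sample", "every_sample")) {
  mode <- match.arg(mode)
  tot_ok <- rowSums(counts) >= min_total
  samp <- if (mode == "any_sample") apply(counts, 1, max) >= min_sample
          else apply(counts, 1, min) >= min_sample
  tot_ok & samp
}

#' Pseudobulk differential expression between age groups
#'
#' Fits a per-feature negative-binomial model with size factors and tests the
#' age coefficient (old vs young, log2 scale) with a Wald test, adjusting p
#' values by Benjamini-Hochberg across the tested features. The fit is
#' delegated to DESeq2 (size factors of type `"poscounts"`, robust to the many
#' zeros of allele-level features; independent filtering and Cook's cutoff
#' disabled so every tested feature receives an adjusted p).
#'
#' @param counts integer feature-by-sample matrix (pre-filtered).
#' @param age character/factor of `young`/`old` per sample column.
#' @param cell_type label stored in the output records.
#' @param alpha,lfc significance thresholds handed to [call_significant()].
#' @return data.frame of class `deg_table`: `gene_id`, `allele`, `cell_type`,
#'   `log2fc`, `p_value`, `p_adjusted`, `significant`.
#' @export
fit_pseudobulk_de <- function(counts, age, cell_type = "all",
                              alpha = 0.05, lfc = 0.1) {
  age <- as.character(age)
  if (length(age) != ncol(counts)) stop("one age label per sample required")
  if (length(unique(age)) < 2)
    stop("degenerate design: both age groups are required")
  if (min(table(age)) < 2)
    stop("at least 2 samples per age group are required")
  coldata <- data.frame(age = factor(age, levels = c("young", "old")))
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                        colData = coldata, design = ~age)
  dds <- DESeq2::estimateSizeFactors(dds, type = "poscounts")
  dds <- suppressWarnings(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  res <- DESeq2::results(dds, name = "age_old_vs_young",
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  parts <- do.call(rbind, strsplit(rownames(res), "::", fixed = TRUE))
  out <- data.frame(
    gene_id = parts[, 1], allele = parts[, 2], cell_type = cell_type,
    log2fc = res$log2FoldChange, p_value = res$pvalue,
    p_adjusted = res$padj, stringsAsFactors = FALSE)
  out$significant <- call_significant(out, alpha = alpha, lfc = lfc)
  structure(out, class = c("deg_table", "data.frame"))
}

#' @export
print.deg_table <- function(x, ...) {
  cat("deg_table:", nrow(x), "features across",
      length(unique(x$cell_type)), "cell-type analyses |",
      sum(x$significant, na.rm = TRUE), "significant\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Significance rule for differential expression
#'
#' Strict thresholds exactly as printed: `p_adjusted < 0.05` and
#' `log2fc > 0.1` or `log2fc < -0.1`. Missing p values are never significant.
#'
#' @param records data.frame with `p_adjusted` and `log2fc`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 0.1).
#' @return Logical vector.
#' @export
call_significant <- function(records, alpha = 0.05, lfc = 0.1) {
  sig <- records$p_adjusted < alpha &
    (records$log2fc > lfc | records$log2fc < -lfc)
  sig & !is.na(sig)
}

#' Run allele-level DE for every cell type plus the combined analysis
#'
#' @param ds an [allele_dataset()].
#' @param cell_types cell types to analyse (default: all present, plus
#'   `"all"`).
#' @param min_total,min_sample,filter_mode see [filter_de_features()].
#' @param alpha,lfc see [call_significant()].
#' @return A `deg_table` covering all analyses, with an `expressed` attribute
#'   listing the features retained by the filter per cell type.
#' @export
run_de <- function(ds, cell_types = NULL, min_total = 10, min_sample = 10,
                   filter_mode = "any_sample", alpha = 0.05, lfc = 0.1) {
  if (is.null(cell_types))
    cell_types <- c("all", sort(unique(ds$cells$cell_type)))
  out <- list(); expressed <- list()
  for (ct in cell_types) {
    dm <- de_count_matrix(ds, ct)
    keep <- filter_de_features(dm$counts, min_total, min_sample, filter_mode)
    expressed[[ct]] <- rownames(dm$counts)[keep]
    if (!any(keep)) next
    out[[ct]] <- fit_pseudobulk_de(dm$counts[keep, , drop = FALSE], dm$age,
                                   cell_type = ct, alpha = alpha, lfc = lfc)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("deg_table", "data.frame"), expressed = expressed)
}

#' Chromosome-level enrichment of differentially expressed genes
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2 table
#' of significant vs non-significant features on the focal chromosome vs the
#' comparison set, both normalized to total expressed features.
#'
#' @param sig_features significant feature/gene ids.
#' @param expressed_features all expressed (tested) feature/gene ids;
#'   must contain `sig_features`.
#' @param genes gene annotation (`gene_id`, `chromosome`). Feature ids of the
#'   form `<gene>::<allele>` are mapped to their gene.
#' @param focal focal chromosome (default `"X"`).
#' @param comparison `"autosomes"` (all non-focal chromosomes) or one
#'   chromosome name (e.g. a size-matched autosome).
#' @return List of class `enrichment_result`: counts, `chi2`, `p_value`.
#' @export
chromosome_enrichment <- function(sig_features, expressed_features, genes,
                                  focal = "X", comparison = "autosomes") {
  chrom_of <- function(f) {
    g <- sub("::.*$", "", f)
    genes$chromosome[match(g, genes$gene_id)]
  }
  ch_e <- chrom_of(expressed_features)
  is_sig <- expressed_features %in% sig_features
  on_focal <- ch_e == focal
  on_comp <- if (identical(comparison, "autosomes")) ch_e != focal
             else ch_e == comparison
  n_expr_f <- sum(on_focal, na.rm = TRUE)
  n_expr_c <- sum(on_comp, na.rm = TRUE)
  if (n_expr_f == 0 || n_expr_c == 0)
    stop("empty margin: no expressed features on focal or comparison set")
  n_sig_f <- sum(is_sig & on_focal, na.rm = TRUE)
  n_sig_c <- sum(is_sig & on_comp, na.rm = TRUE)
  tab <- matrix(c(n_sig_f, n_expr_f - n_sig_f,
                  n_sig_c, n_expr_c - n_sig_c), 2, byrow = TRUE,
                dimnames = list(c(focal, paste(comparison, collapse = "+")),
                                c("sig", "not_sig")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty margin in enrichment table")
  # asymptotic Pearson statistic by design; small-count warnings are expected
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(focal = focal, comparison = comparison,
                 n_sig_focal = n_sig_f, n_expressed_focal = n_expr_f,
                 n_sig_comparison = n_sig_c, n_expressed_comparison = n_expr_c,
                 chi2 = unname(ct$statistic), p_value = ct$p.value),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment %s vs %s: %d/%d vs %d/%d significant | chi2 = %.4f, p = %.4g\n",
              x$focal, paste(x$comparison, collapse = "+"),
              x$n_sig_focal, x$n_expressed_focal,
              x$n_sig_comparison, x$n_expressed_comparison,
              x$chi2, x$p_value))
  invisible(x)
}

#' Cell-type category of a differentially expressed feature
#'
#' Applies, in order: neuronal (significant in >= 2 neuronal cell types and
#' <= 1 glial), glial (>= 2 glial, <= 1 neuronal), multiple (>= 2 cell
#' types; direction conflicts here are `excluded_discordant`), cell-type
#' specific (exactly 1).
#'
#' @param cell_types cell types in which the feature is significant.
#' @param directions fold-change signs (+1/-1) matching `cell_types`.
#' @param cell_class_map named vector mapping cell type to
#'   `"neuronal"`/`"glial"`/`"other"` (default [default_cell_class_map()]).
#' @return List of class `deg_category`: `category` and the supporting cell
#'   types with direction.
#' @export
classify_deg_category <- function(cell_types, directions,
                                  cell_class_map = default_cell_class_map()) {
  if (length(cell_types) != length(directions))
    stop("one direction per cell type required")
  if (length(cell_types) == 0) stop("feature significant in no cell type")
  miss <- setdiff(cell_types, names(cell_class_map))
  if (length(miss)) stop("cell type(s) missing from class map: ",
                         paste(miss, collapse = ", "))
  cls <- cell_class_map[cell_types]
  n_neur <- sum(cls == "neuronal"); n_glia <- sum(cls == "glial")
  category <-
    if (n_neur >= 2 && n_glia <= 1) "neuronal"
    else if (n_glia >= 2 && n_neur <= 1) "glial"
    else if (length(cell_types) >= 2) {
      if (length(unique(sign(directions))) > 1) "excluded_discordant"
      else "multiple"
    } else "cell_type_specific"
  structure(list(category = category,
                 support = data.frame(cell_type = cell_types,
                                      direction = sign(directions),
                                      stringsAsFactors = FALSE)),
            class = "deg_category")
}

#' Categorize all significant features of a DE table
#'
#' @param deg a `deg_table` from [run_de()] (cell-type analyses only; the
#'   combined `"all"` analysis is ignored).
#' @param cell_class_map see [classify_deg_category()].
#' @return data.frame: `gene_id`, `allele`, `category`, `n_cell_types`.
#' @export
categorize_degs <- function(deg, cell_class_map = default_cell_class_map()) {
  d <- deg[deg$significant & deg$cell_type != "all", , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(gene_id = character(), allele = character(),
                      category = character(), n_cell_types = integer()))
  key <- paste(d$gene_id, d$allele, sep = "::")
  out <- lapply(split(seq_len(nrow(d)), key), function(ix) {
    cc <- classify_deg_category(d$cell_type[ix], sign(d$log2fc[ix]),
                                cell_class_map)
    data.frame(gene_id = d$gene_id[ix[1]], allele = d$allele[ix[1]],
               category = cc$category, n_cell_types = length(ix),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id, res$allele), , drop = FALSE]
}
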