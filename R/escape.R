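#' Escape proportion
#'
#' Fraction of a gene's allele-assigned reads originating from the inactive-X
#' strain: `p_esc = xi / (xi + xa)`. Undefined (NA) when both sums are zero —
#' the caller marks such genes `not_detected`.
#'
#' @param xi_reads,xa_reads normalized read sums assigned to the inactive-X
#'   and active-X strain genomes (vectorized).
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
escape_proportion <- function(xi_reads, xa_reads) {
  tot <- xi_reads + xa_reads
  ifelse(tot > 0, xi_reads / tot, NA_real_)
}

#' Autosomal mapping-bias ratio
#'
#' Total normalized autosomal reads assigned to the alternate (castaneus)
#' strain divided by the total assigned to the reference (musculus) strain,
#' summed over all autosomal genes and all groups of the table. A ratio below
#' 1 reflects the usual mapping bias toward the reference genome.
#'
#' @param pb a long pseudobulk table from [pseudobulk()].
#' @param genes gene annotation data.frame (`gene_id`, `chromosome`).
#' @return List of class `bias_ratio`: `a_t_cast`, `a_t_mus`, `ratio`.
#' @export
autosomal_bias_ratio <- function(pb, genes) {
  chrom <- genes$chromosome[match(pb$gene_id, genes$gene_id)]
  auto <- pb[!is.na(chrom) & chrom != "X", , drop = FALSE]
  if (nrow(auto) == 0) stop("no autosomal genes in pseudobulk table")
  a_t_cast <- sum(auto$value[auto$allele == "xi_strain"])
  a_t_mus <- sum(auto$value[auto$allele == "xa_strain"])
  if (a_t_mus <= 0) stop("reference-strain autosomal total is zero")
  structure(list(a_t_cast = a_t_cast, a_t_mus = a_t_mus,
                 ratio = a_t_cast / a_t_mus),
            class = "bias_ratio")
}

#' @export
print.bias_ratio <- function(x, ...) {
  cat(sprintf("autosomal bias ratio (cast/mus): %.4f  [cast %.1f / mus %.1f]\n",
              x$ratio, x$a_t_cast, x$a_t_mus))
  invisible(x)
}

#' Mapping-bias-corrected escape proportion
#'
#' `p_escadj = p_esc / (p_esc + ratio * (1 - p_esc))`, where `ratio` is the
#' autosomal castaneus/musculus read ratio. With `ratio = 1` (no bias) the
#' proportion is returned unchanged.
#'
#' @param p_esc escape proportion(s) from [escape_proportion()].
#' @param ratio a [autosomal_bias_ratio()] result or a bare numeric ratio.
#' @return Adjusted proportion(s) in \[0, 1\].
#' @export
adjust_escape <- function(p_esc, ratio) {
  r <- if (inherits(ratio, "bias_ratio")) ratio$ratio else ratio
  p_esc / (p_esc + r * (1 - p_esc))
}

#' Wald confidence interval for the adjusted escape proportion
#'
#' `p_escadj +/- z * sqrt(p_escadj * (1 - p_escadj) / total_reads)`, with the
#' 99% multiplier `z = 2.575` and bounds clamped to \[0, 1\].
#'
#' @param p_escadj adjusted proportion(s).
#' @param total_reads total normalized reads `xi + xa` (must be positive).
#' @param z normal multiplier (default the printed 2.575).
#' @return Two-column matrix `lower`, `upper`.
#' @export
escape_interval <- function(p_escadj, total_reads, z = 2.575) {
  if (any(total_reads <= 0, na.rm = TRUE))
    stop("total_reads must be positive for interval computation")
  hw <- z * sqrt(p_escadj * (1 - p_escadj) / total_reads)
  cbind(lower = pmax(0, p_escadj - hw), upper = pmin(1, p_escadj + hw))
}

#' Depth threshold for escape calling
#'
#' Pools the per-(gene, allele, group) normalized X-linked read sums of the
#' table into a single distribution and returns its 5th percentile (linear
#' interpolation between order statistics). Genes with an allelic sum strictly
#' below this threshold in a group are not called escapees there.
#'
#' @param pb pseudobulk table (escape grouping).
#' @param genes gene annotation.
#' @param prob percentile (default 0.05).
#' @return Scalar threshold.
#' @export
depth_threshold <- function(pb, genes, prob = 0.05) {
  chrom <- genes$chromosome[match(pb$gene_id, genes$gene_id)]
  vals <- pb$value[!is.na(chrom) & chrom == "X"]
  if (length(vals) == 0) stop("no X-linked genes in pseudobulk table")
  unname(stats::quantile(vals, prob, type = 7))
}

#' Escapee status rule
#'
#' A gene escapes in a group iff the CI lower bound is strictly greater than
#' 0, the adjusted escape proportion is strictly greater than `min_escape`
#' (0.05), and both allelic read sums are at or above the depth threshold
#' (ties pass; "lower than" is strict). Groups with `xa` below threshold are
#' `not_assessable` (age trends are not calculated for them); zero total
#' reads give `not_detected`; everything else is `inactive`.
#'
#' @param p_escadj,ci_lower adjusted proportion and CI lower bound.
#' @param xi_reads,xa_reads allelic normalized read sums.
#' @param threshold depth threshold from [depth_threshold()].
#' @param min_escape minimum adjusted escape proportion (default 0.05).
#' @return Character vector of statuses: `escapee`, `inactive`,
#'   `not_assessable`, `not_detected`.
#' @export
call_escape_status <- function(p_escadj, ci_lower, xi_reads, xa_reads,
                               threshold, min_escape = 0.05) {
  status <- rep("inactive", length(xi_reads))
  esc <- !is.na(p_escadj) & ci_lower > 0 & p_escadj > min_escape &
    xi_reads >= threshold & xa_reads >= threshold
  status[esc] <- "escapee"
  status[xa_reads < threshold] <- "not_assessable"
  status[xi_reads + xa_reads == 0] <- "not_detected"
  status
}

#' Call XCI escape per gene, cell type and age group
#'
#' The full escape-calling procedure: per-cell normalization, pseudobulk
#' aggregation by cell type and age (plus a combined `"all"` cell-type level),
#' global autosomal mapping-bias estimation, per-gene adjusted escape
#' proportions with 99% Wald intervals, depth filtering at the pooled 5th
#' percentile of X allelic read sums, and status assignment.
#'
#' @param ds an [allele_dataset()].
#' @param target_sum per-cell normalization target (default 10,000).
#' @param z CI multiplier (default 2.575, the printed 99% value).
#' @param min_escape escapee threshold on the adjusted proportion (0.05).
#' @param depth_prob depth-filter percentile (0.05).
#' @param bias_scope `"global"` (one ratio from all cells, the default) or
#'   `"per_group"` (one ratio per cell type and age).
#' @param include_all add the combined-cell-type (`cell_type = "all"`) level.
#' @return A data.frame of class `escape_calls` with columns `gene_id`,
#'   `cell_type`, `age_group`, `xi_reads`, `xa_reads`, `p_esc`, `p_escadj`,
#'   `ci_lower`, `ci_upper`, `depth_ok_xi`, `depth_ok_xa`, `status`.
#'   Attributes: `bias_ratio`, `thresholds`, `params`.
#' @export
call_escape <- function(ds, target_sum = 1e4, z = 2.575, min_escape = 0.05,
                        depth_prob = 0.05, bias_scope = c("global", "per_group"),
                        include_all = TRUE) {
  bias_scope <- match.arg(bias_scope)
  if (!any(ds$genes$chromosome == "X"))
    stop("escape stage: dataset contains no X-linked genes")
  factors <- normalize_cells(ds, target_sum)
  pb_ct <- pseudobulk(ds, factors, c("cell_type", "age_group"))
  ratio <- autosomal_bias_ratio(pb_ct, ds$genes)

  calls_one <- function(pb, label) {
    th <- depth_threshold(pb, ds$genes, depth_prob)
    chrom <- ds$genes$chromosome[match(pb$gene_id, ds$genes$gene_id)]
    xpb <- pb[chrom == "X", , drop = FALSE]
    wide <- xpb[xpb$allele == "xa_strain",
                setdiff(names(xpb), c("allele", "value")), drop = FALSE]
    wide$xa_reads <- xpb$value[xpb$allele == "xa_strain"]
    key <- function(d) do.call(paste, c(d[setdiff(names(wide),
                                                  c("xa_reads", "xi_reads"))],
                                        sep = "\r"))
    xi_part <- xpb[xpb$allele == "xi_strain", , drop = FALSE]
    wide$xi_reads <- xi_part$value[match(key(wide), key(xi_part))]
    if (!"cell_type" %in% names(wide)) wide$cell_type <- label
    wide$p_esc <- escape_proportion(wide$xi_reads, wide$xa_reads)
    if (bias_scope == "per_group" && "cell_type" %in% attr(pb, "by")) {
      grp <- paste(wide$cell_type, wide$age_group, sep = "\r")
      rg <- vapply(unique(grp), function(g) {
        sel <- paste(pb$cell_type, pb$age_group, sep = "\r") == g
        autosomal_bias_ratio(pb[sel, , drop = FALSE], ds$genes)$ratio
      }, 0)
      wide$p_escadj <- adjust_escape(wide$p_esc, unname(rg[grp]))
    } else {
      wide$p_escadj <- adjust_escape(wide$p_esc, ratio$ratio)
    }
    tot <- wide$xi_reads + wide$xa_reads
    ci <- matrix(NA_real_, nrow(wide), 2)
    pos <- tot > 0
    ci[pos, ] <- escape_interval(wide$p_escadj[pos], tot[pos], z)
    wide$ci_lower <- ci[, 1]; wide$ci_upper <- ci[, 2]
    wide$depth_ok_xi <- wide$xi_reads >= th
    wide$depth_ok_xa <- wide$xa_reads >= th
    wide$status <- call_escape_status(wide$p_escadj, wide$ci_lower,
                                      wide$xi_reads, wide$xa_reads,
                                      th, min_escape)
    attr(wide, "threshold") <- th
    wide
  }

  res <- calls_one(pb_ct, NULL)
  thresholds <- c(by_celltype = attr(res, "threshold"))
  if (include_all) {
    pb_all <- pseudobulk(ds, factors, "age_group")
    res_all <- calls_one(pb_all, "all")
    thresholds <- c(thresholds, combined = attr(res_all, "threshold"))
    res <- rbind(res[names(res_all)], res_all)
  }
  cols <- c("gene_id", "cell_type", "age_group", "xi_reads", "xa_reads",
            "p_esc", "p_escadj", "ci_lower", "ci_upper",
            "depth_ok_xi", "depth_ok_xa", "status")
  res <- res[cols]
  res <- res[order(res$cell_type, res$gene_id, res$age_group), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("escape_calls", "data.frame"),
            bias_ratio = ratio, thresholds = thresholds,
            params = list(target_sum = target_sum, z = z,
                          min_escape = min_escape, depth_prob = depth_prob,
                          bias_scope = bias_scope))
}

#' @export
print.escape_calls <- function(x, ...) {
  cat("escape_calls:", length(unique(x$gene_id)), "X genes x",
      length(unique(x$cell_type)), "cell-type levels x 2 ages\n")
  cat(sprintf("  bias ratio %.4f | depth threshold(s) %s\n",
              attr(x, "bias_ratio")$ratio,
              paste(sprintf("%.2f", attr(x, "thresholds")), collapse = ", ")))
  print(table(status = x$status, age = x$age_group))
  invisible(x)
}

#' @export
summary.escape_calls <- function(object, ...) {
  esc <- object[object$status == "escapee", , drop = FALSE]
  out <- as.data.frame(table(cell_type = object$cell_type,
                             age_group = object$age_group,
                             status = object$status))
  out <- out[out$Freq > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(counts = out,
                 n_escapee = nrow(esc),
                 bias_ratio = attr(object, "bias_ratio")$ratio),
            class = "summary.escape_calls")
}

#' @export
print.summary.escape_calls <- function(x, ...) {
  cat("escapee calls:", x$n_escapee,
      sprintf("| bias ratio %.4f\n", x$bias_ratio))
  print(x$counts)
  invisible(x)
}

#' Plot escape confidence intervals
#'
#' Draws per-gene 99% CI segments for one cell-type level, young vs old,
#' with the escapee thresholds (0 and `min_escape`) as dotted lines.
#'
#' @param x an `escape_calls` object.
#' @param cell_type cell-type level to plot (default `"all"` if present).
#' @param statuses statuses to include (default escapees in either age).
#' @param ... passed to [graphics::plot()].
#' @export
plot.escape_calls <- function(x, cell_type = NULL, statuses = "escapee", ...) {
  if (is.null(cell_type))
    cell_type <- if ("all" %in% x$cell_type) "all" else x$cell_type[1]
  d <- x[x$cell_type == cell_type, , drop = FALSE]
  keep <- unique(d$gene_id[d$status %in% statuses])
  d <- d[d$gene_id %in% keep, , drop = FALSE]
  if (nrow(d) == 0) stop("nothing to plot for cell type ", cell_type)
  genes <- sort(unique(d$gene_id))
  xpos <- match(d$gene_id, genes) + ifelse(d$age_group == "old", 0.18, -0.18)
  col <- ifelse(d$age_group == "old", "firebrick", "steelblue")
  graphics::plot(xpos, d$p_escadj, pch = 19, col = col, xaxt = "n",
                 xlab = "", ylab = "adjusted escape proportion",
                 ylim = c(0, max(d$ci_upper, 0.1, na.rm = TRUE)),
                 main = paste("Xi escape,", cell_type, "cells"), ...)
  graphics::segments(xpos, d$ci_lower, xpos, d$ci_upper, col = col)
  graphics::axis(1, at = seq_along(genes), labels = genes, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = c(0, attr(x, "params")$min_escape), lty = 3)
  graphics::legend("topleft", legend = c("young", "old"), pch = 19,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
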